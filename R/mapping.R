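#' Build a k-mer seed index of the reference
#'
#' Indexes every k-mer position of the two-subgenome reference.  The default
#' k of 17 separates homeologous sequence at ~85 percent identity for 150 bp
#' reads: most 17-mers carry at least one diagnostic substitution.
#'
#' @param reference output of [build_reference()], a named DNAStringSet, or
#'   a named character vector of contigs.
#' @param k k-mer size, between 11 and 31 and no larger than the shortest
#'   contig.
#' @return A `seed_index` object.
#' @export
build_index <- function(reference, k = 17L) {
  seqs <- if (is.list(reference) && !is.null(reference$sequences))
    reference$sequences else reference
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  if (!length(seqs)) stop("empty reference")
  if (k < 11 || k > 31) stop("k must be between 11 and 31")
  if (k > min(nchar(seqs)))
    stop("k (", k, ") larger than shortest contig (", min(nchar(seqs)), ")")
  ptr <- cpp_build_index(unname(seqs), names(seqs), as.integer(k))
  st <- cpp_index_stats(ptr)
  structure(list(ptr = ptr, k = as.integer(k), contig_names = names(seqs),
                 contig_lengths = stats::setNames(nchar(seqs), names(seqs)),
                 sequences = seqs,
                 n_positions = st$n_positions, n_multi = st$n_multi),
            class = "seed_index")
}

# external pointers do not survive serialization; rebuild transparently
index_ptr <- function(index) {
  if (!cpp_ptr_valid(index$ptr)) {
    index$ptr <- cpp_build_index(unname(index$sequences), index$contig_names,
                                 index$k)
  }
  index$ptr
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index: k =", x$k, "|", length(x$contig_names), "contigs |",
      format(x$n_positions, big.mark = ","), "k-mer positions (",
      format(x$n_multi, big.mark = ","), "multi-mapping )\n")
  invisible(x)
}

#' Positions of one k-mer in the index
#' @param index a `seed_index`.
#' @param kmer k-length string.
#' @return Integer vector of 1-based positions (across contigs in index
#'   order, per contig offset).
#' @export
kmer_positions <- function(index, kmer) {
  cpp_kmer_hits(index_ptr(index), kmer)
}

#' Map reads to the reference
#'
#' Seed-and-extend mapping: k-mer seeds vote for candidate loci, candidates
#' are scored ungapped (match +1, mismatch -2) with an affine-gap glocal
#' alignment fallback (gap open -4, extend -1), and reads that fail both are
#' tested for a split alignment (a prefix and suffix mapping to distinct
#' loci), which is the read-level evidence at recombination junctions.  The
#' best-scoring locus is reported; exact ties are broken by (contig,
#' position) and flagged `ambiguous` with the tie locus recorded.  Unmapped
#' reads are retained with `mapped = FALSE`.
#'
#' @param reads a `read_set` from [simulate_reads()], a data.frame with
#'   seq1/seq2, or a character vector of sequences.
#' @param index a `seed_index` built on the reference.
#' @return data.frame of class `alignments`, one row per read end.
#' @export
map_reads <- function(reads, index) {
  stopifnot(inherits(index, "seed_index"))
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("r%07d", seq_along(reads))
    seqs <- unname(reads)
    mate <- rep(0L, length(seqs))
    pair <- seq_along(seqs)
  } else {
    ids <- c(paste0(reads$read_id, "/1"), paste0(reads$read_id, "/2"))
    seqs <- c(reads$seq1, reads$seq2)
    mate <- rep(1:2, each = nrow(reads))
    pair <- rep(seq_len(nrow(reads)), 2)
  }
  m <- cpp_map_reads(index_ptr(index), seqs)
  cn <- index$contig_names
  aln <- data.frame(
    read_id = ids, mate = mate, pair = pair,
    contig = ifelse(is.na(m$contig), NA_character_, cn[m$contig]),
    pos = m$pos, strand = as.character(m$strand), cigar = as.character(m$cigar),
    seq = as.character(m$seq), score = m$score, nm = m$nm,
    is_split = m$is_split, ambiguous = m$ambiguous, mapped = m$mapped,
    split_contig = ifelse(is.na(m$split_contig), NA_character_, cn[m$split_contig]),
    split_pos = m$split_pos, split_len = m$split_len,
    tie_contig = ifelse(is.na(m$tie_contig), NA_character_, cn[m$tie_contig]),
    tie_pos = m$tie_pos,
    stringsAsFactors = FALSE)
  aln$cigar[!aln$mapped] <- NA_character_
  # mate linkage
  if (any(mate > 0)) {
    n <- length(seqs) / 2
    aln$mate_contig <- c(aln$contig[(n + 1):(2 * n)], aln$contig[1:n])
    aln$mate_pos <- c(aln$pos[(n + 1):(2 * n)], aln$pos[1:n])
    aln$mate_strand <- c(aln$strand[(n + 1):(2 * n)], aln$strand[1:n])
  } else {
    aln$mate_contig <- NA_character_
    aln$mate_pos <- NA_integer_
    aln$mate_strand <- NA_character_
  }
  attr(aln, "contig_lengths") <- index$contig_lengths
  class(aln) <- c("alignments", class(aln))
  aln
}

#' Per-window read coverage
#'
#' Mean aligned depth per fixed-width window per contig, the substrate of
#' copy-number analysis.  Reads mapping equally well to both homeologous
#' loci (`ambiguous`) contribute half a read to each locus, preventing a
#' systematic subgenome bias at high-homology loci.
#'
#' @param alignments an `alignments` data.frame.
#' @param window window width in bp (>= 100).
#' @param contig_lengths named vector; defaults to the lengths recorded by
#'   [map_reads()].
#' @return data.frame of class `coverage_track` with one row per window and
#'   attributes `window`, `genome_median` (median window depth over nuclear
#'   contigs) and `total_aligned` (aligned bases).
#' @export
compute_coverage <- function(alignments, window = 1000L,
                             contig_lengths = attr(alignments, "contig_lengths")) {
  stopifnot(window >= 100)
  if (is.null(contig_lengths)) stop("contig_lengths required")
  a <- alignments[alignments$mapped & !is.na(alignments$contig), , drop = FALSE]
  spans <- if (nrow(a)) cigar_ref_span(a$cigar) else integer(0)
  ctg <- a$contig
  starts <- a$pos
  ends <- a$pos + spans - 1L
  w <- rep(1, nrow(a))
  # split halves of ambiguous reads onto the tie locus
  amb <- which(a$ambiguous & !is.na(a$tie_contig))
  if (length(amb)) {
    w[amb] <- 0.5
    ctg <- c(ctg, a$tie_contig[amb])
    starts <- c(starts, a$tie_pos[amb])
    ends <- c(ends, a$tie_pos[amb] + spans[amb] - 1L)
    w <- c(w, rep(0.5, length(amb)))
  }
  out <- vector("list", length(contig_lengths))
  total_aligned <- 0
  for (ci in seq_along(contig_lengths)) {
    cname <- names(contig_lengths)[ci]
    clen <- contig_lengths[[ci]]
    nwin <- ceiling(clen / window)
    sel <- which(ctg == cname)
    if (length(sel)) {
      s <- pmax(1L, pmin(starts[sel], clen))
      e <- pmax(1L, pmin(ends[sel], clen))
      cov <- IRanges::coverage(IRanges::IRanges(s, e), weight = w[sel],
                               width = clen)
      total_aligned <- total_aligned + sum(as.numeric(S4Vectors::runValue(cov)) *
                                             S4Vectors::runLength(cov))
      wstart <- (seq_len(nwin) - 1L) * window + 1L
      wend <- pmin(wstart + window - 1L, clen)
      v <- IRanges::Views(cov, start = wstart, end = wend)
      depth <- IRanges::viewMeans(v)
    } else {
      wstart <- (seq_len(nwin) - 1L) * window + 1L
      wend <- pmin(wstart + window - 1L, clen)
      depth <- rep(0, nwin)
    }
    out[[ci]] <- data.frame(contig = cname, window_index = seq_len(nwin),
                            start = wstart, end = wend, depth = as.numeric(depth),
                            stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  nuclear <- !is_mito_contig(track$contig)
  attr(track, "window") <- as.integer(window)
  attr(track, "genome_median") <- stats::median(track$depth[nuclear])
  attr(track, "total_aligned") <- total_aligned
  attr(track, "contig_lengths") <- contig_lengths
  class(track) <- c("coverage_track", class(track))
  track
}

#' Discordant-pair and split-read evidence
#'
#' Returns structural-variant read evidence: mate pairs on different
#' contigs (`inter_contig`), pairs with |observed insert - mean| > 4 sd
#' (`aberrant_insert`), pairs not in forward-reverse orientation
#' (`aberrant_orientation`), and split-aligned reads (`split_read`) with
#' the junction coordinates of their two segments.
#'
#' @param alignments an `alignments` data.frame (paired).
#' @param insert_mean,insert_sd the library insert-size distribution.
#' @return data.frame with columns read_id, contig1, pos1, strand1,
#'   contig2, pos2, strand2, class, insert.
#' @export
extract_discordant <- function(alignments, insert_mean, insert_sd) {
  a <- alignments
  recs <- list()

  # split reads: end1 = last aligned base of the prefix segment (junction),
  # end2 = first aligned base of the suffix segment
  sp <- a[a$mapped & a$is_split, , drop = FALSE]
  if (nrow(sp)) {
    mlen <- as.integer(sub("M.*$", "", sp$cigar))
    recs[[length(recs) + 1]] <- data.frame(
      read_id = sub("/[12]$", "", sp$read_id),
      contig1 = sp$contig, pos1 = sp$pos + mlen - 1L, strand1 = sp$strand,
      contig2 = sp$split_contig, pos2 = sp$split_pos, strand2 = sp$strand,
      class = "split_read", insert = NA_integer_, stringsAsFactors = FALSE)
  }

  # pair-level classification
  if (any(a$mate > 0)) {
    m1 <- a[a$mate == 1, , drop = FALSE]
    m2 <- a[a$mate == 2, , drop = FALSE]
    ok <- m1$mapped & m2$mapped
    m1 <- m1[ok, , drop = FALSE]; m2 <- m2[ok, , drop = FALSE]
    if (nrow(m1)) {
      span1 <- cigar_ref_span(m1$cigar); span2 <- cigar_ref_span(m2$cigar)
      inter <- m1$contig != m2$contig
      left1 <- m1$pos <= m2$pos
      lo <- ifelse(left1, m1$pos, m2$pos)
      hi <- ifelse(left1, m2$pos + span2 - 1L, m1$pos + span1 - 1L)
      insert <- hi - lo + 1L
      strand_left <- ifelse(left1, m1$strand, m2$strand)
      strand_right <- ifelse(left1, m2$strand, m1$strand)
      proper_orient <- strand_left == "+" & strand_right == "-"
      cls <- rep(NA_character_, nrow(m1))
      cls[!inter & !proper_orient] <- "aberrant_orientation"
      cls[!inter & proper_orient &
            abs(insert - insert_mean) > 4 * insert_sd] <- "aberrant_insert"
      cls[inter] <- "inter_contig"
      keep <- !is.na(cls) & !(m1$is_split | m2$is_split) # splits already recorded
      if (any(keep)) {
        k1 <- m1[keep, , drop = FALSE]; k2 <- m2[keep, , drop = FALSE]
        # innermost coordinates face the junction
        e1 <- ifelse(k1$strand == "+", k1$pos + span1[keep] - 1L, k1$pos)
        e2 <- ifelse(k2$strand == "+", k2$pos + span2[keep] - 1L, k2$pos)
        recs[[length(recs) + 1]] <- data.frame(
          read_id = sub("/[12]$", "", k1$read_id),
          contig1 = k1$contig, pos1 = e1, strand1 = k1$strand,
          contig2 = k2$contig, pos2 = e2, strand2 = k2$strand,
          class = cls[keep], insert = ifelse(inter[keep], NA_integer_,
                                             insert[keep]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(read_id = character(0), contig1 = character(0),
                      pos1 = integer(0), strand1 = character(0),
                      contig2 = character(0), pos2 = integer(0),
                      strand2 = character(0), class = character(0),
                      insert = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  # canonical end order: end1 <= end2 by (contig, pos)
  swap <- out$contig2 < out$contig1 |
    (out$contig2 == out$contig1 & out$pos2 < out$pos1)
  if (any(swap)) {
    tmp <- out[swap, c("contig1", "pos1", "strand1")]
    out[swap, c("contig1", "pos1", "strand1")] <-
      out[swap, c("contig2", "pos2", "strand2")]
    out[swap, c("contig2", "pos2", "strand2")] <- tmp
  }
  rownames(out) <- NULL
  out
}

#' Write / read alignments as SAM
#'
#' Minimal SAM: mandatory columns with basic FLAG semantics (paired,
#' strand, mate strand, first/last-in-pair, unmapped).  Round-trips through
#' [read_sam()] without loss of the mapped coordinates.
#'
#' @param alignments an `alignments` data.frame.
#' @param file output path.
#' @param contig_lengths named vector for the header.
#' @export
write_sam <- function(alignments, file,
                      contig_lengths = attr(alignments, "contig_lengths")) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  a <- alignments
  paired <- a$mate > 0
  flag <- ifelse(paired, 1L, 0L)
  flag <- flag + ifelse(!a$mapped, 4L, 0L)
  flag <- flag + ifelse(a$mapped & a$strand == "-", 16L, 0L)
  flag <- flag + ifelse(paired & !is.na(a$mate_strand) & a$mate_strand == "-", 32L, 0L)
  flag <- flag + ifelse(a$mate == 1, 64L, ifelse(a$mate == 2, 128L, 0L))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
                   sub("/[12]$", "", a$read_id), flag,
                   ifelse(a$mapped, a$contig, "*"),
                   ifelse(a$mapped, a$pos, 0L),
                   ifelse(a$mapped, ifelse(a$ambiguous, 0L, 60L), 0L),
                   ifelse(a$mapped, a$cigar, "*"),
                   ifelse(!is.na(a$mate_contig), a$mate_contig, "*"),
                   ifelse(!is.na(a$mate_pos), a$mate_pos, 0L),
                   a$seq)
  writeLines(c(hdr, lines), file)
  invisible(file)
}

#' @rdname write_sam
#' @export
read_sam <- function(file) {
  ln <- readLines(file)
  hdr <- ln[startsWith(ln, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  contig_lengths <- stats::setNames(
    as.integer(sub("^.*\tLN:", "", sq)),
    sub("\t.*$", "", sub("^@SQ\tSN:", "", sq)))
  body <- ln[!startsWith(ln, "@")]
  f <- strsplit(body, "\t")
  g <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(g(2))
  mate <- ifelse(bitwAnd(flag, 64L) > 0, 1L, ifelse(bitwAnd(flag, 128L) > 0, 2L, 0L))
  mapped <- bitwAnd(flag, 4L) == 0
  aln <- data.frame(
    read_id = ifelse(mate > 0, paste0(g(1), "/", mate), g(1)),
    mate = mate, pair = NA_integer_,
    contig = ifelse(mapped, g(3), NA_character_),
    pos = ifelse(mapped, as.integer(g(4)), NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
                    NA_character_),
    cigar = ifelse(mapped, g(6), NA_character_),
    seq = g(10),
    score = NA_integer_, nm = NA_integer_,
    is_split = FALSE, ambiguous = mapped & as.integer(g(5)) == 0L,
    mapped = mapped,
    split_contig = NA_character_, split_pos = NA_integer_,
    split_len = NA_integer_, tie_contig = NA_character_,
    tie_pos = NA_integer_,
    mate_contig = ifelse(g(7) == "*", NA_character_, g(7)),
    mate_pos = ifelse(g(8) == "0", NA_integer_, as.integer(g(8))),
    mate_strand = ifelse(bitwAnd(flag, 32L) > 0, "-", "+"),
    stringsAsFactors = FALSE)
  attr(aln, "contig_lengths") <- contig_lengths
  class(aln) <- c("alignments", class(aln))
  aln
}

#' Write a coverage track as BED
#'
#' 0-based half-open windows, score column = mean depth.
#' @param track a `coverage_track`.
#' @param file output path.
#' @export
write_coverage_bed <- function(track, file) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.4f", track$contig, track$start - 1L,
                     track$end, paste0("win", track$window_index), track$depth),
             file)
  invisible(file)
}
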