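#' Segment a coverage track into integer copy-number segments
#'
#' Recursive binary segmentation of the per-window copy ratio
#' (depth / genome median).  Within each segment the split point
#' minimizing the residual sum of squares is found; the split is accepted
#' when the local mean shift at the boundary (means over the
#' `min_windows` windows on each side) exceeds `min_shift` copy-ratio
#' units and both parts span at least `min_windows` windows.  The copy
#' number of a segment is the rounded mean ratio; baseline is 1 per
#' homeologous chromosome (an allodiploid carries one copy of each
#' subgenome), so a duplicated segment has copy number 2 and a lost
#' segment 0.
#'
#' @param track a `coverage_track` (windows of one or more contigs).
#' @param genome_median genome-wide median window depth (> 0); defaults to
#'   the value recorded on the track.
#' @param min_shift minimum copy-ratio shift at a boundary (default 0.5).
#' @param min_windows minimum windows per segment (default 3).
#' @return data.frame of class `copy_segments`: contig, start, end,
#'   n_windows, mean_ratio, copy_number.  Segments tile each contig.
#' @export
segment_coverage <- function(track, genome_median = attr(track, "genome_median"),
                             min_shift = 0.5, min_windows = 3L) {
  stopifnot(!is.null(genome_median), genome_median > 0)
  out <- list()
  for (ctg in unique(track$contig)) {
    tw <- track[track$contig == ctg, , drop = FALSE]
    ratio <- tw$depth / genome_median
    bounds <- segment_ratio(ratio, min_shift, min_windows)
    seg_start <- c(1L, bounds + 1L)
    seg_end <- c(bounds, length(ratio))
    mr <- vapply(seq_along(seg_start),
                 function(i) mean(ratio[seg_start[i]:seg_end[i]]), numeric(1))
    out[[length(out) + 1]] <- data.frame(
      contig = ctg, start = tw$start[seg_start], end = tw$end[seg_end],
      n_windows = seg_end - seg_start + 1L, mean_ratio = mr,
      copy_number = pmax(0L, as.integer(round(mr))),
      stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  attr(segs, "window") <- attr(track, "window")
  attr(segs, "genome_median") <- genome_median
  attr(segs, "contig_lengths") <- attr(track, "contig_lengths")
  class(segs) <- c("copy_segments", class(segs))
  segs
}

# returns sorted split indices b (segments are [..b], [b+1..]) found by
# recursive RSS-optimal binary splitting with a local mean-shift test
segment_ratio <- function(r, min_shift, min_windows) {
  n <- length(r)
  recurse <- function(i, j) {
    len <- j - i + 1L
    if (len < 2 * min_windows) return(integer(0))
    x <- r[i:j]
    cs <- cumsum(x); tot <- cs[len]
    ks <- seq.int(min_windows, len - min_windows)
    # RSS reduction is maximized by maximizing weighted mean difference
    ml <- cs[ks] / ks
    mr <- (tot - cs[ks]) / (len - ks)
    stat <- (ml - mr)^2 * ks * (len - ks) / len
    k <- ks[which.max(stat)]
    # local shift at the chosen boundary
    left_loc <- mean(x[(k - min_windows + 1):k])
    right_loc <- mean(x[(k + 1):(k + min_windows)])
    if (abs(left_loc - right_loc) <= min_shift) return(integer(0))
    b <- i + k - 1L
    sort(c(recurse(i, b), b, recurse(b + 1L, j)))
  }
  recurse(1L, n)
}

#' Classify copy-number events from segments
#'
#' Whole-contig copy number 2 / 0 become CHR_GAIN / CHR_LOSS; partial
#' segments become SEG_DUP / SEG_DEL.  A deletion whose homeologous
#' corresponding interval on the partner chromosome is duplicated is
#' merged into a single LOH_SUBST (loss of heterozygosity: the acceptor
#' allele is replaced by a second copy of the donor allele, conserving
#' total copy number).  Event boundaries are reported by the nearest
#' flanking or containing ORF; boundaries within one window of a contig
#' end use the `"end"` sentinel.
#'
#' @param segments `copy_segments` from [segment_coverage()].
#' @param homeology_map data.frame pairing homeologous contigs
#'   (`contig_a`, `contig_b`; coordinates correspond 1:1).
#' @param orfs ORF annotation data.frame used to name boundaries.
#' @return data.frame of class `copy_events`: kind, contig, start, end,
#'   copy_number, donor fields, boundary genes, nomenclature.
#' @export
classify_events <- function(segments, homeology_map, orfs = NULL) {
  segs <- segments[!is_mito_contig(segments$contig), , drop = FALSE]
  lens <- attr(segments, "contig_lengths")
  window <- attr(segments, "window") %||% 1000L
  for (ctg in unique(segs$contig)) {
    inmap <- ctg %in% homeology_map$contig_a | ctg %in% homeology_map$contig_b
    if (!inmap) stop("contig ", ctg, " missing from homeology_map")
  }
  partner <- function(ctg) {
    i <- match(ctg, homeology_map$contig_a)
    if (!is.na(i)) return(homeology_map$contig_b[i])
    homeology_map$contig_a[match(ctg, homeology_map$contig_b)]
  }

  ev <- list()
  whole <- list()
  for (ctg in unique(segs$contig)) {
    s <- segs[segs$contig == ctg, , drop = FALSE]
    if (nrow(s) == 1 && s$copy_number != 1) {
      whole[[ctg]] <- s$copy_number
    }
  }
  used_whole <- character(0)
  for (ctg in names(whole)) {
    if (ctg %in% used_whole) next
    p <- partner(ctg)
    if (whole[[ctg]] == 0 && !is.null(whole[[p]]) && whole[[p]] >= 2) {
      ev[[length(ev) + 1]] <- data.frame(
        kind = "LOH_SUBST", scope = "chromosome", contig = ctg, start = 1L,
        end = lens[[ctg]], copy_number = 0L, donor_contig = p,
        donor_start = 1L, donor_end = lens[[p]],
        boundary_gene1 = "end", boundary_gene2 = "end",
        stringsAsFactors = FALSE)
      used_whole <- c(used_whole, ctg, p)
    }
  }
  for (ctg in names(whole)) {
    if (ctg %in% used_whole) next
    kind <- if (whole[[ctg]] >= 2) "CHR_GAIN" else "CHR_LOSS"
    ev[[length(ev) + 1]] <- data.frame(
      kind = kind, scope = "chromosome", contig = ctg, start = 1L,
      end = lens[[ctg]], copy_number = whole[[ctg]],
      donor_contig = NA_character_, donor_start = NA_integer_,
      donor_end = NA_integer_, boundary_gene1 = "end",
      boundary_gene2 = "end", stringsAsFactors = FALSE)
  }

  # partial segments
  part <- segs[!(segs$contig %in% names(whole)), , drop = FALSE]
  dels <- part[part$copy_number == 0, , drop = FALSE]
  dups <- part[part$copy_number >= 2, , drop = FALSE]
  dup_used <- rep(FALSE, nrow(dups))
  for (r in seq_len(nrow(dels))) {
    p <- partner(dels$contig[r])
    cand <- which(!dup_used & dups$contig == p &
                    dups$start <= dels$end[r] + window &
                    dups$end >= dels$start[r] - window)
    if (length(cand)) {
      # reciprocal overlap of corresponding coordinates
      j <- cand[1]
      ov <- min(dels$end[r], dups$end[j]) - max(dels$start[r], dups$start[j]) + 1
      if (ov >= 0.5 * max(dels$end[r] - dels$start[r] + 1,
                          dups$end[j] - dups$start[j] + 1)) {
        dup_used[j] <- TRUE
        ev[[length(ev) + 1]] <- data.frame(
          kind = "LOH_SUBST", scope = "segment", contig = dels$contig[r],
          start = dels$start[r], end = dels$end[r], copy_number = 0L,
          donor_contig = p, donor_start = dups$start[j],
          donor_end = dups$end[j], boundary_gene1 = NA_character_,
          boundary_gene2 = NA_character_, stringsAsFactors = FALSE)
        next
      }
    }
    ev[[length(ev) + 1]] <- data.frame(
      kind = "SEG_DEL", scope = "segment", contig = dels$contig[r],
      start = dels$start[r], end = dels$end[r], copy_number = 0L,
      donor_contig = NA_character_, donor_start = NA_integer_,
      donor_end = NA_integer_, boundary_gene1 = NA_character_,
      boundary_gene2 = NA_character_, stringsAsFactors = FALSE)
  }
  for (j in which(!dup_used)) {
    ev[[length(ev) + 1]] <- data.frame(
      kind = "SEG_DUP", scope = "segment", contig = dups$contig[j],
      start = dups$start[j], end = dups$end[j],
      copy_number = dups$copy_number[j], donor_contig = NA_character_,
      donor_start = NA_integer_, donor_end = NA_integer_,
      boundary_gene1 = NA_character_, boundary_gene2 = NA_character_,
      stringsAsFactors = FALSE)
  }

  if (!length(ev)) {
    out <- data.frame(kind = character(0), scope = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), copy_number = integer(0),
                      donor_contig = character(0), donor_start = integer(0),
                      donor_end = integer(0), boundary_gene1 = character(0),
                      boundary_gene2 = character(0),
                      nomenclature = character(0), stringsAsFactors = FALSE)
    class(out) <- c("copy_events", class(out))
    return(out)
  }
  out <- do.call(rbind, ev)
  # name segment boundaries by flanking/containing ORFs
  for (r in which(out$scope == "segment")) {
    out$boundary_gene1[r] <- boundary_gene(out$contig[r], out$start[r],
                                           orfs, lens, window)
    out$boundary_gene2[r] <- boundary_gene(out$contig[r], out$end[r],
                                           orfs, lens, window)
  }
  out$nomenclature <- vapply(seq_len(nrow(out)),
                             function(r) format_nomenclature(out[r, ]),
                             character(1))
  rownames(out) <- NULL
  attr(out, "window") <- window
  class(out) <- c("copy_events", class(out))
  out
}

# name a boundary coordinate: containing ORF, else nearest ORF, else "end"
boundary_gene <- function(contig, pos, orfs, lens, window) {
  clen <- if (!is.null(lens) && contig %in% names(lens)) lens[[contig]] else NA
  if (!is.na(clen) && (pos <= window || pos > clen - window)) return("end")
  if (is.null(orfs)) return(sprintf("%s:%d", contig, pos))
  o <- orfs[orfs$contig == contig, , drop = FALSE]
  if (!nrow(o)) return(sprintf("%s:%d", contig, pos))
  inside <- which(pos >= o$start & pos <= o$end)
  if (length(inside)) return(o$orf_id[inside[1]])
  d <- pmin(abs(o$start - pos), abs(o$end - pos))
  o$orf_id[which.min(d)]
}

#' Mitochondrial-genome status
#'
#' Classifies the isolate's mitochondrial DNA from read coverage of the
#' mitochondrial contigs: covered fraction below `full_thresh` is complete
#' loss (rho-minus), between `full_thresh` and `partial_thresh` partial
#' loss (rho-zero), otherwise present.  With two candidate mitochondrial
#' contigs in the reference (one per parent), the carried genome is the
#' one with the highest covered fraction.
#'
#' @param track a `coverage_track` including mitochondrial contigs.
#' @param mito_contigs names of mitochondrial contigs; default all
#'   contigs matching `"_MT$"`.
#' @param full_thresh,partial_thresh covered-fraction thresholds.
#' @param isolate_id optional label.
#' @return One-row data.frame: isolate_id, status (present /
#'   partial_loss / full_loss), covered_fraction, mito_contig.
#' @export
classify_mito <- function(track, mito_contigs = NULL, full_thresh = 0.05,
                          partial_thresh = 0.8, isolate_id = NA_character_) {
  if (is.null(mito_contigs))
    mito_contigs <- unique(track$contig[is_mito_contig(track$contig)])
  if (!length(mito_contigs)) stop("no mitochondrial contigs identified")
  frac <- vapply(mito_contigs, function(ctg) {
    tw <- track[track$contig == ctg, , drop = FALSE]
    if (!nrow(tw)) return(0)
    wlen <- tw$end - tw$start + 1
    sum(wlen[tw$depth >= 1]) / sum(wlen)
  }, numeric(1))
  best <- which.max(frac)
  cf <- frac[best]
  status <- if (cf < full_thresh) "full_loss"
  else if (cf < partial_thresh) "partial_loss" else "present"
  data.frame(isolate_id = isolate_id, status = status,
             covered_fraction = unname(cf),
             mito_contig = mito_contigs[best], stringsAsFactors = FALSE)
}

#' Copy-number event nomenclature
#'
#' Grammar used in evolved-isolate tables: `"Δ"` marks a deletion,
#' `"2x"` a duplication, and `"::"` a substitution of the acceptor locus
#' by the donor locus.  A locus is either a chromosome label
#' (`2xA(CHRVIII)`) or a pair of boundary genes
#' (`ΔA(g003-g004)`, with `end` as the contig-end sentinel).
#' `parse_nomenclature()` is the exact inverse on this grammar.
#'
#' @param event one-row data.frame from [classify_events()] (or a list
#'   with the same fields).
#' @return A nomenclature string.
#' @export
format_nomenclature <- function(event) {
  tag <- function(ctg) split_contig_name(ctg)$tag
  lab <- function(ctg) split_contig_name(ctg)$label
  if (identical(event$scope, "chromosome")) {
    if (event$kind == "CHR_GAIN")
      return(paste0("2x", tag(event$contig), "(", lab(event$contig), ")"))
    if (event$kind == "CHR_LOSS")
      return(paste0("Δ", tag(event$contig), "(", lab(event$contig), ")"))
    # whole-chromosome LOH
    return(paste0("Δ", tag(event$contig), "::", tag(event$donor_contig),
                  "(", lab(event$contig), ")"))
  }
  loci <- paste0("(", event$boundary_gene1, "-", event$boundary_gene2, ")")
  if (event$kind == "SEG_DEL")
    return(paste0("Δ", tag(event$contig), loci))
  if (event$kind == "SEG_DUP")
    return(paste0("2x", tag(event$contig), loci))
  # segmental LOH: acceptor deleted, donor copy gained over the same span
  paste0("Δ", tag(event$contig), "::", tag(event$donor_contig), loci)
}

#' @rdname format_nomenclature
#' @param text a nomenclature string.
#' @export
parse_nomenclature <- function(text) {
  # composite replacement with two explicit locus groups
  m <- regmatches(text, regexec(
    "^Δ([^:()]+)\\(([^()-]+)-([^()-]+)\\)::([^:()]+)\\(([^()-]+)-([^()-]+)\\)$",
    text))[[1]]
  if (length(m) == 7) {
    return(list(kind = "LOH_SUBST", scope = "segment", composite = TRUE,
                acceptor_tag = m[2], boundary_gene1 = m[3],
                boundary_gene2 = m[4], donor_tag = m[5],
                donor_gene1 = m[6], donor_gene2 = m[7]))
  }
  m <- regmatches(text, regexec(
    "^(Δ|2x)([^:()]+)(::([^:()]+))?\\(([^()]+)\\)$", text))[[1]]
  if (!length(m)) {
    # locate first offending character for the error message
    ok <- regexpr("^(Δ|2x)[^:()]+", text)
    stop("cannot parse nomenclature at position ",
         if (ok > 0) attr(ok, "match.length") + 1 else 1, ": ", text)
  }
  prefix <- m[2]; acceptor <- m[3]; donor <- m[5]; body <- m[6]
  subst <- nzchar(donor)
  if (grepl("-", body)) {
    genes <- strsplit(body, "-", fixed = TRUE)[[1]]
    if (length(genes) != 2)
      stop("cannot parse nomenclature locus body: ", body)
    kind <- if (subst) "LOH_SUBST" else if (prefix == "2x") "SEG_DUP" else "SEG_DEL"
    return(list(kind = kind, scope = "segment", composite = FALSE,
                acceptor_tag = acceptor, boundary_gene1 = genes[1],
                boundary_gene2 = genes[2],
                donor_tag = if (subst) donor else NA_character_))
  }
  kind <- if (subst) "LOH_SUBST" else if (prefix == "2x") "CHR_GAIN" else "CHR_LOSS"
  list(kind = kind, scope = "chromosome", composite = FALSE,
       acceptor_tag = acceptor, chromosome = body,
       donor_tag = if (subst) donor else NA_character_)
}

#' Write copy segments as BED
#'
#' 0-based half-open, score column = integer copy number.
#' @param segments `copy_segments`.
#' @param file path.
#' @export
write_segments_bed <- function(segments, file) {
  writeLines(sprintf("%s\t%d\t%d\tseg\t%d", segments$contig,
                     segments$start - 1L, segments$end, segments$copy_number),
             file)
  invisible(file)
}
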