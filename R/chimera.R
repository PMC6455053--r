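#' Extract reads local to a recombination site
#'
#' All read pairs with an alignment start within `window` bp of either
#' junction locus, plus their mates regardless of where the mate maps --
#' the read set used for local assembly of the recombined allele.
#'
#' @param alignments isolate `alignments`.
#' @param site list or one-row data.frame with contig1, pos1, contig2,
#'   pos2 (a retained breakpoint candidate).
#' @param reads the `read_set` the alignments came from.
#' @param window locality window in bp (default 3000).
#' @return Subset of `reads` (pairs; both mates included by the mate rule).
#' @export
extract_local_reads <- function(alignments, site, reads, window = 3000L) {
  a <- alignments[alignments$mapped, , drop = FALSE]
  near <- (a$contig == site$contig1 & abs(a$pos - site$pos1) <= window) |
    (a$contig == site$contig2 & abs(a$pos - site$pos2) <= window)
  ids <- unique(sub("/[12]$", "", a$read_id[near]))
  out <- reads[reads$read_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy overlap-layout-consensus local assembly
#'
#' Deterministic greedy assembly of a small local read set: reads (and
#' their reverse complements) are deduplicated and sorted, contigs grow by
#' repeatedly appending the read with the longest suffix-prefix overlap
#' (minimum `min_overlap` bp at `min_identity` or better), and the result
#' is reported in a canonical orientation.  Suited to clonal, high-depth
#' local data; not a general-purpose assembler.
#'
#' @param reads a `read_set` subset (or character vector of sequences).
#' @param min_reads minimum number of read pairs required (default 10).
#' @param min_overlap minimum overlap length in bp.
#' @param min_identity minimum overlap identity.
#' @param min_contig minimum contig length to report.
#' @return list with `status` ("ok" or "assembly failed") and `contigs`
#'   (character vector, longest first).
#' @export
assemble_local <- function(reads, min_reads = 10L, min_overlap = 30L,
                           min_identity = 0.95, min_contig = 200L) {
  seqs <- if (is.character(reads)) reads else c(reads$seq1, reads$seq2)
  n_units <- if (is.character(reads)) length(reads) else nrow(reads)
  if (n_units < min_reads)
    stop("assembly requires at least ", min_reads, " reads (got ", n_units, ")")
  contigs <- cpp_assemble(seqs, as.integer(min_overlap), min_identity,
                          as.integer(min_contig))
  if (!length(contigs)) {
    return(list(status = "assembly failed", contigs = character(0)))
  }
  list(status = "ok", contigs = as.character(contigs))
}

# global alignment of an ORF pair with the homology scoring scheme
# (match +1, mismatch -1, gap -2 per base)
align_orf_pair <- function(orf1, orf2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(orf1),
                                      Biostrings::DNAString(orf2),
                                      type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 2)
  list(aligned1 = as.character(Biostrings::alignedPattern(pa)),
       aligned2 = as.character(Biostrings::alignedSubject(pa)),
       nmatch = Biostrings::nmatch(pa),
       width = nchar(as.character(Biostrings::alignedPattern(pa))))
}

#' Percent identity of two ORFs under global alignment
#'
#' Global alignment (match +1, mismatch -1, gap -2); identity is matching
#' columns over total alignment columns, in percent rounded to 2 decimals.
#' Homologies below 70 percent are conventionally reported as the
#' category `"<70"` in summary tables (see [format_homology()]).
#'
#' @param orf1,orf2 nucleotide sequences.
#' @return Numeric percentage.
#' @export
homology_percent <- function(orf1, orf2) {
  stopifnot(nzchar(orf1), nzchar(orf2))
  al <- align_orf_pair(orf1, orf2)
  round(100 * al$nmatch / al$width, 2)
}

#' @rdname homology_percent
#' @param h numeric homology percentage.
#' @export
format_homology <- function(h) {
  ifelse(h < 70, "<70", sprintf("%.2f%%", h))
}

#' Locate the breakpoint ambiguity interval between two homologous ORFs
#'
#' Given an assembled contig spanning a recombination junction, finds the
#' transition from orf1-matching to orf2-matching sequence and reports the
#' breakpoint ambiguity interval: the maximal run of columns of the
#' orf1/orf2 global alignment around the junction in which the two ORFs
#' are identical, expressed in each ORF's own 1-based coordinates.  Any
#' crossover within this run yields the same chimeric sequence, so the
#' true breakpoint cannot be resolved further; the interval width is the
#' attainable resolution and shrinks as local homology decreases.
#'
#' @param contig assembled junction contig sequence.
#' @param orf1_seq the ORF contributing the chimera prefix.
#' @param orf2_seq the ORF contributing the chimera suffix.
#' @return list of class `breakpoint_interval` with a1, b1 (orf1 range),
#'   a2, b2 (orf2 range), width, and the observed junction coordinates
#'   `prefix_end` / `suffix_start`; or a list with `status = "no junction"`.
#' @export
locate_interval <- function(contig, orf1_seq, orf2_seq) {
  L1 <- nchar(orf1_seq); L2 <- nchar(orf2_seq)
  anchor_len <- min(30L, max(6L, min(L1, L2) %/% 3L))

  orient <- find_orf_prefix(contig, orf1_seq, anchor_len)
  if (is.null(orient)) return(list(status = "no junction"))
  contig <- orient$contig
  b1 <- orient$matched  # last orf1 position supported by the contig
  p_end <- orient$at + b1 - 1L  # contig position of that base

  if (b1 >= L1) {
    # the whole of orf1 is present: a junction exists only in the
    # fully-identical-pair case, where the ambiguity spans the entire ORF
    if (identical(orf1_seq, orf2_seq)) {
      return(structure(list(a1 = 1L, b1 = L1, a2 = 1L, b2 = L2, width = L1,
                            prefix_end = b1, status = "ok"),
                       class = "breakpoint_interval"))
    }
    return(list(status = "no junction"))
  }

  # a junction claim needs the contig to continue past the matched prefix;
  # a contig that merely ends inside orf1 is truncation, not recombination
  if (nchar(contig) - p_end < 5) return(list(status = "no junction"))

  al <- align_orf_pair(orf1_seq, orf2_seq)
  runs <- cpp_identical_runs(al$aligned1, al$aligned2)
  if (!length(runs$orf1_start)) return(list(status = "no junction"))
  hit <- which(runs$orf1_start <= b1 & runs$orf1_end >= b1)
  if (!length(hit)) {
    before <- which(runs$orf1_end <= b1)
    if (!length(before)) return(list(status = "no junction"))
    hit <- before[which.max(runs$orf1_end[before])]
  } else {
    hit <- hit[1]
  }
  a1 <- runs$orf1_start[hit]; rb1 <- runs$orf1_end[hit]
  a2 <- runs$orf2_start[hit]; b2 <- runs$orf2_end[hit]

  # a real junction continues with orf2 sequence after the identical run
  cont_from <- p_end + 1L
  n_check <- min(anchor_len, nchar(contig) - cont_from + 1L, L2 - b2)
  if (n_check >= 5) {
    cont_contig <- substr(contig, cont_from, cont_from + n_check - 1L)
    cont_orf2 <- substr(orf2_seq, b2 + 1L, b2 + n_check)
    d <- sum(strsplit(cont_contig, "")[[1]] != strsplit(cont_orf2, "")[[1]])
    if (d > max(1, 0.1 * n_check)) return(list(status = "no junction"))
  }
  structure(list(a1 = a1, b1 = rb1, a2 = a2, b2 = b2,
                 width = rb1 - a1 + 1L, prefix_end = b1, status = "ok"),
            class = "breakpoint_interval")
}

# locate orf start in contig (either orientation) and extend the exact
# match; returns reoriented contig and matched prefix length
find_orf_prefix <- function(contig, orf, anchor_len) {
  anchor <- substr(orf, 1, anchor_len)
  for (ori in 1:2) {
    cand <- if (ori == 1) contig else rc(contig)
    p <- regexpr(anchor, cand, fixed = TRUE)[1]
    if (p > 0) {
      avail <- nchar(cand) - p + 1L
      n <- min(nchar(orf), avail)
      o <- substr(orf, 1, n)
      cc <- substr(cand, p, p + n - 1L)
      d <- which(strsplit(o, "")[[1]] != strsplit(cc, "")[[1]])
      matched <- if (length(d)) d[1] - 1L else n
      if (matched >= anchor_len)
        return(list(contig = cand, matched = matched, at = p))
    }
  }
  NULL
}

#' Reconstruct a chimeric ORF from its parents and breakpoint interval
#'
#' The chimera is the orf1 prefix through the interval start joined to
#' orf2 resuming immediately after the corresponding interval-start
#' position: `orf1[1..a1] + orf2[(a2+1)..len2]`.  Because every column of
#' the interval is identical between the parents, any crossover inside
#' the interval yields this same sequence.  Frame and stop-codon
#' consequences and parental homology are reported alongside.
#'
#' @param orf1_seq,orf2_seq parental ORF sequences.
#' @param interval a `breakpoint_interval` from [locate_interval()] (or a
#'   list with a1/a2).
#' @param codon_table genetic code for stop-codon analysis.
#' @return list of class `chimera_result`: chimera_sequence,
#'   chimera_length, in_frame, premature_stop, homology_percent, interval.
#' @export
reconstruct_chimera <- function(orf1_seq, orf2_seq, interval,
                                codon_table = Biostrings::GENETIC_CODE) {
  a1 <- interval$a1; a2 <- interval$a2
  L2 <- nchar(orf2_seq)
  if (is.null(a1) || is.null(a2) || a1 < 1 || a1 > nchar(orf1_seq) ||
      a2 < 1 || a2 > L2)
    stop("interval inconsistent with the parental sequences")
  if (substr(orf1_seq, a1, a1) != substr(orf2_seq, a2, a2))
    stop("interval inconsistent: parents differ at the interval start")
  chim <- paste0(substr(orf1_seq, 1, a1),
                 if (a2 < L2) substr(orf2_seq, a2 + 1L, L2) else "")
  fr <- analyze_frame(chim, codon_table)
  structure(list(chimera_sequence = chim, chimera_length = nchar(chim),
                 in_frame = fr$in_frame, premature_stop = fr$premature_stop,
                 homology_percent = homology_percent(orf1_seq, orf2_seq),
                 interval = interval),
            class = "chimera_result")
}

#' Chimeric ORF length from printed breakpoint-interval coordinates
#'
#' Summary tables of recombined ORFs print, for each locus, the length
#' and the breakpoint-interval coordinate range; the recombined ORF
#' length follows from the geometry of joining locus 1 through its
#' printed interval start to locus 2 from its printed interval start
#' onward: `a1 + len2 - a2 + 1`.  This is the arithmetic used to check
#' table self-consistency; it operates on the printed coordinate
#' convention, in which the locus-2 range is the position at which the
#' donor sequence resumes.
#'
#' @param prefix_interval_start interval start in locus 1 (a1).
#' @param suffix_length length of locus 2 in bp.
#' @param suffix_interval_start interval start in locus 2 (a2).
#' @return Chimera length in bp.
#' @export
chimera_length_closed_form <- function(prefix_interval_start, suffix_length,
                                       suffix_interval_start) {
  prefix_interval_start + suffix_length - suffix_interval_start + 1
}

#' Frame and stop-codon analysis of a chimeric ORF
#'
#' @param sequence nucleotide sequence beginning with a start codon.
#' @param codon_table genetic code.
#' @return list(in_frame, premature_stop): in_frame iff the length is a
#'   multiple of 3; premature_stop iff any frame-0 stop codon occurs
#'   before the final codon.
#' @export
analyze_frame <- function(sequence, codon_table = Biostrings::GENETIC_CODE) {
  if (substr(sequence, 1, 3) != "ATG")
    stop("sequence does not start with a start codon")
  L <- nchar(sequence)
  in_frame <- L %% 3 == 0
  n_cod <- L %/% 3
  stops <- integer(0)
  if (n_cod >= 1) {
    starts <- seq(1, by = 3, length.out = n_cod)
    cods <- substring(sequence, starts, starts + 2)
    stops <- which(cods %in% STOP_CODONS)
  }
  # the terminal stop of an in-frame ORF is not premature
  premature <- if (in_frame) any(stops < n_cod) else length(stops) > 0
  list(in_frame = in_frame, premature_stop = premature)
}

#' Reconstruct the chimeric ORF at a retained breakpoint candidate
#'
#' End-to-end helper: extracts reads within `window` of the junction
#' (plus mates), assembles them, identifies the affected homeologous ORF
#' pair from the candidate loci, locates the breakpoint ambiguity
#' interval and reconstructs the chimera.
#'
#' @param candidate one-row retained `breakpoint_candidates`.
#' @param alignments,reads isolate alignments and reads.
#' @param reference output of [build_reference()] (provides homolog ORFs).
#' @param window read-extraction window (default 3000 bp).
#' @return A `chimera_result`, or a list with `status` describing why no
#'   chimera could be reconstructed.
#' @export
call_chimera <- function(candidate, alignments, reads, reference,
                         window = 3000L) {
  h <- reference$homologs
  if (is.null(h)) return(list(status = "no ORF annotation"))
  find_orf <- function(ctg, pos) {
    ia <- which(h$contig_a == ctg & pos >= h$start_a - window / 2 &
                  pos <= h$end_a + window / 2)
    ib <- which(h$contig_b == ctg & pos >= h$start_b - window / 2 &
                  pos <= h$end_b + window / 2)
    if (length(ia)) list(pair = ia[1], side = "a")
    else if (length(ib)) list(pair = ib[1], side = "b")
    else NULL
  }
  o1 <- find_orf(candidate$contig1, candidate$pos1)
  o2 <- find_orf(candidate$contig2, candidate$pos2)
  if (is.null(o1) || is.null(o2) || o1$pair != o2$pair)
    return(list(status = "junction not within a homeologous ORF pair"))
  pair <- h[o1$pair, ]
  # acceptor (prefix) side: locus1 of the candidate
  orf_acc <- orf_sequence(reference$sequences, data.frame(
    contig = if (o1$side == "a") pair$contig_a else pair$contig_b,
    start = if (o1$side == "a") pair$start_a else pair$start_b,
    end = if (o1$side == "a") pair$end_a else pair$end_b,
    strand = "+"))
  orf_don <- orf_sequence(reference$sequences, data.frame(
    contig = if (o2$side == "a") pair$contig_a else pair$contig_b,
    start = if (o2$side == "a") pair$start_a else pair$start_b,
    end = if (o2$side == "a") pair$end_a else pair$end_b,
    strand = "+"))
  local <- extract_local_reads(alignments, candidate, reads, window)
  if (nrow(local) < 10) return(list(status = "insufficient local reads"))
  asm <- assemble_local(local)
  if (asm$status != "ok") return(list(status = asm$status))
  for (ctg in asm$contigs) {
    iv <- locate_interval(ctg, orf_acc, orf_don)
    if (identical(iv$status, "ok")) {
      res <- reconstruct_chimera(orf_acc, orf_don, iv)
      res$gene_id <- pair$gene_id
      res$assembled_contig <- ctg
      return(res)
    }
    # junction may run donor-to-acceptor relative to the candidate order
    iv <- locate_interval(ctg, orf_don, orf_acc)
    if (identical(iv$status, "ok")) {
      res <- reconstruct_chimera(orf_don, orf_acc, iv)
      res$gene_id <- pair$gene_id
      res$assembled_contig <- ctg
      return(res)
    }
  }
  list(status = "no junction")
}
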