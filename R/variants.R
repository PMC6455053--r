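#' Call SNPs and INDELs from read pileups
#'
#' Per-position allele counts are accumulated from CIGAR-projected reads;
#' a SNP is called where the strongest non-reference base reaches
#' `min_alt_fraction` of the base-call depth at `min_depth` or more.
#' INDELs are called from gapped alignments under the same support rule,
#' left-aligned to a normalized representation.  Defaults (fraction 0.8,
#' depth 10) reflect clonal single-colony isolates in which real variants
#' are near-fixed.  Multi-allelic positions report the highest-fraction
#' alternative only.
#'
#' @param alignments an `alignments` data.frame.
#' @param reference named DNAStringSet / character vector the reads were
#'   mapped against (same contigs as the index).
#' @param min_depth minimum base-call depth (>= 4).
#' @param min_alt_fraction minimum alternative-allele fraction in (0, 1].
#' @return data.frame of class `variant_calls`: contig, pos, ref, alt,
#'   depth, alt_count, alt_fraction, kind.
#' @export
call_pileup <- function(alignments, reference, min_depth = 10L,
                        min_alt_fraction = 0.8) {
  stopifnot(min_depth >= 4, min_alt_fraction > 0, min_alt_fraction <= 1)
  seqs <- if (is.list(reference) && !is.null(reference$sequences))
    reference$sequences else reference
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  pl <- pileup_counts(alignments, seqs)
  calls <- list()

  for (ci in seq_along(seqs)) {
    counts <- pl$counts[[ci]]              # 4 x L
    L <- ncol(counts)
    if (!L) next
    depth <- colSums(counts)
    refc <- strsplit(seqs[[ci]], "")[[1]]
    ref_idx <- match(refc, BASES)
    m <- t(counts)
    valid <- !is.na(ref_idx)
    m[cbind(which(valid), ref_idx[valid])] <- -1L
    alt_idx <- max.col(m, ties.method = "first")
    alt_count <- m[cbind(seq_len(L), alt_idx)]
    af <- ifelse(depth > 0, alt_count / depth, 0)
    hit <- which(valid & depth >= min_depth & alt_count > 0 &
                   af >= min_alt_fraction)
    if (length(hit)) {
      calls[[length(calls) + 1]] <- data.frame(
        contig = names(seqs)[ci], pos = hit, ref = refc[hit],
        alt = BASES[alt_idx[hit]], depth = depth[hit],
        alt_count = alt_count[hit], alt_fraction = af[hit], kind = "SNP",
        stringsAsFactors = FALSE)
    }
  }

  # INDELs from gapped-alignment evidence
  if (length(pl$indel$kind)) {
    ind <- pl$indel
    for (r in seq_along(ind$kind)) {
      ctg <- names(seqs)[ind$contig[r]]
      anchor <- as.integer(ind$pos_before[r])  # last unchanged base, 1-based
      if (anchor < 1) next
      counts <- pl$counts[[ind$contig[r]]]
      depth <- sum(counts[, anchor])
      if (depth < min_depth) next
      af <- ind$count[r] / depth
      if (af < min_alt_fraction) next
      s <- seqs[[ctg]]
      if (ind$kind[r] == "D") {
        dlen <- as.integer(ind$alt[r])
        norm <- left_align_indel(s, anchor, deleted_len = dlen)
        refa <- substr(s, norm$anchor, norm$anchor + dlen)
        alta <- substr(s, norm$anchor, norm$anchor)
      } else {
        norm <- left_align_indel(s, anchor, inserted = ind$alt[r])
        refa <- substr(s, norm$anchor, norm$anchor)
        alta <- paste0(refa, norm$inserted)
      }
      calls[[length(calls) + 1]] <- data.frame(
        contig = ctg, pos = norm$anchor, ref = refa, alt = alta,
        depth = depth, alt_count = ind$count[r], alt_fraction = af,
        kind = "INDEL", stringsAsFactors = FALSE)
    }
  }

  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), depth = numeric(0), alt_count = numeric(0),
               alt_fraction = numeric(0), kind = character(0),
               stringsAsFactors = FALSE)
  # merge duplicate indel representations normalized to the same site
  if (nrow(out)) {
    key <- paste(out$contig, out$pos, out$ref, out$alt)
    if (anyDuplicated(key)) {
      agg <- tapply(out$alt_count, key, sum)
      out <- out[!duplicated(key), , drop = FALSE]
      out$alt_count <- as.numeric(agg[paste(out$contig, out$pos, out$ref, out$alt)])
      out$alt_fraction <- pmin(1, out$alt_count / out$depth)
    }
    out <- out[order(out$contig, out$pos), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "reference_contigs") <- names(seqs)
  attr(out, "min_depth") <- min_depth
  class(out) <- c("variant_calls", class(out))
  out
}

pileup_counts <- function(alignments, seqs) {
  a <- alignments[alignments$mapped & !is.na(alignments$contig), , drop = FALSE]
  cidx <- match(a$contig, names(seqs))
  pl <- cpp_pileup(cidx, a$pos, a$cigar, a$seq,
                   as.integer(nchar(seqs)))
  list(counts = pl$counts,
       indel = list(kind = pl$indel_kind, contig = pl$indel_contig,
                    pos_before = pl$indel_pos_before, alt = pl$indel_alt,
                    count = pl$indel_count))
}

# canonical left-aligned representation of an indel
left_align_indel <- function(seq, anchor, deleted_len = NULL, inserted = NULL) {
  if (!is.null(deleted_len)) {
    # deletion of seq[(anchor+1)..(anchor+d)]
    d <- deleted_len
    while (anchor >= 1 &&
           substr(seq, anchor, anchor) == substr(seq, anchor + d, anchor + d)) {
      anchor <- anchor - 1L
    }
    anchor <- max(anchor, 1L)
    list(anchor = anchor)
  } else {
    ins <- inserted
    while (anchor >= 1 &&
           substr(seq, anchor, anchor) == substr(ins, nchar(ins), nchar(ins))) {
      ins <- paste0(substr(ins, nchar(ins), nchar(ins)),
                    substr(ins, 1, nchar(ins) - 1))
      anchor <- anchor - 1L
    }
    anchor <- max(anchor, 1L)
    list(anchor = anchor, inserted = ins)
  }
}

#' Positions where the parent strain is ambiguous
#'
#' A position is ambiguous in the parent when its strongest non-reference
#' allele fraction falls in `band` (neither clearly absent nor clearly
#' fixed) or its depth is below `min_depth`.  Isolate calls at such
#' positions cannot be attributed to evolution and are disregarded by
#' [subtract_parent()].
#'
#' @param parent_alignments parent `alignments`.
#' @param reference same reference as used for calling.
#' @param min_depth minimum informative depth.
#' @param band allele-fraction ambiguity band.
#' @return data.frame contig/start/end of merged ambiguous runs.
#' @export
parent_ambiguous_regions <- function(parent_alignments, reference,
                                     min_depth = 10L, band = c(0.2, 0.8)) {
  seqs <- if (is.list(reference) && !is.null(reference$sequences))
    reference$sequences else reference
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  pl <- pileup_counts(parent_alignments, seqs)
  out <- list()
  for (ci in seq_along(seqs)) {
    counts <- pl$counts[[ci]]
    L <- ncol(counts)
    depth <- colSums(counts)
    refc <- strsplit(seqs[[ci]], "")[[1]]
    ref_idx <- match(refc, BASES)
    m <- t(counts)
    valid <- !is.na(ref_idx)
    m[cbind(which(valid), ref_idx[valid])] <- -1L
    alt_count <- m[cbind(seq_len(L), max.col(m, ties.method = "first"))]
    af <- ifelse(depth > 0, pmax(alt_count, 0) / depth, 0)
    amb <- depth < min_depth | (af >= band[1] & af <= band[2])
    if (any(amb)) {
      r <- S4Vectors::Rle(amb)
      ends <- cumsum(S4Vectors::runLength(r))
      starts <- ends - S4Vectors::runLength(r) + 1L
      keep <- S4Vectors::runValue(r)
      if (any(keep)) {
        out[[length(out) + 1]] <- data.frame(
          contig = names(seqs)[ci], start = starts[keep], end = ends[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subtract parent-strain calls from isolate calls
#'
#' Removes isolate variants that are also called in the parent (identical
#' contig/position/alleles) or that fall in a parent-ambiguous region, so
#' only mutations acquired during the evolution experiment remain.
#'
#' @param isolate_calls,parent_calls `variant_calls` on the same reference.
#' @param parent_ambiguous regions from [parent_ambiguous_regions()].
#' @return Filtered `variant_calls`.
#' @export
subtract_parent <- function(isolate_calls, parent_calls,
                            parent_ambiguous = NULL) {
  rc1 <- attr(isolate_calls, "reference_contigs")
  rc2 <- attr(parent_calls, "reference_contigs")
  if (!is.null(rc1) && !is.null(rc2) && !identical(rc1, rc2))
    stop("isolate and parent calls come from different references")
  if (!nrow(isolate_calls)) return(isolate_calls)
  key <- function(x) paste(x$contig, x$pos, x$ref, x$alt)
  drop <- key(isolate_calls) %in% key(parent_calls)
  if (!is.null(parent_ambiguous) && nrow(parent_ambiguous)) {
    for (r in seq_len(nrow(parent_ambiguous))) {
      drop <- drop | (isolate_calls$contig == parent_ambiguous$contig[r] &
                        isolate_calls$pos >= parent_ambiguous$start[r] &
                        isolate_calls$pos <= parent_ambiguous$end[r])
    }
  }
  out <- isolate_calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("reference_contigs", "min_depth", "class")] <-
    attributes(isolate_calls)[c("reference_contigs", "min_depth", "class")]
  out
}

validate_orfs <- function(orfs, seqs) {
  for (r in seq_len(nrow(orfs))) {
    len <- orfs$end[r] - orfs$start[r] + 1L
    if (len %% 3 != 0)
      stop("ORF ", orfs$orf_id[r], " length not a multiple of 3")
    sq <- orf_sequence(seqs, orfs[r, ])
    if (substr(sq, 1, 3) != "ATG")
      stop("ORF ", orfs$orf_id[r], " lacks a start codon")
    if (!substr(sq, len - 2, len) %in% STOP_CODONS)
      stop("ORF ", orfs$orf_id[r], " lacks a stop codon")
  }
  invisible(TRUE)
}

#' Annotate ORF effects and variant nomenclature
#'
#' Classifies each call against non-overlapping ORF annotations using the
#' standard genetic code: synonymous / missense / nonsense for SNPs,
#' frameshift for INDELs of length not divisible by 3, inframe_indel
#' otherwise, intergenic outside ORFs.  Nomenclature follows the
#' field convention for evolved-isolate reports: SNPs as
#' `<orf>^<Ref><orfPos><Alt>` (e.g. `ScSFL1^T605A`) and INDELs as
#' `<orf>^<orfPos>+<N>N` / `<orf>^<orfPos>-<N>N`, where the coordinate is
#' the last unchanged nucleotide of the ORF (strand-aware).
#'
#' @param calls `variant_calls`.
#' @param orfs ORF annotation data.frame (orf_id, contig, start, end,
#'   strand, subgenome).
#' @param reference reference sequences (for codon context and ORF
#'   validation).
#' @param codon_table named vector mapping codons to amino acids.
#' @return `calls` with added columns orf_id, orf_pos, effect,
#'   nomenclature.
#' @export
annotate_effects <- function(calls, orfs, reference,
                             codon_table = Biostrings::GENETIC_CODE) {
  seqs <- if (is.list(reference) && !is.null(reference$sequences))
    reference$sequences else reference
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  if (!is.null(orfs) && nrow(orfs)) {
    o <- orfs[order(orfs$contig, orfs$start), ]
    same <- o$contig[-1] == o$contig[-nrow(o)]
    if (any(same & o$start[-1] <= o$end[-nrow(o)]))
      stop("ORF annotations overlap")
    validate_orfs(orfs, seqs)
  }
  calls$orf_id <- rep(NA_character_, nrow(calls))
  calls$orf_pos <- rep(NA_integer_, nrow(calls))
  calls$effect <- rep("intergenic", nrow(calls))
  calls$nomenclature <- rep(NA_character_, nrow(calls))
  if (!nrow(calls)) return(calls)

  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  for (i in seq_len(nrow(calls))) {
    hit <- which(orfs$contig == calls$contig[i] &
                   calls$pos[i] >= orfs$start &
                   calls$pos[i] <= orfs$end)
    if (!length(hit)) next
    o <- orfs[hit[1], ]
    minus <- identical(o$strand, "-")
    orf_seq <- orf_sequence(seqs, o)
    L <- nchar(orf_seq)
    if (calls$kind[i] == "SNP") {
      orf_pos <- if (minus) o$end - calls$pos[i] + 1L else
        calls$pos[i] - o$start + 1L
      refb <- if (minus) comp1(calls$ref[i]) else calls$ref[i]
      altb <- if (minus) comp1(calls$alt[i]) else calls$alt[i]
      cod_i <- (orf_pos - 1L) %/% 3L
      cod <- substr(orf_seq, cod_i * 3 + 1, cod_i * 3 + 3)
      within <- orf_pos - cod_i * 3L
      newcod <- cod
      substr(newcod, within, within) <- altb
      aa_old <- codon_table[[cod]]
      aa_new <- codon_table[[newcod]]
      eff <- if (aa_old == aa_new) "synonymous"
      else if (aa_new == "*") "nonsense" else "missense"
      calls$orf_id[i] <- o$orf_id
      calls$orf_pos[i] <- orf_pos
      calls$effect[i] <- eff
      calls$nomenclature[i] <- paste0(o$orf_id, "^", refb, orf_pos, altb)
    } else {
      len <- nchar(calls$alt[i]) - nchar(calls$ref[i])
      if (minus) {
        anchor <- if (len < 0) o$end - (calls$pos[i] + abs(len)) else
          o$end - calls$pos[i]
      } else {
        anchor <- calls$pos[i] - o$start + 1L
      }
      anchor <- max(1L, min(L, anchor))
      eff <- if (abs(len) %% 3 != 0) "frameshift" else "inframe_indel"
      calls$orf_id[i] <- o$orf_id
      calls$orf_pos[i] <- anchor
      calls$effect[i] <- eff
      calls$nomenclature[i] <- paste0(o$orf_id, "^", anchor,
                                      if (len > 0) "+" else "-", abs(len), "N")
    }
  }
  calls
}

#' Format / parse the point-mutation nomenclature
#'
#' `parse_variant_nomenclature(format_variant_nomenclature(x))` is the
#' identity on the grammar.
#'
#' @param x for parse: a nomenclature string; for format: a list with
#'   fields orf, kind ("SNP"/"INDEL"), and pos/ref/alt or pos/len.
#' @return Parse: list(orf, kind, pos, ref, alt, len); format: string.
#' @export
parse_variant_nomenclature <- function(x) {
  m <- regmatches(x, regexec("^(.+)\\^([ACGT])([0-9]+)([ACGT])$", x))[[1]]
  if (length(m) == 5) {
    return(list(orf = m[2], kind = "SNP", pos = as.integer(m[4]),
                ref = m[3], alt = m[5], len = NA_integer_))
  }
  m <- regmatches(x, regexec("^(.+)\\^([0-9]+)([+-])([0-9]+)N$", x))[[1]]
  if (length(m) == 5) {
    return(list(orf = m[2], kind = "INDEL", pos = as.integer(m[3]),
                ref = NA_character_, alt = NA_character_,
                len = as.integer(m[5]) * if (m[4] == "+") 1L else -1L))
  }
  stop("cannot parse variant nomenclature: ", x)
}

#' @rdname parse_variant_nomenclature
#' @export
format_variant_nomenclature <- function(x) {
  if (x$kind == "SNP") paste0(x$orf, "^", x$ref, x$pos, x$alt)
  else paste0(x$orf, "^", x$pos, if (x$len > 0) "+" else "-", abs(x$len), "N")
}

#' Non-synonymous ORF-affecting calls
#'
#' The reporting subset used in per-isolate mutation tables: ORF calls
#' whose effect is missense, nonsense, frameshift or inframe_indel.
#' @param calls annotated `variant_calls`.
#' @export
nonsynonymous_calls <- function(calls) {
  calls[!is.na(calls$orf_id) &
          calls$effect %in% c("missense", "nonsense", "frameshift",
                              "inframe_indel"), , drop = FALSE]
}

#' Write calls as minimal VCF
#'
#' VCF 4.2-style minimal body with DP and AF in INFO.
#' @param calls `variant_calls`.
#' @param file path.
#' @export
write_vcf <- function(calls, file) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
                  calls$contig, calls$pos, calls$ref, calls$alt,
                  as.integer(calls$depth), calls$alt_fraction)
  writeLines(c(hdr, body), file)
  invisible(file)
}
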