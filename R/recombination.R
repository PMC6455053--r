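#' Cluster structural-variant read evidence into breakpoint candidates
#'
#' Discordant pairs and split reads whose two end loci co-locate within
#' `radius` on both sides are merged into one candidate.  The candidate
#' junction position is the median of split-read junction coordinates when
#' split evidence exists, otherwise it is extrapolated from the innermost
#' mate coordinates by half the expected mate gap.  The support fraction
#' denominator (`local_total_reads`) counts the reads aligned at the
#' junction locus: alignments overlapping a window of +/- one read
#' length around locus 1.
#'
#' @param discordant output of [extract_discordant()].
#' @param alignments the isolate `alignments` (for local read totals).
#' @param radius clustering radius in bp (should be at least the insert
#'   mean; default 500).
#' @param insert_mean,read_length library parameters used for mate-gap
#'   extrapolation.
#' @param support_window half-width (bp) of the locus-1 window whose
#'   overlapping reads form the support-fraction denominator.
#' @return data.frame of class `breakpoint_candidates`: contig1, pos1,
#'   contig2, pos2, supporting_reads, n_split, local_total_reads,
#'   support_fraction.
#' @export
cluster_evidence <- function(discordant, alignments, radius = 500L,
                             insert_mean = 450L, read_length = 150L,
                             support_window = read_length) {
  empty <- data.frame(contig1 = character(0), pos1 = integer(0),
                      contig2 = character(0), pos2 = integer(0),
                      supporting_reads = integer(0), n_split = integer(0),
                      local_total_reads = integer(0),
                      support_fraction = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("breakpoint_candidates", class(empty))
  if (!nrow(discordant)) return(empty)
  # aberrant-insert-only pairs are not junction evidence by themselves
  d <- discordant[discordant$class %in%
                    c("inter_contig", "split_read", "aberrant_insert",
                      "aberrant_orientation"), , drop = FALSE]
  if (!nrow(d)) return(empty)
  d <- d[order(d$contig1, d$pos1, d$contig2, d$pos2), , drop = FALSE]
  cl <- integer(nrow(d))
  centers <- list()
  for (i in seq_len(nrow(d))) {
    assigned <- FALSE
    for (j in seq_along(centers)) {
      cen <- centers[[j]]
      if (d$contig1[i] == cen$contig1 && d$contig2[i] == cen$contig2 &&
          abs(d$pos1[i] - cen$pos1) <= radius &&
          abs(d$pos2[i] - cen$pos2) <= radius) {
        cl[i] <- j
        cen$n <- cen$n + 1L
        cen$pos1 <- cen$pos1 + (d$pos1[i] - cen$pos1) / cen$n
        cen$pos2 <- cen$pos2 + (d$pos2[i] - cen$pos2) / cen$n
        centers[[j]] <- cen
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centers[[length(centers) + 1]] <- list(contig1 = d$contig1[i],
                                             contig2 = d$contig2[i],
                                             pos1 = d$pos1[i],
                                             pos2 = d$pos2[i], n = 1L)
      cl[i] <- length(centers)
    }
  }

  a <- alignments[alignments$mapped, , drop = FALSE]
  spans <- cigar_ref_span(a$cigar)
  out <- vector("list", length(centers))
  for (j in seq_along(centers)) {
    rows <- d[cl == j, , drop = FALSE]
    support <- length(unique(rows$read_id))
    splits <- rows[rows$class == "split_read", , drop = FALSE]
    if (nrow(splits)) {
      p1 <- as.integer(round(stats::median(splits$pos1)))
      p2 <- as.integer(round(stats::median(splits$pos2)))
    } else {
      gap <- max(0L, as.integer(round((insert_mean - 2 * read_length) / 2)))
      p1 <- as.integer(round(stats::median(rows$pos1))) +
        ifelse(any(rows$strand1 == "+"), gap, -gap)
      p2 <- as.integer(round(stats::median(rows$pos2))) -
        ifelse(any(rows$strand2 == "-"), gap, -gap)
    }
    ctg1 <- rows$contig1[1]; ctg2 <- rows$contig2[1]
    local_total <- sum(a$contig == ctg1 &
                         a$pos <= p1 + support_window &
                         a$pos + spans - 1L >= p1 - support_window)
    out[[j]] <- data.frame(
      contig1 = ctg1, pos1 = p1, contig2 = ctg2, pos2 = p2,
      supporting_reads = support, n_split = nrow(splits),
      local_total_reads = local_total,
      support_fraction = if (local_total > 0) support / local_total else 0,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig1, res$pos1), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "radius") <- radius
  class(res) <- c("breakpoint_candidates", class(res))
  res
}

#' Filter breakpoint candidates by support fraction and parent absence
#'
#' A candidate is retained when at least `min_fraction` of the reads
#' aligned at its locus support the rearrangement (inclusive threshold:
#' exactly 10 percent passes at the default) and no parent candidate
#' matches within `radius` on both loci.
#'
#' @param candidates isolate `breakpoint_candidates`.
#' @param parent_candidates parent candidates (from running the same
#'   evidence pipeline on the parent strain).
#' @param min_fraction minimum support fraction in (0, 1]; default 0.10.
#' @param radius matching radius for parent subtraction.
#' @return Filtered candidates with a `present_in_parent` column.
#' @export
filter_candidates <- function(candidates, parent_candidates = NULL,
                              min_fraction = 0.10,
                              radius = attr(candidates, "radius") %||% 500L) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  if (!nrow(candidates)) return(candidates)
  in_parent <- rep(FALSE, nrow(candidates))
  if (!is.null(parent_candidates) && nrow(parent_candidates)) {
    for (i in seq_len(nrow(candidates))) {
      in_parent[i] <- any(
        parent_candidates$contig1 == candidates$contig1[i] &
          parent_candidates$contig2 == candidates$contig2[i] &
          abs(parent_candidates$pos1 - candidates$pos1[i]) <= radius &
          abs(parent_candidates$pos2 - candidates$pos2[i]) <= radius)
    }
  }
  candidates$present_in_parent <- in_parent
  keep <- candidates$support_fraction >= min_fraction & !in_parent
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "radius") <- radius
  class(out) <- class(candidates)
  out
}

#' Link breakpoint candidates to copy-number events
#'
#' A candidate whose loci fall within the boundary windows of a segmental
#' deletion / duplication / LOH substitution is linked to that event
#' (these junctions are the read-level signature of the copy-number
#' change); unlinked candidates remain reported.  Candidates whose loci
#' pair copy-neutral regions are flagged `reciprocal` — copy-number
#' conservative translocations are reported with a distinct class rather
#' than dropped.
#'
#' @param candidates `breakpoint_candidates`.
#' @param copy_events `copy_events` from [classify_events()].
#' @param window boundary tolerance in bp (default: the coverage window).
#' @return Candidates with `linked_copy_event` (nomenclature string or
#'   NA) and `class` columns.
#' @export
link_to_copy_events <- function(candidates, copy_events,
                                window = attr(copy_events, "window") %||% 1000L) {
  if (!nrow(candidates)) {
    candidates$linked_copy_event <- character(0)
    candidates$class <- character(0)
    return(candidates)
  }
  candidates$linked_copy_event <- NA_character_
  candidates$class <- "unlinked"
  if (!is.null(copy_events) && nrow(copy_events)) {
    seg <- copy_events[copy_events$kind %in%
                         c("SEG_DEL", "SEG_DUP", "LOH_SUBST"), , drop = FALSE]
    near <- function(ctg, pos, ectg, es, ee) {
      !is.na(ectg) & ctg == ectg &
        (abs(pos - es) <= 2 * window | abs(pos - ee) <= 2 * window)
    }
    for (i in seq_len(nrow(candidates))) {
      for (r in seq_len(nrow(seg))) {
        hit1 <- near(candidates$contig1[i], candidates$pos1[i],
                     seg$contig[r], seg$start[r], seg$end[r]) |
          near(candidates$contig1[i], candidates$pos1[i],
               seg$donor_contig[r], seg$donor_start[r], seg$donor_end[r])
        hit2 <- near(candidates$contig2[i], candidates$pos2[i],
                     seg$contig[r], seg$start[r], seg$end[r]) |
          near(candidates$contig2[i], candidates$pos2[i],
               seg$donor_contig[r], seg$donor_start[r], seg$donor_end[r])
        if (isTRUE(hit1) && isTRUE(hit2)) {
          candidates$linked_copy_event[i] <- seg$nomenclature[r]
          candidates$class[i] <- "copy_linked"
          break
        }
      }
      if (candidates$class[i] == "unlinked" &&
          candidates$contig1[i] != candidates$contig2[i]) {
        candidates$class[i] <- "reciprocal"
      }
    }
  }
  candidates
}

#' Write breakpoint candidates as BEDPE-like TSV
#' @param candidates `breakpoint_candidates`.
#' @param file path.
#' @export
write_candidates_tsv <- function(candidates, file) {
  utils::write.table(candidates, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
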