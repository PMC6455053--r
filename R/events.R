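#' Evolution-event truth ledgers
#'
#' A truth ledger records the evolution events injected into one simulated
#' isolate.  Event kinds cover the mutation classes observed in evolved
#' allodiploid hybrids: point mutations (SNP, INDEL), segmental copy-number
#' changes (SEG_DEL, SEG_DUP), loss-of-heterozygosity substitutions
#' (LOH_SUBST: an acceptor segment replaced by the homeologous donor
#' segment), whole-chromosome gain/loss (CHR_GAIN, CHR_LOSS) and
#' mitochondrial-genome loss (MT_LOSS_FULL, MT_LOSS_PARTIAL).
#'
#' Coordinates are 1-based inclusive.  INDEL events use the coordinate of
#' the last unchanged nucleotide as anchor (`start`), with `indel_len` > 0
#' for insertions (inserted sequence in `alt`) and < 0 for deletions.
#'
#' @param isolate_id isolate identifier.
#' @param events data.frame of events (see event constructors `ev_*`).
#' @return A `truth_ledger` object.
#' @export
truth_ledger <- function(isolate_id, events) {
  cols <- c("kind", "contig", "start", "end", "alt", "indel_len",
            "donor_contig", "donor_start", "donor_end", "gene_id")
  for (cc in base::setdiff(cols, names(events))) {
    na <- if (cc %in% c("start", "end", "indel_len",
                        "donor_start", "donor_end")) NA_integer_
          else NA_character_
    events[[cc]] <- rep(na, nrow(events))
  }
  events <- events[, cols]
  kinds <- c("SNP", "INDEL", "SEG_DEL", "SEG_DUP", "LOH_SUBST",
             "CHR_GAIN", "CHR_LOSS", "MT_LOSS_FULL", "MT_LOSS_PARTIAL")
  if (!all(events$kind %in% kinds))
    stop("unknown event kind: ", paste(setdiff(events$kind, kinds), collapse = ", "))
  if (any(events$kind == "INDEL" &
          (is.na(events$indel_len) | events$indel_len == 0)))
    stop("INDEL events must have nonzero indel_len")
  structure(list(isolate_id = isolate_id, events = events),
            class = "truth_ledger")
}

#' @rdname truth_ledger
#' @param ... event data.frames from the `ev_*` constructors.
#' @export
bind_events <- function(...) {
  evs <- list(...)
  cols <- c("kind", "contig", "start", "end", "alt", "indel_len",
            "donor_contig", "donor_start", "donor_end", "gene_id")
  evs <- lapply(evs, function(e) {
    for (cc in base::setdiff(cols, names(e))) {
      na <- if (cc %in% c("start", "end", "indel_len",
                          "donor_start", "donor_end")) NA_integer_
            else NA_character_
      e[[cc]] <- rep(na, nrow(e))
    }
    e[, cols]
  })
  do.call(rbind, evs)
}

#' @rdname truth_ledger
#' @param contig,pos,alt,start,end,len,seq,donor_contig,donor_start,donor_end,gene_id
#'   event fields; see Details of [truth_ledger()].
#' @export
ev_snp <- function(contig, pos, alt) {
  data.frame(kind = "SNP", contig = contig, start = as.integer(pos),
             end = as.integer(pos), alt = alt, stringsAsFactors = FALSE)
}

#' @rdname truth_ledger
#' @export
ev_indel <- function(contig, pos, len, seq = NULL) {
  len <- as.integer(len)
  if (len > 0 && is.null(seq)) seq <- rand_dna(len)
  if (len > 0) stopifnot(nchar(seq) == len)
  data.frame(kind = "INDEL", contig = contig, start = as.integer(pos),
             end = as.integer(pos) + max(0L, -len), indel_len = len,
             alt = if (len > 0) seq else NA_character_, stringsAsFactors = FALSE)
}

#' @rdname truth_ledger
#' @export
ev_seg_del <- function(contig, start, end) {
  data.frame(kind = "SEG_DEL", contig = contig, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' @rdname truth_ledger
#' @export
ev_seg_dup <- function(contig, start, end) {
  data.frame(kind = "SEG_DUP", contig = contig, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' @rdname truth_ledger
#' @export
ev_loh <- function(contig, start, end, donor_contig, donor_start = start,
                   donor_end = end, gene_id = NA_character_) {
  data.frame(kind = "LOH_SUBST", contig = contig, start = as.integer(start),
             end = as.integer(end), donor_contig = donor_contig,
             donor_start = as.integer(donor_start),
             donor_end = as.integer(donor_end), gene_id = gene_id,
             stringsAsFactors = FALSE)
}

#' @rdname truth_ledger
#' @export
ev_chr_gain <- function(contig) {
  data.frame(kind = "CHR_GAIN", contig = contig, stringsAsFactors = FALSE)
}

#' @rdname truth_ledger
#' @export
ev_chr_loss <- function(contig) {
  data.frame(kind = "CHR_LOSS", contig = contig, stringsAsFactors = FALSE)
}

#' @rdname truth_ledger
#' @export
ev_mt_loss <- function(contig, fraction = NULL, contig_len = NULL) {
  if (is.null(fraction)) {
    return(data.frame(kind = "MT_LOSS_FULL", contig = contig,
                      stringsAsFactors = FALSE))
  }
  stopifnot(!is.null(contig_len), fraction > 0, fraction < 1)
  # deletion of a contiguous fraction from the middle of the contig
  dlen <- as.integer(round(fraction * contig_len))
  st <- as.integer((contig_len - dlen) %/% 2) + 1L
  data.frame(kind = "MT_LOSS_PARTIAL", contig = contig, start = st,
             end = st + dlen - 1L, stringsAsFactors = FALSE)
}

#' LOH substitution through a homeologous ORF pair
#'
#' Builds an LOH_SUBST event whose acceptor boundary lies inside an ORF, so
#' the isolate carries a chimeric ORF: the acceptor segment from the in-ORF
#' breakpoint to the contig end is replaced by the homeologous donor
#' segment.  The acceptor subgenome keeps the ORF prefix (positions
#' `1..breakpoint`); the donor subgenome supplies the suffix.
#'
#' @param reference output of [build_reference()].
#' @param gene_id gene id of the homeolog pair.
#' @param breakpoint in-ORF breakpoint position (1-based, within the ORF).
#' @param acceptor which subgenome loses its allele ("A"-side tag or
#'   "B"-side tag; default the second label, emulating loss on one parent).
#' @return One-row event data.frame.
#' @export
ev_loh_through_pair <- function(reference, gene_id, breakpoint,
                                acceptor = reference$spec$subgenome_labels[2]) {
  h <- reference$homologs[reference$homologs$gene_id == gene_id, ]
  if (nrow(h) != 1) stop("unknown gene_id: ", gene_id)
  tags <- reference$spec$subgenome_labels
  stopifnot(breakpoint >= 1, breakpoint <= h$length)
  if (acceptor == tags[2]) {
    acc_contig <- h$contig_b; acc_orf_start <- h$start_b
    don_contig <- h$contig_a
  } else {
    acc_contig <- h$contig_a; acc_orf_start <- h$start_a
    don_contig <- h$contig_b
  }
  gpos <- acc_orf_start + breakpoint  # first replaced base (after breakpoint)
  clen <- nchar(as.character(reference$sequences[[acc_contig]]))
  ev_loh(acc_contig, gpos, clen, don_contig, gpos, clen, gene_id = gene_id)
}

#' Apply a truth ledger to a reference genome
#'
#' Deterministically replays the ledger's events on the reference sequences
#' to produce the isolate genome.  Sequence-level events on one contig must
#' not overlap; they are applied right-to-left so coordinates stay valid.
#' CHR_GAIN appends a duplicate contig named `<contig>_gain`; CHR_LOSS and
#' MT_LOSS_FULL drop the contig; MT_LOSS_PARTIAL deletes the recorded
#' interval.
#'
#' @param reference output of [build_reference()] (or a named character
#'   vector / DNAStringSet of contigs).
#' @param ledger a [truth_ledger()].
#' @return Named [Biostrings::DNAStringSet] of isolate contigs.
#' @export
inject_events <- function(reference, ledger) {
  stopifnot(inherits(ledger, "truth_ledger"))
  seqs <- if (is.list(reference) && !is.null(reference$sequences))
    reference$sequences else reference
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  ev <- ledger$events
  if (!nrow(ev)) return(Biostrings::DNAStringSet(seqs))

  seq_ev <- ev[ev$kind %in% c("SNP", "INDEL", "SEG_DEL", "SEG_DUP",
                              "LOH_SUBST", "MT_LOSS_PARTIAL"), , drop = FALSE]
  chr_ev <- ev[ev$kind %in% c("CHR_GAIN", "CHR_LOSS", "MT_LOSS_FULL"), , drop = FALSE]

  bad <- setdiff(unique(ev$contig), names(seqs))
  if (length(bad)) stop("events name unknown contigs: ", paste(bad, collapse = ", "))

  # bounds and overlap validation per contig
  for (ctg in unique(seq_ev$contig)) {
    e <- seq_ev[seq_ev$contig == ctg, , drop = FALSE]
    clen <- nchar(seqs[[ctg]])
    if (any(e$start < 1 | e$end > clen | e$end < e$start))
      stop("event interval out of bounds on ", ctg)
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1) {
      ov <- which(e$start[-1] <= e$end[-nrow(e)])
      if (length(ov))
        stop("overlapping events on ", ctg, " at positions ",
             paste(e$start[ov + 1], collapse = ", "))
    }
  }

  # all event coordinates (acceptor and donor alike) are reference-frame;
  # donor segments are sliced from the unmodified reference so that edits
  # applied earlier on the donor contig cannot shift them
  orig <- seqs
  for (ctg in unique(seq_ev$contig)) {
    e <- seq_ev[seq_ev$contig == ctg, , drop = FALSE]
    e <- e[order(e$start, decreasing = TRUE), , drop = FALSE]
    s <- seqs[[ctg]]
    for (i in seq_len(nrow(e))) {
      k <- e$kind[i]; st <- e$start[i]; en <- e$end[i]
      if (k == "SNP") {
        substr(s, st, st) <- e$alt[i]
      } else if (k == "INDEL") {
        if (e$indel_len[i] > 0) {
          s <- paste0(substr(s, 1, st), e$alt[i], substr(s, st + 1, nchar(s)))
        } else {
          dlen <- -e$indel_len[i]
          s <- paste0(substr(s, 1, st), substr(s, st + dlen + 1, nchar(s)))
        }
      } else if (k %in% c("SEG_DEL", "MT_LOSS_PARTIAL")) {
        s <- paste0(substr(s, 1, st - 1), substr(s, en + 1, nchar(s)))
      } else if (k == "SEG_DUP") {
        seg <- substr(s, st, en)
        s <- paste0(substr(s, 1, en), seg, substr(s, en + 1, nchar(s)))
      } else if (k == "LOH_SUBST") {
        donor <- substr(orig[[e$donor_contig[i]]], e$donor_start[i], e$donor_end[i])
        s <- paste0(substr(s, 1, st - 1), donor, substr(s, en + 1, nchar(s)))
      }
    }
    seqs[[ctg]] <- s
  }

  for (i in seq_len(nrow(chr_ev))) {
    k <- chr_ev$kind[i]; ctg <- chr_ev$contig[i]
    if (k == "CHR_GAIN") {
      seqs[[paste0(ctg, "_gain")]] <- seqs[[ctg]]
    } else {
      seqs <- seqs[names(seqs) != ctg]
    }
  }
  Biostrings::DNAStringSet(seqs)
}

#' Draw a random set of clonal point mutations for an isolate
#'
#' Samples SNP and INDEL positions on nuclear contigs, by default avoiding
#' the homeologous ORFs (so variants fall in uniquely mappable sequence)
#' and keeping events well separated.
#'
#' @param reference output of [build_reference()].
#' @param n_snp,n_indel event counts.
#' @param indel_lens pool of INDEL lengths (positive insertion, negative
#'   deletion) sampled from.
#' @param avoid_orfs keep events out of annotated ORFs.
#' @param avoid_ranges optional data.frame (contig, start, end) of regions
#'   to keep clear of (e.g. planned segmental events).
#' @param margin minimum distance from contig ends and between events (bp).
#' @param seed integer seed.
#' @return Event data.frame usable with [truth_ledger()].
#' @export
random_point_events <- function(reference, n_snp = 5, n_indel = 3,
                                indel_lens = c(-3L, -1L, 1L, 3L),
                                avoid_orfs = TRUE, margin = 2000L, seed = 1L,
                                avoid_ranges = NULL) {
  seqs <- reference$sequences
  nuclear <- names(seqs)[!is_mito_contig(names(seqs))]
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  with_seed(derive_seed(seed, 7), {
    taken <- data.frame(contig = character(0), pos = integer(0))
    pick_pos <- function() {
      for (try in 1:200) {
        ctg <- sample(nuclear, 1)
        pos <- sample.int(lens[[ctg]] - 2 * margin, 1) + margin
        if (avoid_orfs && !is.null(reference$orfs)) {
          o <- reference$orfs
          inorf <- any(o$contig == ctg & pos >= o$start - 50 & pos <= o$end + 50)
          if (inorf) next
        }
        clash <- any(taken$contig == ctg & abs(taken$pos - pos) < 300)
        if (clash) next
        if (!is.null(avoid_ranges) &&
            any(avoid_ranges$contig == ctg & pos >= avoid_ranges$start - 300 &
                  pos <= avoid_ranges$end + 300)) next
        taken <<- rbind(taken, data.frame(contig = ctg, pos = pos))
        return(list(contig = ctg, pos = pos))
      }
      stop("could not place event away from ORFs")
    }
    evs <- list()
    for (i in seq_len(n_snp)) {
      p <- pick_pos()
      refb <- substr(as.character(seqs[[p$contig]]), p$pos, p$pos)
      evs[[length(evs) + 1]] <- ev_snp(p$contig, p$pos, sample(setdiff(BASES, refb), 1))
    }
    for (i in seq_len(n_indel)) {
      p <- pick_pos()
      evs[[length(evs) + 1]] <- ev_indel(p$contig, p$pos, sample(indel_lens, 1))
    }
    do.call(bind_events, evs)
  })
}

#' Write / read a truth ledger as TSV
#' @param ledger a [truth_ledger()].
#' @param file path.
#' @export
write_ledger <- function(ledger, file) {
  df <- if (nrow(ledger$events))
    cbind(isolate_id = ledger$isolate_id, ledger$events)
  else cbind(data.frame(isolate_id = character(0)), ledger$events)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  truth_ledger(df$isolate_id[1], df[, setdiff(names(df), "isolate_id")])
}
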