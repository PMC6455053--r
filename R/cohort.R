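#' Packaged per-isolate mutation table
#'
#' Transcription of the published per-isolate overview for the 55 evolved
#' isolates: evolution line, batch cycles and estimated generations,
#' phenotypes (maltotriose utilization, flocculation, respiratory
#' competence), mitochondrial status (`rho-` complete loss, `rho0`
#' partial loss, empty = present), whole-chromosome aneuploidy, segmental
#' aneuploidy / loss-of-heterozygosity nomenclature, and non-synonymous
#' SNPs / INDELs (semicolon-separated within a field).
#'
#' @param file TSV path; defaults to the packaged fixture.
#' @return data.frame with one row per isolate.
#' @export
read_table2 <- function(file = system.file("extdata", "table2_isolates.tsv",
                                           package = "hybriddyn")) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, fill = TRUE,
                          fileEncoding = "UTF-8")
  for (cc in c("mito_status", "aneuploidy", "segmental", "snps", "indels"))
    df[[cc]][is.na(df[[cc]])] <- ""
  df
}

#' Packaged recombination table
#'
#' Transcription of the published recombination overview: one record per
#' observed recombination, with the two affected loci (name, ORF length,
#' breakpoint-interval coordinate range), their homology (numeric percent
#' or the left-censored category `"<70"`), the recombined ORF length, and
#' the locus class (ORF, rDNA or Ty transposon).
#'
#' @param file TSV path; defaults to the packaged fixture.
#' @return data.frame with one row per recombination record.
#' @export
read_table3 <- function(file = system.file("extdata",
                                           "table3_recombinations.tsv",
                                           package = "hybriddyn")) {
  utils::read.delim(file, stringsAsFactors = FALSE,
                    colClasses = c(homology = "character"),
                    fileEncoding = "UTF-8")
}

#' Generations from sequential-batch cycles
#'
#' In a sequential batch regime where a fraction `carryover_fraction` of
#' the culture inoculates the next cycle, the population doubles
#' log2(1 / carryover) times per cycle.  At the 7 percent carry-over used
#' in simulated brewing this is 3.84, rounded to 4 generations per cycle,
#' which reproduces every printed generation count from its cycle count.
#'
#' @param cycles number of completed batch cycles (>= 0).
#' @param carryover_fraction inoculum fraction in (0, 1).
#' @return Estimated number of generations (cycles x rounded
#'   generations/cycle).
#' @export
generations_from_cycles <- function(cycles, carryover_fraction = 0.07) {
  if (any(carryover_fraction >= 1) || any(carryover_fraction <= 0))
    stop("carryover_fraction must be in (0, 1)")
  stopifnot(all(cycles >= 0))
  gpc <- round(log2(1 / carryover_fraction))
  cycles * gpc
}

#' Per-cell-division mutation frequency
#'
#' @param event_count number of events of one class in an isolate.
#' @param generations estimated generations of growth (> 0).
#' @return events per cell division.
#' @export
per_division_frequency <- function(event_count, generations) {
  if (any(generations <= 0)) stop("generations must be positive")
  event_count / generations
}

#' Per-nucleotide mutation rate
#'
#' Scales a per-division frequency by the genome size (default 24.2 Mbp,
#' the combined size of the two parental subgenomes).
#'
#' @param frequency events per cell division.
#' @param genome_size_bp genome size in bp (> 0).
#' @param sig_figs significant figures for the reported rate.
#' @return rate per nucleotide per cell division.
#' @export
per_nucleotide_rate <- function(frequency, genome_size_bp = 24200000,
                                sig_figs = 2) {
  stopifnot(genome_size_bp > 0)
  signif(frequency / genome_size_bp, sig_figs)
}

split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Cohort tallies across isolates
#'
#' Aggregates a per-isolate summary table: how many isolates carry
#' whole-chromosome aneuploidy, segmental copy-number changes, or
#' mitochondrial loss; how often each recurrent event nomenclature
#' occurs; whether generation counts are consistent with the
#' generations-per-cycle model; and per-line per-division frequency
#' ranges for each mutation class.
#'
#' @param summaries data.frame as returned by [read_table2()].
#' @param carryover_fraction used for the generation-consistency check.
#' @return list of cohort statistics.
#' @export
tally_cohort <- function(summaries, carryover_fraction = 0.07) {
  stopifnot(nrow(summaries) > 0)
  if (anyDuplicated(summaries$isolate_id))
    stop("duplicate isolate_id: ",
         paste(unique(summaries$isolate_id[duplicated(summaries$isolate_id)]),
               collapse = ", "))
  s <- summaries
  n <- nrow(s)
  aneu <- lapply(s$aneuploidy, split_field)
  segm <- lapply(s$segmental, split_field)
  snps <- lapply(s$snps, split_field)
  indels <- lapply(s$indels, split_field)
  mito_loss <- s$mito_status %in% c("rho-", "rho0")

  all_events <- c(unlist(segm), unlist(aneu))
  recurrence <- sort(table(all_events), decreasing = TRUE)

  gen_expected <- generations_from_cycles(s$cycles, carryover_fraction)
  counts <- data.frame(
    isolate_id = s$isolate_id, line_id = s$line_id,
    generations = s$generations,
    SNP = lengths(snps), INDEL = lengths(indels),
    recombination = lengths(segm), aneuploidy = lengths(aneu),
    mito_loss = as.integer(mito_loss), stringsAsFactors = FALSE)

  per_line <- do.call(rbind, lapply(split(counts, counts$line_id), function(g) {
    do.call(rbind, lapply(c("SNP", "INDEL", "recombination", "aneuploidy",
                            "mito_loss"), function(cl) {
      f <- per_division_frequency(g[[cl]], g$generations)
      data.frame(line_id = g$line_id[1], class = cl,
                 min_frequency = min(f), max_frequency = max(f),
                 mean_frequency = mean(f), stringsAsFactors = FALSE)
    }))
  }))
  rownames(per_line) <- NULL

  list(n_isolates = n,
       n_whole_chromosome_aneuploidy = sum(lengths(aneu) > 0),
       n_segmental = sum(lengths(segm) > 0),
       n_mito_loss = sum(mito_loss),
       n_rho_minus = sum(s$mito_status == "rho-"),
       n_rho_zero = sum(s$mito_status == "rho0"),
       recurrence = recurrence,
       generations_consistent = all(s$generations == gen_expected),
       per_isolate_counts = counts,
       per_line_frequencies = per_line)
}

# median with "<70"-style left-censored values ranked below all numeric
# values; returns list(value, censored)
censored_median <- function(values, censored) {
  n <- length(values)
  stopifnot(n > 0, length(censored) == n)
  ord <- order(!censored, values)  # censored first, then numeric ascending
  v <- values[ord]; cns <- censored[ord]
  if (n %% 2 == 1) {
    i <- (n + 1) / 2
    list(value = if (cns[i]) NA_real_ else v[i], censored = cns[i])
  } else {
    i <- n / 2
    if (cns[i] || cns[i + 1]) list(value = NA_real_, censored = TRUE)
    else list(value = mean(v[i:(i + 1)]), censored = FALSE)
  }
}

#' Summary statistics over recombination records
#'
#' Totals, the in-ORF subset, the median homology of recombined ORF pairs
#' (with `"<70"` categories treated as left-censored, ranked below every
#' numeric value), the breakpoint-interval width range, and a
#' closed-form consistency check of chimera lengths (see
#' [chimera_length_closed_form()]).
#'
#' @param records data.frame as returned by [read_table3()].
#' @return list of summary statistics.
#' @export
summarize_recombinations <- function(records) {
  stopifnot(nrow(records) > 0)
  r <- records
  orf <- r[r$locus_class == "ORF", , drop = FALSE]
  # interval widths must agree between the two loci of an ORF record
  w1 <- orf$locus1_end - orf$locus1_start + 1
  w2 <- orf$locus2_end - orf$locus2_start + 1
  bad <- which(!is.na(w1) & !is.na(w2) & w1 != w2)
  if (length(bad))
    stop("interval width mismatch between loci in record(s): ",
         paste(orf$locus1_name[bad], collapse = ", "))
  cens <- orf$homology == "<70"
  hom <- suppressWarnings(as.numeric(orf$homology))
  hom[cens] <- NA_real_
  med <- censored_median(ifelse(cens, -Inf, hom), cens)
  list(n_total = nrow(r),
       n_in_orf = nrow(orf),
       median_homology = med$value,
       median_homology_censored = med$censored,
       min_interval_width = min(w1, na.rm = TRUE),
       max_interval_width = max(w1, na.rm = TRUE),
       interval_widths = stats::setNames(w1, orf$locus1_name))
}

#' Per-isolate summary from pipeline results
#'
#' Collects the per-isolate event counts and rate estimates produced by
#' the analysis stages into one row, mirroring the columns of the
#' published per-isolate table.
#'
#' @param isolate_id isolate label.
#' @param line_id evolution line label.
#' @param cycles completed batch cycles.
#' @param variant_calls annotated, parent-subtracted `variant_calls`.
#' @param copy_events `copy_events`.
#' @param mito one-row result of [classify_mito()].
#' @param carryover_fraction inoculum fraction.
#' @return One-row data.frame compatible with [tally_cohort()].
#' @export
isolate_summary <- function(isolate_id, line_id, cycles, variant_calls,
                            copy_events, mito, carryover_fraction = 0.07) {
  nsyn <- nonsynonymous_calls(variant_calls)
  snps <- nsyn$nomenclature[nsyn$kind == "SNP"]
  indels <- nsyn$nomenclature[nsyn$kind == "INDEL"]
  aneu <- copy_events$nomenclature[copy_events$scope == "chromosome"]
  segm <- copy_events$nomenclature[copy_events$scope == "segment"]
  mito_status <- switch(mito$status, full_loss = "rho-",
                        partial_loss = "rho0", "")
  data.frame(line_id = line_id, condition = "",
             cycles = cycles,
             generations = generations_from_cycles(cycles, carryover_fraction),
             isolate_id = isolate_id, maltotriose = "", flocculation = "",
             respiration = "",
             mito_status = mito_status,
             aneuploidy = paste(aneu, collapse = ";"),
             segmental = paste(segm, collapse = ";"),
             snps = paste(snps, collapse = ";"),
             indels = paste(indels, collapse = ";"),
             stringsAsFactors = FALSE)
}
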