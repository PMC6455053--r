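#' Run the full synthetic-evolution analysis pipeline
#'
#' Orchestrates simulate -> map -> call -> cnv -> recomb -> chimera ->
#' summarize for a set of simulated isolates against a simulated parent,
#' with every intermediate optionally written in its standard format
#' (FASTA, FASTQ, SAM, VCF, BED, TSV) plus a run manifest.
#'
#' @param config a list with components:
#'   \describe{
#'     \item{seed}{integer; drives every random stream.}
#'     \item{genome}{arguments for [genome_spec()] (optional).}
#'     \item{isolates}{named list: isolate_id -> event data.frame
#'       (see [truth_ledger()]).}
#'     \item{reads}{arguments for [read_sim_params()] (optional).}
#'     \item{params}{stage thresholds: k, window, min_depth, min_af,
#'       min_fraction, radius, chimera_window, carryover (all optional).}
#'     \item{outdir}{output directory; omit to skip writing files.}
#'     \item{line_id, cycles}{metadata for the isolate summaries.}
#'   }
#' @return list: reference, parent results, per-isolate results
#'   (variants, segments, copy_events, mito, candidates, chimeras,
#'   summary), cohort tally, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  known <- c("seed", "genome", "isolates", "reads", "params", "outdir",
             "line_id", "cycles")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  seed <- config$seed %||% 1L
  p <- config$params %||% list()
  k <- p$k %||% 17L
  window <- p$window %||% 1000L
  min_depth <- p$min_depth %||% 10L
  min_af <- p$min_af %||% 0.8
  min_fraction <- p$min_fraction %||% 0.10
  radius <- p$radius %||% 500L
  chim_window <- p$chimera_window %||% 3000L
  carryover <- p$carryover %||% 0.07

  outdir <- config$outdir
  emit <- function(fun, ...) if (!is.null(outdir)) fun(...)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gargs <- config$genome %||% list()
  gargs$seed <- gargs$seed %||% seed
  reference <- stage("simulate", build_reference(do.call(genome_spec, gargs)))
  emit(write_fasta, reference$sequences,
       file.path(outdir, "reference.fasta"))

  rargs <- config$reads %||% list()
  rargs$seed <- rargs$seed %||% seed
  rp <- do.call(read_sim_params, rargs)
  index <- stage("map", build_index(reference, k = k))

  run_isolate <- function(genome, label, sub_seed) {
    rp_i <- rp; rp_i$seed <- derive_seed(sub_seed, 101)
    reads <- stage("simulate", simulate_reads(genome, rp_i))
    aln <- stage("map", map_reads(reads, index))
    track <- stage("map", compute_coverage(aln, window = window))
    list(reads = reads, alignments = aln, track = track)
  }

  carried <- parent_genome(reference)
  parent <- run_isolate(carried, "parent", seed)
  parent_calls <- stage("call", call_pileup(parent$alignments, reference,
                                            min_depth, min_af))
  parent_amb <- stage("call", parent_ambiguous_regions(parent$alignments,
                                                       reference, min_depth))
  parent_disc <- stage("recomb", extract_discordant(parent$alignments,
                                                    rp$insert_mean,
                                                    rp$insert_sd))
  parent_cand <- stage("recomb", cluster_evidence(parent_disc,
                                                  parent$alignments, radius,
                                                  rp$insert_mean,
                                                  rp$read_length))
  emit(write_sam, parent$alignments, file.path(outdir, "parent.sam"))

  isolates <- config$isolates %||% list()
  results <- list()
  summaries <- list()
  for (iso in names(isolates)) {
    ledger <- truth_ledger(iso, isolates[[iso]])
    genome <- stage("simulate", inject_events(carried, ledger))
    r <- run_isolate(genome, iso, derive_seed(seed, match(iso, names(isolates))))
    calls <- stage("call", call_pileup(r$alignments, reference, min_depth,
                                       min_af))
    calls <- stage("call", subtract_parent(calls, parent_calls, parent_amb))
    calls <- stage("call", annotate_effects(calls, reference$orfs, reference))
    segs <- stage("cnv", segment_coverage(r$track))
    events <- stage("cnv", classify_events(segs, reference$homeology_map,
                                           reference$orfs))
    mito <- stage("cnv", classify_mito(r$track, isolate_id = iso))
    disc <- stage("recomb", extract_discordant(r$alignments, rp$insert_mean,
                                               rp$insert_sd))
    cand <- stage("recomb", cluster_evidence(disc, r$alignments, radius,
                                             rp$insert_mean, rp$read_length))
    cand <- stage("recomb", filter_candidates(cand, parent_cand, min_fraction))
    cand <- stage("recomb", link_to_copy_events(cand, events, window))
    chims <- list()
    for (ci in seq_len(nrow(cand))) {
      ch <- stage("chimera", call_chimera(cand[ci, ], r$alignments, r$reads,
                                          reference, chim_window))
      if (inherits(ch, "chimera_result"))
        chims[[length(chims) + 1]] <- ch
    }
    summ <- stage("summarize", isolate_summary(
      iso, config$line_id %||% "SIM", config$cycles %||% 29L, calls, events,
      mito, carryover))
    if (!is.null(outdir)) {
      write_fasta(genome, file.path(outdir, paste0(iso, ".fasta")))
      write_sam(r$alignments, file.path(outdir, paste0(iso, ".sam")))
      write_vcf(calls, file.path(outdir, paste0(iso, ".vcf")))
      write_segments_bed(segs, file.path(outdir, paste0(iso, ".cn.bed")))
      write_candidates_tsv(cand, file.path(outdir, paste0(iso, ".recomb.tsv")))
      write_ledger(ledger, file.path(outdir, paste0(iso, ".truth.tsv")))
    }
    results[[iso]] <- list(ledger = ledger, variants = calls, segments = segs,
                           copy_events = events, mito = mito,
                           candidates = cand, chimeras = chims,
                           summary = summ)
    summaries[[iso]] <- summ
  }

  cohort <- if (length(summaries))
    stage("summarize", tally_cohort(do.call(rbind, summaries))) else NULL

  manifest <- list(package_version = as.character(utils::packageVersion("hybriddyn")),
                   seed = seed,
                   params = list(k = k, window = window, min_depth = min_depth,
                                 min_af = min_af, min_fraction = min_fraction,
                                 radius = radius, chimera_window = chim_window,
                                 carryover = carryover),
                   read_params = unclass(rp),
                   isolates = names(isolates))
  if (!is.null(outdir)) {
    mtxt <- vapply(names(manifest), function(nm)
      paste0(nm, "\t", paste(unlist(manifest[[nm]]), collapse = ",")),
      character(1))
    writeLines(mtxt, file.path(outdir, "manifest.tsv"))
  }
  list(reference = reference,
       parent = list(calls = parent_calls, candidates = parent_cand),
       isolates = results, cohort = cohort, manifest = manifest)
}

#' Validate the packaged in-paper tables
#'
#' Schema and internal-consistency checks on the packaged per-isolate and
#' recombination fixtures: generation counts are 4 generations/cycle;
#' breakpoint-interval widths agree between the two loci of each ORF
#' record; printed chimera lengths match the closed-form reconstruction
#' geometry, with a whitelist for the two rows whose printed values
#' deviate from the closed form by one base.
#'
#' @param table2,table3 fixture data.frames; default the packaged files.
#' @param closed_form_whitelist locus-1 names exempt from the closed-form
#'   length check.
#' @return list with per-check results; stops on schema violations.
#' @export
validate_fixtures <- function(table2 = read_table2(), table3 = read_table3(),
                              closed_form_whitelist = c("SeTOP1",
                                                        "ScHMLALPHA2")) {
  need2 <- c("line_id", "cycles", "generations", "isolate_id", "mito_status",
             "aneuploidy", "segmental", "snps", "indels")
  missing2 <- setdiff(need2, names(table2))
  if (length(missing2))
    stop("per-isolate table lacks columns: ", paste(missing2, collapse = ", "))
  need3 <- c("recombination", "isolates", "locus1_name", "locus1_length",
             "locus1_start", "locus1_end", "locus2_name", "locus2_length",
             "locus2_start", "locus2_end", "homology", "chimera_length",
             "locus_class")
  missing3 <- setdiff(need3, names(table3))
  if (length(missing3))
    stop("recombination table lacks columns: ", paste(missing3, collapse = ", "))

  gen_ok <- table2$generations == generations_from_cycles(table2$cycles)
  if (!all(gen_ok))
    stop("generation count inconsistent for isolate(s): ",
         paste(table2$isolate_id[!gen_ok], collapse = ", "))

  orf <- table3[table3$locus_class == "ORF", , drop = FALSE]
  w1 <- orf$locus1_end - orf$locus1_start + 1
  w2 <- orf$locus2_end - orf$locus2_start + 1
  bad_w <- which(w1 != w2)
  if (length(bad_w))
    stop("interval width mismatch in recombination record(s): ",
         paste(orf$locus1_name[bad_w], collapse = ", "))

  cf <- chimera_length_closed_form(orf$locus1_start, orf$locus2_length,
                                   orf$locus2_start)
  checked <- !(orf$locus1_name %in% closed_form_whitelist)
  cf_ok <- cf[checked] == orf$chimera_length[checked]
  if (!all(cf_ok))
    stop("closed-form chimera length mismatch in record(s): ",
         paste(orf$locus1_name[checked][!cf_ok], collapse = ", "))

  hom_ok <- orf$homology == "<70" |
    (!is.na(suppressWarnings(as.numeric(orf$homology))) &
       suppressWarnings(as.numeric(orf$homology)) > 0 &
       suppressWarnings(as.numeric(orf$homology)) <= 100)
  if (!all(hom_ok))
    stop("invalid homology entries: ",
         paste(orf$locus1_name[!hom_ok], collapse = ", "))

  list(n_isolates = nrow(table2), n_recombination_records = nrow(table3),
       generations_ok = TRUE, interval_widths_ok = TRUE,
       closed_form_ok = TRUE,
       closed_form_whitelisted = intersect(orf$locus1_name,
                                           closed_form_whitelist))
}
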