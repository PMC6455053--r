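test_that("generation accounting reproduces the printed cycle arithmetic", {
  expect_equal(generations_from_cycles(29), 116)
  expect_equal(generations_from_cycles(116), 464)
  expect_equal(generations_from_cycles(0), 0)
  # 7% carry-over: log2(1/0.07) = 3.84 rounds to 4 generations per cycle
  expect_equal(generations_from_cycles(1, 0.07), 4)
  expect_error(generations_from_cycles(10, 1.2), "carryover")
  expect_error(generations_from_cycles(10, 0), "carryover")
})

test_that("per-division frequencies and per-nucleotide rates scale correctly", {
  expect_equal(per_division_frequency(2, 52), 2 / 52)
  expect_equal(round(per_division_frequency(2, 52), 4), 0.0385)
  expect_equal(per_division_frequency(0, 100), 0)
  expect_equal(round(per_division_frequency(1, 468), 5), 0.00214)
  expect_error(per_division_frequency(1, 0), "positive")
  # linearity / inverse proportionality
  expect_equal(per_division_frequency(6, 100), 3 * per_division_frequency(2, 100))
  expect_equal(per_division_frequency(2, 200), per_division_frequency(2, 100) / 2)

  expect_equal(per_nucleotide_rate(0.004), 1.7e-10)
  expect_equal(per_nucleotide_rate(0.039), 1.6e-9)
  expect_equal(per_nucleotide_rate(0), 0)
})

test_that("cohort tallies match the packaged per-isolate table", {
  t2 <- read_table2()
  expect_equal(nrow(t2), 55)
  tl <- tally_cohort(t2)
  expect_equal(tl$n_whole_chromosome_aneuploidy, 5)
  expect_equal(tl$n_mito_loss, 15)
  expect_equal(tl$n_rho_minus, 14)
  expect_equal(tl$n_rho_zero, 1)
  expect_equal(tl$n_segmental, 29)
  expect_equal(unname(tl$recurrence["ΔSc(YKL032C-YKL054C)"]), 13L)
  expect_true(tl$generations_consistent)
  # permutation invariance
  tl2 <- tally_cohort(t2[sample(nrow(t2)), ])
  expect_equal(tl2$n_segmental, tl$n_segmental)
  expect_equal(sort(tl2$recurrence), sort(tl$recurrence))
  # duplicate isolate ids are rejected
  expect_error(tally_cohort(rbind(t2, t2[1, ])), "duplicate")
})

test_that("per-line frequency ranges are computed per mutation class", {
  tl <- tally_cohort(read_table2())
  pl <- tl$per_line_frequencies
  expect_setequal(unique(pl$line_id),
                  c("LG12.1", "LG12.2", "LG30.1", "LG30.2", "HG12.1", "HG12.2"))
  expect_true(all(pl$min_frequency <= pl$max_frequency))
  # the highest observed SNP frequency in the cohort: 3 SNPs at 464
  # generations (within the printed per-division range 0.004-0.039)
  snp_max <- max(pl$max_frequency[pl$class == "SNP"])
  expect_lte(snp_max, 0.039)
  expect_gte(snp_max, 0.004)
})

test_that("recombination summaries match the packaged recombination table", {
  t3 <- read_table3()
  sm <- summarize_recombinations(t3)
  expect_equal(sm$n_total, 26)
  expect_equal(sm$n_in_orf, 23)
  expect_equal(sm$median_homology, 82.41)
  expect_false(sm$median_homology_censored)
  expect_equal(sm$min_interval_width, 2)
  expect_equal(sm$max_interval_width, 633)
  # width mismatch fails loudly naming the record
  bad <- t3
  bad$locus2_end[1] <- bad$locus2_end[1] + 5
  expect_error(summarize_recombinations(bad), bad$locus1_name[1])
})

test_that("censored median ranks '<70' below any numeric value", {
  t3 <- read_table3()
  orf <- t3[t3$locus_class == "ORF", ]
  cens <- orf$homology == "<70"
  base <- summarize_recombinations(t3)$median_homology
  # substituting arbitrary numeric values below 70 cannot change the median
  set.seed(11)
  for (i in 1:10) {
    vals <- suppressWarnings(as.numeric(orf$homology))
    vals[cens] <- runif(sum(cens), 0, 69.9)
    expect_equal(stats::median(vals), base)
  }
})

test_that("isolate summaries feed the cohort tally", {
  fx <- fixture_reference()
  iso1 <- fixture_iso1()
  calls <- isolate_calls(iso1)
  evs <- classify_events(segment_coverage(iso1$track), fx$ref$homeology_map,
                         fx$ref$orfs)
  mito <- classify_mito(iso1$track, isolate_id = "iso1")
  s <- isolate_summary("iso1", "SIM1", 29, calls, evs, mito)
  expect_equal(s$generations, 116)
  expect_equal(s$mito_status, "rho0")
  expect_match(s$aneuploidy, "2xB\\(CHRII\\)")
  tl <- tally_cohort(s)
  expect_equal(tl$n_isolates, 1)
  expect_equal(tl$n_whole_chromosome_aneuploidy, 1)
  expect_equal(tl$n_mito_loss, 1)
})
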