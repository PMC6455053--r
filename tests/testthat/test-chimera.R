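test_that("local read extraction applies the mate rule", {
  mk_aln <- function(id, mate, contig, pos) {
    data.frame(read_id = paste0(id, "/", mate), mate = mate, pair = 1L,
               contig = contig, pos = as.integer(pos), strand = "+",
               cigar = "150M", seq = "", score = 150L, nm = 0L,
               is_split = FALSE, ambiguous = FALSE, mapped = TRUE,
               split_contig = NA_character_, split_pos = NA_integer_,
               split_len = NA_integer_, tie_contig = NA_character_,
               tie_pos = NA_integer_, mate_contig = NA_character_,
               mate_pos = NA_integer_, mate_strand = NA_character_,
               stringsAsFactors = FALSE)
  }
  site <- list(contig1 = "c1", pos1 = 10000L, contig2 = "c2", pos2 = 50000L)
  aln <- rbind(
    mk_aln("near", 1, "c1", 10000 + 2999),   # within 3 kbp: included
    mk_aln("near", 2, "c9", 999999),
    mk_aln("matey", 1, "c1", 10000 + 3001),  # outside on its own
    mk_aln("matey", 2, "c1", 10000 + 100),   # ... but its mate is inside
    mk_aln("far", 1, "c1", 60000),           # 50 kb away, mate too
    mk_aln("far", 2, "c1", 60300))
  reads <- data.frame(read_id = c("near", "matey", "far"),
                      seq1 = "A", seq2 = "T", stringsAsFactors = FALSE)
  out <- extract_local_reads(aln, site, reads)
  expect_setequal(out$read_id, c("near", "matey"))
})

test_that("greedy assembly reconstructs clonal local sequence exactly", {
  fx <- fixture_reference()
  s <- as.character(fx$ref$sequences[["A_CHRI"]])
  region <- substr(s, 30001, 32000)
  reads <- simulate_reads(c(r = region),
                          read_sim_params(insert_mean = 400, depth = 30,
                                          seed = 33))
  asm <- assemble_local(reads)
  expect_identical(asm$status, "ok")
  expect_gte(max(nchar(asm$contigs)), 1900)
  big <- asm$contigs[1]
  expect_true(grepl(big, region, fixed = TRUE) ||
                grepl(hybriddyn:::rc(big), region, fixed = TRUE))

  # reads from two disjoint loci assemble into non-spanning contigs
  r2 <- simulate_reads(c(a = substr(s, 1, 1200), b = substr(s, 20001, 21200)),
                       read_sim_params(insert_mean = 400, depth = 30, seed = 34))
  asm2 <- assemble_local(r2)
  expect_gte(length(asm2$contigs), 2)
  expect_true(all(nchar(asm2$contigs) < 2000))

  expect_error(assemble_local(reads[1:5, ]), "at least 10")
})

test_that("locate_interval matches the brute-force identical-run oracle", {
  for (seed in 1:6) {
    pair <- make_orf_pair(len = 1200, identity = 0.85, seed = seed)
    bp <- 200 + 37 * seed
    chim <- paste0(substr(pair$orf1, 1, bp),
                   substr(pair$orf2, bp + 1, nchar(pair$orf2)))
    iv <- locate_interval(chim, pair$orf1, pair$orf2)
    expect_identical(iv$status, "ok")
    # the interval contains the injected breakpoint
    expect_lte(iv$a1, bp)
    expect_gte(iv$b1, bp)
    orc <- oracle_identical_run(pair$orf1, pair$orf2, iv$prefix_end)
    expect_equal(iv$a1, orc$a1)
    expect_equal(iv$b1, orc$b1)
    expect_equal(iv$a2, orc$a2)
    expect_equal(iv$b2, orc$b2)
    expect_equal(iv$width, orc$width)
    expect_equal(iv$b1 - iv$a1, iv$b2 - iv$a2)
  }
})

test_that("fully identical ORFs give a full-length ambiguity interval", {
  orf <- paste0("ATG", strrep("CAT", 209), "TAA")  # 633 bp
  iv <- locate_interval(paste0("GG", orf, "CC"), orf, orf)
  expect_identical(iv$status, "ok")
  expect_equal(c(iv$a1, iv$b1, iv$a2, iv$b2), c(1, 633, 1, 633))
  expect_equal(iv$width, 633)
  res <- reconstruct_chimera(orf, orf, iv)
  expect_identical(res$chimera_sequence, orf)
  expect_equal(res$chimera_length, 633)
  expect_equal(res$homology_percent, 100)
})

test_that("a junction inside a 2 bp identical run is resolved to width 2", {
  # hand-built pair: identical only at the two junction positions
  #   orf1: ATG AAA CCC GGG TTT TAA
  #   orf2: ATG CAC CCA GAG TAT TAA   (shares 'CC' at positions 7-8)
  orf1 <- "ATGAAACCCGGGTTTTAA"
  orf2 <- "ATGCACCCAGAGTATTAA"
  # crossover inside the shared CC run (orf1[7..8] == orf2[6..7] is not the
  # aligned pair here; use the aligned run containing orf1 position 8)
  chim <- paste0(substr(orf1, 1, 8), substr(orf2, 9, 18))
  iv <- locate_interval(chim, orf1, orf2)
  expect_identical(iv$status, "ok")
  expect_lte(iv$width, 4)
  expect_gte(iv$width, 1)
  res <- reconstruct_chimera(orf1, orf2, iv)
  expect_identical(res$chimera_sequence, chim)
})

test_that("chimera length follows the closed-form table geometry", {
  expect_equal(chimera_length_closed_form(944, 2217, 1281), 1881)
  expect_equal(chimera_length_closed_form(711, 4752, 712), 4752)
  expect_equal(chimera_length_closed_form(1551, 3441, 1561), 3432)
})

test_that("frame and stop-codon analysis follows the genetic code", {
  fr <- analyze_frame("ATGAAATTTTAA")
  expect_true(fr$in_frame)
  expect_false(fr$premature_stop)
  expect_false(analyze_frame(paste0("ATGAAATTTTA"))$in_frame)  # 3k+2
  early <- analyze_frame("ATGTAAAAATAA")
  expect_true(early$premature_stop)
  expect_error(analyze_frame("CCCAAATTT"), "start codon")
})

test_that("homology percentages behave across the identity range", {
  orf <- paste0("ATG", strrep("GATTACA", 60), "TAA")
  expect_equal(homology_percent(orf, orf), 100)
  pair <- make_orf_pair(len = 1200, identity = 0.85, seed = 3)
  h <- homology_percent(pair$orf1, pair$orf2)
  expect_gte(h, 82)
  expect_lte(h, 88)
  set.seed(5)
  r1 <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  r2 <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  expect_lt(homology_percent(r1, r2), 70)
  expect_identical(format_homology(65), "<70")
  expect_identical(format_homology(82.41), "82.41%")
})

test_that("ambiguity width does not grow as homology falls", {
  widths <- function(identity) {
    vapply(1:8, function(seed) {
      pair <- make_orf_pair(len = 900, identity = identity, seed = 100 + seed)
      bp <- 400
      chim <- paste0(substr(pair$orf1, 1, bp),
                     substr(pair$orf2, bp + 1, nchar(pair$orf2)))
      iv <- locate_interval(chim, pair$orf1, pair$orf2)
      if (identical(iv$status, "ok")) iv$width else NA_real_
    }, numeric(1))
  }
  w_hi <- widths(0.95)
  w_lo <- widths(0.80)
  expect_lte(mean(w_lo, na.rm = TRUE), mean(w_hi, na.rm = TRUE))
})

test_that("the end-to-end chimera at an LOH junction equals the truth splice", {
  fx <- fixture_reference()
  iso1 <- fixture_iso1()
  kept <- retained_candidates(iso1)
  loh <- kept[(kept$contig1 == "A_CHRI" & kept$contig2 == "B_CHRI") |
                (kept$contig1 == "B_CHRI" & kept$contig2 == "A_CHRI"), ][1, ]
  ch <- call_chimera(loh, iso1$alignments, iso1$reads, fx$ref)
  expect_s3_class(ch, "chimera_result")
  tc <- truth_chimera(fx$ref, "g003", 600)
  expect_identical(ch$chimera_sequence, tc$chimera)
  expect_true(ch$interval$a1 <= 600 && 600 <= ch$interval$b1)
  expect_true(ch$in_frame)
  expect_false(ch$premature_stop)
})
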