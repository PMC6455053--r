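test_that("build_reference emits the right contigs with valid homeolog ORFs", {
  fx <- fixture_reference()
  ref <- fx$ref
  expect_setequal(names(ref$sequences),
                  c("A_CHRI", "A_CHRII", "B_CHRI", "B_CHRII", "A_MT", "B_MT"))
  h <- ref$homologs
  expect_equal(nrow(h), 4)
  expect_true(all(h$length %% 3 == 0))
  # both loci begin with a start codon, end with a stop, no internal stops
  for (r in seq_len(nrow(h))) {
    for (side in c("a", "b")) {
      orf <- substr(as.character(ref$sequences[[h[[paste0("contig_", side)]][r]]]),
                    h[[paste0("start_", side)]][r], h[[paste0("end_", side)]][r])
      expect_identical(substr(orf, 1, 3), "ATG")
      n <- nchar(orf)
      cods <- substring(orf, seq(1, n - 2, 3), seq(3, n, 3))
      expect_true(cods[length(cods)] %in% c("TAA", "TAG", "TGA"))
      expect_false(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("realized homeolog identity tracks the target", {
  fx <- fixture_reference()
  # direct-comparison oracle: count matching positions
  h <- fx$ref$homologs
  for (r in seq_len(nrow(h))) {
    oa <- strsplit(substr(as.character(fx$ref$sequences[[h$contig_a[r]]]),
                          h$start_a[r], h$end_a[r]), "")[[1]]
    ob <- strsplit(substr(as.character(fx$ref$sequences[[h$contig_b[r]]]),
                          h$start_b[r], h$end_b[r]), "")[[1]]
    direct <- mean(oa == ob)
    expect_equal(h$realized_identity[r], direct)
    expect_gte(direct, 0.82)
    expect_lte(direct, 0.88)
  }
  # identity 1 target: no mutations at all
  perfect <- build_reference(genome_spec(chromosomes_per_subgenome = 1,
                                         chromosome_lengths = 20000,
                                         n_homolog_pairs = 2,
                                         homolog_length_range = c(600, 900),
                                         target_identity = 1, seed = 3))
  expect_true(all(perfect$homologs$realized_identity == 1))
})

test_that("the same seed reproduces a byte-identical genome", {
  s <- genome_spec(chromosomes_per_subgenome = 1, chromosome_lengths = 15000,
                   n_homolog_pairs = 1, seed = 99)
  r1 <- build_reference(s)
  r2 <- build_reference(s)
  expect_identical(as.character(r1$sequences), as.character(r2$sequences))
})

test_that("inject_events replays point mutations exactly (diff oracle)", {
  fx <- fixture_reference()
  pg <- parent_genome(fx$ref)
  # empty ledger: identity
  empty <- inject_events(pg, truth_ledger("x", data.frame(
    kind = character(0), contig = character(0))))
  expect_identical(as.character(empty), as.character(pg))
  # single SNP: exactly one position differs
  s0 <- as.character(pg[["A_CHRI"]])
  alt <- setdiff(c("A", "C", "G", "T"), substr(s0, 5000, 5000))[1]
  g <- inject_events(pg, truth_ledger("x", ev_snp("A_CHRI", 5000, alt)))
  d <- which(strsplit(as.character(g[["A_CHRI"]]), "")[[1]] !=
               strsplit(s0, "")[[1]])
  expect_identical(d, 5000L)
  # several SNPs: whole-sequence diff recovers each exactly
  evs <- random_point_events(fx$ref, n_snp = 5, n_indel = 0, seed = 11)
  g2 <- inject_events(pg, truth_ledger("x", evs))
  for (ctg in unique(evs$contig)) {
    diffs <- which(strsplit(as.character(g2[[ctg]]), "")[[1]] !=
                     strsplit(as.character(pg[[ctg]]), "")[[1]])
    expect_setequal(diffs, evs$start[evs$contig == ctg])
  }
})

test_that("chromosome-level events add and remove contigs", {
  fx <- fixture_reference()
  pg <- parent_genome(fx$ref)
  g <- inject_events(pg, truth_ledger("x", bind_events(
    ev_chr_gain("A_CHRI"), ev_chr_loss("B_CHRII"), ev_mt_loss("B_MT"))))
  expect_true("A_CHRI_gain" %in% names(g))
  expect_identical(as.character(g[["A_CHRI_gain"]]),
                   as.character(pg[["A_CHRI"]]))
  expect_false("B_CHRII" %in% names(g))
  expect_false("B_MT" %in% names(g))
})

test_that("overlapping events are rejected with the collision listed", {
  fx <- fixture_reference()
  ev <- bind_events(ev_seg_del("A_CHRI", 1000, 2000),
                    ev_snp("A_CHRI", 1500, "A"))
  expect_error(inject_events(fx$ref, truth_ledger("x", ev)), "overlap")
})

test_that("LOH through a homeolog pair yields the reconstructable chimera", {
  fx <- fixture_reference()
  ref <- fx$ref
  bp <- 450L
  ev <- ev_loh_through_pair(ref, "g002", bp)
  g <- inject_events(parent_genome(ref), truth_ledger("x", ev))
  h <- ref$homologs[ref$homologs$gene_id == "g002", ]
  tc <- truth_chimera(ref, "g002", bp)
  iso_orf <- substr(as.character(g[[h$contig_b]]), h$start_b, h$end_b)
  expect_identical(iso_orf, tc$chimera)
  # and the chimera module reproduces it from the interval
  iv <- locate_interval(tc$chimera, tc$orf_b, tc$orf_a)
  expect_identical(iv$status, "ok")
  res <- reconstruct_chimera(tc$orf_b, tc$orf_a, iv)
  expect_identical(res$chimera_sequence, tc$chimera)
})

test_that("read simulation matches its sampling contract", {
  fx <- fixture_reference()
  pg <- parent_genome(fx$ref)["A_CHRI"]
  reads <- simulate_reads(pg, read_sim_params(depth = 30, seed = 21))
  total_bases <- sum(nchar(reads$seq1)) + sum(nchar(reads$seq2))
  expect_lt(abs(total_bases - 30 * 40000) / (30 * 40000), 0.10)
  # error-free reads are exact substrings of their source
  s <- as.character(pg[[1]])
  some <- reads[seq(1, nrow(reads), length.out = 50), ]
  expect_true(all(vapply(seq_len(nrow(some)), function(i) {
    grepl(some$seq1[i], s, fixed = TRUE)
  }, logical(1))))
  # determinism: byte-identical FASTQ on rerun
  f1a <- tempfile(); f2a <- tempfile(); f1b <- tempfile(); f2b <- tempfile()
  write_fastq(reads, f1a, f2a)
  write_fastq(simulate_reads(pg, read_sim_params(depth = 30, seed = 21)),
              f1b, f2b)
  expect_identical(readLines(f1a), readLines(f1b))
  expect_identical(readLines(f2a), readLines(f2b))
  unlink(c(f1a, f2a, f1b, f2b))
})

test_that("read simulation rejects an insert longer than the shortest contig", {
  expect_error(simulate_reads(c(c1 = strrep("ACGT", 50)),
                              read_sim_params(insert_mean = 450)),
               "insert_mean")
})

test_that("simulated reads at error_rate 0 map back to their origin cleanly", {
  fx <- fixture_reference()
  par <- fixture_parent()
  m1 <- par$alignments[par$alignments$mate == 1, ]
  ok <- m1$mapped & m1$contig == par$reads$contig &
    abs(m1$pos - par$reads$start) <= 2 & m1$nm == 0
  expect_gte(mean(ok), 0.99)
})
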