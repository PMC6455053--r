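test_that("the seed index records L-k+1 positions and flags multi-mappers", {
  idx <- build_index(c(c1 = "ACGTACGTACGTACGTACGT"), k = 11)
  expect_equal(idx$n_positions, 20 - 11 + 1)
  # duplicated sequence: every k-mer is multi-mapping
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  idx2 <- build_index(c(c1 = s, c2 = s), k = 13)
  expect_gt(idx2$n_multi, 0)
  expect_equal(length(kmer_positions(idx2, substr(s, 1, 13))), 2)
  expect_error(build_index(character(0)), "empty")
  expect_error(build_index(c(c1 = "ACGTACGT"), k = 11), "shortest contig")
  expect_error(build_index(c(c1 = "ACGTACGT"), k = 5), "between 11 and 31")
})

test_that("homeologous loci share flagged k-mers", {
  fx <- fixture_reference()
  h <- fx$ref$homologs[1, ]
  orf_a <- substr(as.character(fx$ref$sequences[[h$contig_a]]), h$start_a, h$end_a)
  orf_b <- substr(as.character(fx$ref$sequences[[h$contig_b]]), h$start_b, h$end_b)
  # direct k-mer set intersection oracle
  k <- fx$index$k
  kms <- function(s) unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  shared <- intersect(kms(orf_a), kms(orf_b))
  expect_gt(length(shared), 0)
  expect_true(all(vapply(shared[seq_len(min(5, length(shared)))], function(km)
    length(kmer_positions(fx$index, km)) >= 2, logical(1))))
})

test_that("error-free unique-region reads map exactly and deterministically", {
  fx <- fixture_reference()
  s <- as.character(fx$ref$sequences[["A_CHRI"]])
  read <- substr(s, 1001, 1150)
  aln <- map_reads(c(r1 = read), fx$index)
  expect_identical(aln$contig, "A_CHRI")
  expect_identical(aln$pos, 1001L)
  expect_identical(aln$strand, "+")
  expect_identical(aln$nm, 0L)
  # reverse complement maps to the same locus on the minus strand
  aln2 <- map_reads(c(r1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(read)))), fx$index)
  expect_identical(aln2$pos, 1001L)
  expect_identical(aln2$strand, "-")
  # determinism
  par <- fixture_parent()
  again <- map_reads(par$reads[1:200, ], fx$index)
  expect_identical(again, map_reads(par$reads[1:200, ], fx$index))
})

test_that("a read across an LOH junction is reported split at the junction", {
  fx <- fixture_reference()
  iso <- fixture_iso1()
  h <- fx$ref$homologs[fx$ref$homologs$gene_id == "g003", ]
  junction <- h$start_b + 600L  # first replaced base on the acceptor
  g <- as.character(iso$genome[["B_CHRI"]])
  read <- substr(g, junction - 75, junction + 74)
  aln <- map_reads(c(jr = read), fx$index)
  expect_true(aln$is_split)
  ends <- c(aln$contig, aln$split_contig)
  expect_setequal(ends, c("B_CHRI", "A_CHRI"))
  junction_here <- aln$pos + as.integer(sub("M.*", "", aln$cigar)) - 1L
  expect_lt(abs(junction_here - junction), 40)
})

test_that("coverage windows reflect uniform depth and tile the contigs", {
  fx <- fixture_reference()
  par <- fixture_parent()
  trk <- par$track
  lens <- attr(trk, "contig_lengths")
  for (ctg in names(lens))
    expect_equal(sum(trk$contig == ctg), ceiling(lens[[ctg]] / 1000))
  nuc <- trk[!grepl("_MT$", trk$contig) & trk$end - trk$start == 999, ]
  expect_true(all(nuc$depth >= 15 & nuc$depth <= 45))
  expect_gt(attr(trk, "genome_median"), 25)
  expect_lt(attr(trk, "genome_median"), 35)
  # uncovered mito contig (not carried) is all zero
  expect_true(all(trk$depth[trk$contig == "A_MT"] == 0))
})

test_that("window depths integrate to the total aligned bases", {
  # two exact reads on a 2 kb contig, window 1000: depth 0.15 each window
  set.seed(3)
  ref <- c(c1 = paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                      collapse = ""))
  idx <- build_index(ref, k = 11)
  aln <- map_reads(c(r1 = substr(ref, 101, 250), r2 = substr(ref, 1101, 1250)),
                   idx)
  trk <- compute_coverage(aln, window = 1000,
                          contig_lengths = c(c1 = 2000L))
  expect_equal(trk$depth, c(0.15, 0.15))
  expect_equal(sum(trk$depth * 1000), attr(trk, "total_aligned"))
  # no alignments: all-zero track, not an error
  none <- map_reads(c(r1 = strrep("N", 150)), idx)
  trk0 <- compute_coverage(none, window = 1000, contig_lengths = c(c1 = 2000L))
  expect_true(all(trk0$depth == 0))
})

test_that("discordant extraction classifies pairs by the stated rules", {
  par <- fixture_parent()
  disc <- extract_discordant(par$alignments, 450, 50)
  # clean parent: essentially no junction evidence
  expect_equal(sum(disc$class %in% c("inter_contig", "split_read")), 0)
  expect_lt(nrow(disc) / nrow(par$reads), 5e-3)

  # constructed cases
  mk <- function(c1, p1, s1, c2, p2, s2) {
    a <- data.frame(
      read_id = c("p/1", "p/2"), mate = 1:2, pair = 1L,
      contig = c(c1, c2), pos = c(p1, p2), strand = c(s1, s2),
      cigar = "150M", seq = strrep("A", 150), score = 150L, nm = 0L,
      is_split = FALSE, ambiguous = FALSE, mapped = TRUE,
      split_contig = NA_character_, split_pos = NA_integer_,
      split_len = NA_integer_, tie_contig = NA_character_,
      tie_pos = NA_integer_,
      mate_contig = c(c2, c1), mate_pos = c(p2, p1),
      mate_strand = c(s2, s1), stringsAsFactors = FALSE)
    class(a) <- c("alignments", class(a))
    a
  }
  expect_equal(extract_discordant(mk("c1", 100, "+", "c2", 5000, "-"),
                                  450, 50)$class, "inter_contig")
  # insert 10 sd above the mean
  far <- extract_discordant(mk("c1", 100, "+", "c1", 100 + 450 + 500 - 150, "-"),
                            450, 50)
  expect_equal(far$class, "aberrant_insert")
  expect_equal(extract_discordant(mk("c1", 100, "+", "c1", 400, "+"),
                                  450, 50)$class, "aberrant_orientation")
  conc <- extract_discordant(mk("c1", 100, "+", "c1", 400, "-"), 450, 50)
  expect_equal(nrow(conc), 0)
})

test_that("SAM output round-trips through the module reader", {
  par <- fixture_parent()
  aln <- par$alignments[1:400, ]
  f <- tempfile(fileext = ".sam")
  write_sam(aln, f)
  back <- read_sam(f)
  expect_equal(nrow(back), 400)
  keep <- c("contig", "pos", "strand", "cigar", "seq", "mapped")
  expect_identical(back[, keep], aln[, keep])
  expect_identical(attr(back, "contig_lengths"), attr(aln, "contig_lengths"))
  # byte determinism
  f2 <- tempfile(fileext = ".sam")
  write_sam(aln, f2)
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2))
})
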