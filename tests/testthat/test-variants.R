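test_that("clonal injected SNPs and INDELs are recovered completely", {
  fx <- fixture_reference()
  for (run in list(fixture_iso1(), fixture_iso2())) {
    calls <- isolate_calls(run)
    truth <- truth_point_variants(run$ledger, fx$ref)
    key <- function(x) paste(x$contig, x$pos, x$ref, x$alt, x$kind)
    # recall and precision both 100% in uniquely mappable regions
    expect_setequal(key(calls[, names(truth)]), key(truth))
    snps <- calls[calls$kind == "SNP", ]
    expect_true(all(snps$alt_fraction == 1.0))
  }
})

test_that("an injected 3 bp deletion yields one INDEL call 3 bp shorter", {
  fx <- fixture_reference()
  runs <- list(fixture_iso1(), fixture_iso2())
  found <- FALSE
  for (run in runs) {
    tr <- run$ledger$events
    del3 <- tr[tr$kind == "INDEL" & !is.na(tr$indel_len) & tr$indel_len == -3, ]
    if (!nrow(del3)) next
    found <- TRUE
    calls <- isolate_calls(run)
    hit <- calls[calls$kind == "INDEL" & calls$contig == del3$contig[1] &
                   abs(calls$pos - del3$start[1]) <= 5, ]
    expect_equal(nrow(hit), 1)
    expect_equal(nchar(hit$ref) - nchar(hit$alt), 3)
  }
  expect_true(found)
})

test_that("sequencing errors alone produce no calls at clonal thresholds", {
  # binomial argument: P(>=90% alt at depth >=10 | error rate 1e-3) is
  # negligible, so an event-free noisy simulation yields zero calls
  ref <- build_reference(genome_spec(chromosomes_per_subgenome = 1,
                                     chromosome_lengths = 20000,
                                     n_homolog_pairs = 1, seed = 17))
  idx <- build_index(ref)
  run <- run_genome(parent_genome(ref), idx, seed = 18, error_rate = 0.001)
  calls <- call_pileup(run$alignments, ref, min_depth = 10,
                       min_alt_fraction = 0.9)
  expect_equal(nrow(calls), 0)
})

test_that("parent self-subtraction leaves no variants", {
  fx <- fixture_reference()
  par <- fixture_parent()
  self <- subtract_parent(par$calls, par$calls, par$ambiguous)
  expect_equal(nrow(self), 0)
})

test_that("subtraction removes parent-shared and parent-ambiguous calls", {
  mk_calls <- function(df, ref_contigs = c("c1", "c2")) {
    attr(df, "reference_contigs") <- ref_contigs
    class(df) <- c("variant_calls", class(df))
    df
  }
  iso <- mk_calls(data.frame(contig = c("c1", "c1", "c2"),
                             pos = c(100L, 200L, 300L),
                             ref = c("A", "C", "G"), alt = c("T", "T", "A"),
                             depth = 30, alt_count = 30, alt_fraction = 1,
                             kind = "SNP", stringsAsFactors = FALSE))
  par <- mk_calls(data.frame(contig = "c1", pos = 100L, ref = "A", alt = "T",
                             depth = 30, alt_count = 30, alt_fraction = 1,
                             kind = "SNP", stringsAsFactors = FALSE))
  amb <- data.frame(contig = "c2", start = 250L, end = 350L)
  out <- subtract_parent(iso, par, amb)
  expect_equal(out$pos, 200L)  # de novo call retained, others disregarded
  expect_error(subtract_parent(iso, mk_calls(par, "other_ref")),
               "different references")
})

test_that("ORF effects and nomenclature follow the codon table", {
  # hand-built ORF: ATG AAA TGC GGG TAA on the plus strand at 11..25
  orf <- "ATGAAATGCGGGTAA"
  flank <- strrep("C", 10)
  seqs <- c(chr = paste0(flank, orf, strrep("C", 10)))
  orfs <- data.frame(orf_id = "Ag1", contig = "chr", start = 11L, end = 25L,
                     strand = "+", subgenome = "A", stringsAsFactors = FALSE)
  mk <- function(pos, ref, alt, kind = "SNP") {
    df <- data.frame(contig = "chr", pos = as.integer(pos), ref = ref,
                     alt = alt, depth = 30, alt_count = 30, alt_fraction = 1,
                     kind = kind, stringsAsFactors = FALSE)
    class(df) <- c("variant_calls", class(df))
    df
  }
  # AAA (Lys) -> AGA (Arg): missense at ORF position 5
  out <- annotate_effects(mk(15, "A", "G"), orfs, seqs)
  expect_equal(out$effect, "missense")
  expect_equal(out$nomenclature, "Ag1^A5G")
  expect_equal(out$orf_pos, 5L)
  # GGG -> GGA: synonymous (Gly)
  expect_equal(annotate_effects(mk(22, "G", "A"), orfs, seqs)$effect,
               "synonymous")
  # TGC (Cys) -> TGA (stop): nonsense
  expect_equal(annotate_effects(mk(19, "C", "A"), orfs, seqs)$effect,
               "nonsense")
  # 1 bp insertion after ORF pos 6: frameshift, "Ag1^6+1N"
  ins <- annotate_effects(mk(16, "A", "AT", kind = "INDEL"), orfs, seqs)
  expect_equal(ins$effect, "frameshift")
  expect_equal(ins$nomenclature, "Ag1^6+1N")
  # 3 bp deletion after ORF pos 6: in-frame
  del <- annotate_effects(mk(16, "ATGC", "A", kind = "INDEL"), orfs, seqs)
  expect_equal(del$effect, "inframe_indel")
  expect_equal(del$nomenclature, "Ag1^6-3N")
  # intergenic call
  expect_equal(annotate_effects(mk(3, "C", "A"), orfs, seqs)$effect,
               "intergenic")
  # minus-strand ORF: same ORF revcomp'd at 11..25
  seqs2 <- c(chr = paste0(flank, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(orf))), strrep("C", 10)))
  orfs2 <- orfs; orfs2$strand <- "-"
  # genomic pos 21 is ORF position 5 (A); genomic T->C is ORF A->G
  out2 <- annotate_effects(mk(21, "T", "C"), orfs2, seqs2)
  expect_equal(out2$orf_pos, 5L)
  expect_equal(out2$nomenclature, "Ag1^A5G")
  expect_equal(out2$effect, "missense")
  # invalid ORF is rejected by name
  bad <- orfs; bad$start <- 12L; bad$end <- 26L
  expect_error(annotate_effects(mk(15, "A", "G"), bad, seqs), "Ag1")
})

test_that("variant nomenclature round-trips", {
  cases <- list(
    list(orf = "ScSFL1", kind = "SNP", pos = 605L, ref = "T", alt = "A",
         len = NA_integer_),
    list(orf = "SeMED2", kind = "INDEL", pos = 462L, ref = NA_character_,
         alt = NA_character_, len = 3L),
    list(orf = "SeKEX1", kind = "INDEL", pos = 1875L, ref = NA_character_,
         alt = NA_character_, len = -6L))
  for (x in cases) {
    s <- format_variant_nomenclature(x)
    expect_identical(format_variant_nomenclature(parse_variant_nomenclature(s)), s)
  }
  expect_identical(format_variant_nomenclature(cases[[1]]), "ScSFL1^T605A")
  expect_identical(format_variant_nomenclature(cases[[2]]), "SeMED2^462+3N")
  expect_error(parse_variant_nomenclature("garbage"), "parse")
})

test_that("VCF output carries the calls", {
  iso <- fixture_iso1()
  calls <- isolate_calls(iso)
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, f)
  ln <- readLines(f)
  expect_true(any(startsWith(ln, "##fileformat=VCFv4.2")))
  body <- ln[!startsWith(ln, "#")]
  expect_equal(length(body), nrow(calls))
  expect_true(all(grepl("DP=\\d+;AF=", body)))
  unlink(f)
})
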