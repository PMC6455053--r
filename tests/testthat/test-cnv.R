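# build a coverage_track from a per-window ratio vector (depth = ratio * 30)
mk_track <- function(ratios, contig = "A_CHRI", window = 1000L) {
  n <- length(ratios)
  trk <- data.frame(contig = contig, window_index = seq_len(n),
                    start = (seq_len(n) - 1L) * window + 1L,
                    end = seq_len(n) * window, depth = ratios * 30,
                    stringsAsFactors = FALSE)
  attr(trk, "window") <- window
  attr(trk, "genome_median") <- 30
  attr(trk, "contig_lengths") <- stats::setNames(n * window, contig)
  class(trk) <- c("coverage_track", class(trk))
  trk
}

# exhaustive changepoint oracle for noiseless piecewise-constant ratios:
# boundaries wherever the value changes (instances respect min-length 3)
oracle_breaks <- function(ratios) which(diff(ratios) != 0)

test_that("segmentation recovers noiseless piecewise-constant tracks exactly", {
  expect_equal(segment_coverage(mk_track(rep(1, 40)))$copy_number, 1L)
  segs <- segment_coverage(mk_track(c(rep(1, 20), rep(2, 20))))
  expect_equal(segs$copy_number, c(1L, 2L))
  expect_equal(segs$start[2], 20001L)
  expect_equal(segment_coverage(mk_track(rep(2, 25)))$copy_number, 2L)
  expect_equal(segment_coverage(mk_track(rep(0, 25)))$copy_number, 0L)

  # randomized instances <= 200 windows vs the exhaustive oracle
  set.seed(404)
  for (i in 1:25) {
    n_seg <- sample(1:5, 1)
    lens <- sample(3:40, n_seg, replace = TRUE)
    cn <- sample(0:3, n_seg, replace = TRUE)
    while (any(diff(cn) == 0)) cn <- sample(0:3, n_seg, replace = TRUE)
    ratios <- rep(cn, lens)
    if (length(ratios) > 200) next
    segs <- segment_coverage(mk_track(ratios))
    got <- cumsum(segs$n_windows)
    got <- got[-length(got)]
    expect_equal(got, oracle_breaks(ratios))
    expect_equal(rep(segs$copy_number, segs$n_windows), ratios)
  }
})

test_that("injected duplication is segmented near the true boundaries", {
  iso <- fixture_iso1()
  segs <- segment_coverage(iso$track)
  dup <- segs[segs$contig == "A_CHRII" & segs$copy_number == 2, ]
  expect_equal(nrow(dup), 1)
  # truth 2001..14000; boundaries within +/- 2 windows
  expect_lte(abs(dup$start - 2001), 2000)
  expect_lte(abs(dup$end - 14000), 2000)
})

test_that("event classification covers gains, losses, LOH and nomenclature", {
  fx <- fixture_reference()
  iso1 <- fixture_iso1()
  segs1 <- segment_coverage(iso1$track)
  ev1 <- classify_events(segs1, fx$ref$homeology_map, fx$ref$orfs)
  expect_true("2xB(CHRII)" %in% ev1$nomenclature)          # chromosome gain
  loh <- ev1[ev1$kind == "LOH_SUBST", ]
  expect_equal(nrow(loh), 1)
  expect_equal(loh$contig, "B_CHRI")
  expect_equal(loh$donor_contig, "A_CHRI")
  expect_match(loh$nomenclature, "^ΔB::A\\(Bg003-end\\)$")
  expect_true(any(ev1$kind == "SEG_DUP" & ev1$contig == "A_CHRII"))

  iso2 <- fixture_iso2()
  ev2 <- classify_events(segment_coverage(iso2$track), fx$ref$homeology_map,
                         fx$ref$orfs)
  expect_true("ΔA(CHRII)" %in% ev2$nomenclature)           # chromosome loss
  expect_true(any(ev2$kind == "SEG_DEL" & ev2$contig == "B_CHRII"))
  expect_true(any(ev2$kind == "LOH_SUBST" & ev2$contig == "B_CHRI"))

  # copy-number conservation at every LOH substitution: acceptor + donor = 2
  for (ev in list(ev1, ev2)) {
    for (r in which(ev$kind == "LOH_SUBST")) {
      segs <- if (identical(ev, ev1)) segs1 else segment_coverage(iso2$track)
      acc <- segs[segs$contig == ev$contig[r] &
                    segs$start <= ev$end[r] & segs$end >= ev$start[r], ]
      don <- segs[segs$contig == ev$donor_contig[r] &
                    segs$start <= ev$donor_end[r] & segs$end >= ev$donor_start[r], ]
      expect_equal(min(acc$copy_number) + max(don$copy_number), 2L)
    }
  }

  # a clean parent shows no copy events at all
  par <- fixture_parent()
  ev0 <- classify_events(segment_coverage(par$track), fx$ref$homeology_map,
                         fx$ref$orfs)
  expect_equal(nrow(ev0), 0)

  expect_error(classify_events(segs1, data.frame(contig_a = "A_CHRI",
                                                 contig_b = "B_CHRI"),
                               fx$ref$orfs),
               "missing from homeology_map")
})

test_that("mitochondrial status follows the covered fraction", {
  par <- fixture_parent()
  expect_equal(classify_mito(par$track)$status, "present")
  expect_equal(classify_mito(fixture_iso1()$track)$status, "partial_loss")
  iso2 <- classify_mito(fixture_iso2()$track)
  expect_equal(iso2$status, "full_loss")
  expect_lt(iso2$covered_fraction, 0.05)
  # boundary thresholds on synthetic tracks
  t60 <- mk_track(c(rep(1, 4), rep(0, 6)), contig = "B_MT")
  expect_equal(classify_mito(t60)$status, "partial_loss")
  t0 <- mk_track(rep(0, 10), contig = "B_MT")
  expect_equal(classify_mito(t0)$status, "full_loss")
  expect_error(classify_mito(mk_track(rep(1, 5), contig = "A_CHRI")),
               "no mitochondrial contigs")
})

test_that("copy-event nomenclature parses back to its components", {
  # table-style strings
  p <- parse_nomenclature("ΔSc(YKL032C-YKL054C)")
  expect_equal(p$kind, "SEG_DEL")
  expect_equal(p$acceptor_tag, "Sc")
  expect_equal(p$boundary_gene1, "YKL032C")
  p2 <- parse_nomenclature("ΔSe::Sc(YOLend-YOL072W)")
  expect_equal(p2$kind, "LOH_SUBST")
  expect_equal(p2$donor_tag, "Sc")
  p3 <- parse_nomenclature("2xSc(CHRVIII)")
  expect_equal(p3$kind, "CHR_GAIN")
  expect_equal(p3$chromosome, "CHRVIII")
  p4 <- parse_nomenclature("ΔSc(YGR279C-YGRend)::Se(YMR305C-YMRend)")
  expect_true(p4$composite)
  expect_equal(p4$donor_gene1, "YMR305C")
  expect_error(parse_nomenclature("nonsense string"), "position")

  # round trip over grammar-valid random events
  set.seed(7)
  for (i in 1:30) {
    ev <- list(kind = sample(c("CHR_GAIN", "CHR_LOSS", "SEG_DEL", "SEG_DUP",
                               "LOH_SUBST"), 1),
               contig = sample(c("A_CHRI", "B_CHRIV"), 1),
               donor_contig = sample(c("A_CHRII", "B_CHRII"), 1),
               boundary_gene1 = sample(c("g001", "end"), 1),
               boundary_gene2 = sample(c("g002", "end"), 1))
    ev$scope <- if (ev$kind %in% c("CHR_GAIN", "CHR_LOSS")) "chromosome"
    else "segment"
    if (ev$kind == "LOH_SUBST" && i %% 2 == 0) ev$scope <- "chromosome"
    s <- format_nomenclature(ev)
    p <- parse_nomenclature(s)
    expect_equal(p$kind, ev$kind)
    expect_equal(p$scope, ev$scope)
    expect_equal(p$acceptor_tag, sub("_.*", "", ev$contig))
    if (ev$scope == "segment") {
      expect_equal(p$boundary_gene1, ev$boundary_gene1)
      expect_equal(p$boundary_gene2, ev$boundary_gene2)
    }
  }
})

test_that("segments export as BED with copy-number scores", {
  segs <- segment_coverage(mk_track(c(rep(1, 10), rep(2, 10))))
  f <- tempfile(fileext = ".bed")
  write_segments_bed(segs, f)
  ln <- readLines(f)
  expect_equal(length(ln), 2)
  expect_match(ln[1], "^A_CHRI\t0\t10000\tseg\t1$")
  unlink(f)
})
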