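# Shared simulation fixture: one allodiploid reference, a parent run, and
# two isolates covering every event class.  Built once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture_reference <- function() {
  if (!exists("ref", .fixture_env)) {
    spec <- genome_spec(chromosomes_per_subgenome = 2,
                        chromosome_lengths = c(40000, 30000),
                        n_homolog_pairs = 4, target_identity = 0.85,
                        seed = 42)
    .fixture_env$ref <- build_reference(spec)
    .fixture_env$index <- build_index(.fixture_env$ref)
  }
  list(ref = .fixture_env$ref, index = .fixture_env$index)
}

# run one genome through simulate/map/coverage
run_genome <- function(genome, index, seed, depth = 30, error_rate = 0) {
  reads <- simulate_reads(genome, read_sim_params(depth = depth,
                                                  error_rate = error_rate,
                                                  seed = seed))
  aln <- map_reads(reads, index)
  track <- compute_coverage(aln, window = 1000L)
  list(reads = reads, alignments = aln, track = track)
}

fixture_parent <- function() {
  if (!exists("parent", .fixture_env)) {
    fx <- fixture_reference()
    pg <- parent_genome(fx$ref)
    run <- run_genome(pg, fx$index, seed = 7)
    run$genome <- pg
    run$calls <- call_pileup(run$alignments, fx$ref)
    run$ambiguous <- parent_ambiguous_regions(run$alignments, fx$ref)
    disc <- extract_discordant(run$alignments, 450, 50)
    run$candidates <- cluster_evidence(disc, run$alignments)
    .fixture_env$parent <- run
  }
  .fixture_env$parent
}

# isolate 1: point mutations, tandem duplication, LOH through an ORF pair,
# whole-chromosome gain, partial mitochondrial loss
fixture_iso1 <- function() {
  if (!exists("iso1", .fixture_env)) {
    fx <- fixture_reference()
    ref <- fx$ref
    avoid <- data.frame(contig = c("A_CHRII", "B_CHRI"),
                        start = c(1500, 25000), end = c(14500, 40000))
    pts <- random_point_events(ref, n_snp = 4, n_indel = 3, seed = 5,
                               avoid_ranges = avoid)
    ev <- bind_events(pts,
                      ev_seg_dup("A_CHRII", 2001, 14000),
                      ev_loh_through_pair(ref, "g003", 600),
                      ev_chr_gain("B_CHRII"),
                      ev_mt_loss("B_MT", fraction = 0.6, contig_len = 6000))
    ledger <- truth_ledger("iso1", ev)
    genome <- inject_events(parent_genome(ref), ledger)
    run <- run_genome(genome, fx$index, seed = 8)
    run$ledger <- ledger
    run$genome <- genome
    .fixture_env$iso1 <- run
  }
  .fixture_env$iso1
}

# isolate 2: point mutations, segmental deletion, LOH through another pair,
# whole-chromosome loss, full mitochondrial loss
fixture_iso2 <- function() {
  if (!exists("iso2", .fixture_env)) {
    fx <- fixture_reference()
    ref <- fx$ref
    avoid <- data.frame(contig = c("A_CHRII", "B_CHRII", "B_CHRI"),
                        start = c(1, 4500, 13000),
                        end = c(30000, 15500, 40000))
    pts <- random_point_events(ref, n_snp = 3, n_indel = 2, seed = 6,
                               avoid_ranges = avoid)
    ev <- bind_events(pts,
                      ev_seg_del("B_CHRII", 5001, 15000),
                      ev_loh_through_pair(ref, "g001", 900),
                      ev_chr_loss("A_CHRII"),
                      ev_mt_loss("B_MT"))
    ledger <- truth_ledger("iso2", ev)
    genome <- inject_events(parent_genome(ref), ledger)
    run <- run_genome(genome, fx$index, seed = 9)
    run$ledger <- ledger
    run$genome <- genome
    .fixture_env$iso2 <- run
  }
  .fixture_env$iso2
}

# parent-subtracted annotated calls for an isolate run
isolate_calls <- function(run) {
  fx <- fixture_reference()
  par <- fixture_parent()
  calls <- call_pileup(run$alignments, fx$ref)
  calls <- subtract_parent(calls, par$calls, par$ambiguous)
  annotate_effects(calls, fx$ref$orfs, fx$ref)
}

retained_candidates <- function(run) {
  par <- fixture_parent()
  disc <- extract_discordant(run$alignments, 450, 50)
  cand <- cluster_evidence(disc, run$alignments)
  filter_candidates(cand, par$candidates)
}

# independent left-alignment of a truth indel for comparison with calls
# (simple repeated shift on the reference string)
oracle_left_align <- function(refseq, anchor, del_len = NULL, ins = NULL) {
  if (!is.null(del_len)) {
    while (anchor >= 1 &&
           substr(refseq, anchor, anchor) ==
             substr(refseq, anchor + del_len, anchor + del_len)) {
      anchor <- anchor - 1
    }
    list(anchor = max(anchor, 1))
  } else {
    while (anchor >= 1 &&
           substr(refseq, anchor, anchor) == substr(ins, nchar(ins), nchar(ins))) {
      ins <- paste0(substr(ins, nchar(ins), nchar(ins)),
                    substr(ins, 1, nchar(ins) - 1))
      anchor <- anchor - 1
    }
    list(anchor = max(anchor, 1), ins = ins)
  }
}

# truth (contig, pos, ref, alt) rows in normalized VCF-like form
truth_point_variants <- function(ledger, reference) {
  seqs <- stats::setNames(as.character(reference$sequences),
                          names(reference$sequences))
  ev <- ledger$events
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == "SNP") {
      s <- seqs[[ev$contig[i]]]
      rows[[length(rows) + 1]] <- data.frame(
        contig = ev$contig[i], pos = ev$start[i],
        ref = substr(s, ev$start[i], ev$start[i]), alt = ev$alt[i],
        kind = "SNP", stringsAsFactors = FALSE)
    } else if (ev$kind[i] == "INDEL") {
      s <- seqs[[ev$contig[i]]]
      if (ev$indel_len[i] < 0) {
        d <- -ev$indel_len[i]
        n <- oracle_left_align(s, ev$start[i], del_len = d)
        rows[[length(rows) + 1]] <- data.frame(
          contig = ev$contig[i], pos = n$anchor,
          ref = substr(s, n$anchor, n$anchor + d),
          alt = substr(s, n$anchor, n$anchor), kind = "INDEL",
          stringsAsFactors = FALSE)
      } else {
        n <- oracle_left_align(s, ev$start[i], ins = ev$alt[i])
        rows[[length(rows) + 1]] <- data.frame(
          contig = ev$contig[i], pos = n$anchor,
          ref = substr(s, n$anchor, n$anchor),
          alt = paste0(substr(s, n$anchor, n$anchor), n$ins), kind = "INDEL",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# truth chimera sequence for an LOH-through-pair event
truth_chimera <- function(reference, gene_id, breakpoint) {
  h <- reference$homologs[reference$homologs$gene_id == gene_id, ]
  seqs <- reference$sequences
  orf_a <- substr(as.character(seqs[[h$contig_a]]), h$start_a, h$end_a)
  orf_b <- substr(as.character(seqs[[h$contig_b]]), h$start_b, h$end_b)
  list(orf_a = orf_a, orf_b = orf_b,
       chimera = paste0(substr(orf_b, 1, breakpoint),
                        substr(orf_a, breakpoint + 1, nchar(orf_a))))
}

# brute-force identical-run scan in plain R (oracle for locate_interval):
# enumerates all maximal identical runs of the pair's global alignment and
# returns the one containing the given orf1 coordinate
oracle_identical_run <- function(orf1, orf2, b1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(orf1, orf2, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 2)
  c1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  c2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  eq <- c1 == c2 & c1 != "-" & c2 != "-"
  p1 <- cumsum(c1 != "-")
  p2 <- cumsum(c2 != "-")
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  best <- NULL
  for (k in which(r$values)) {
    o1s <- p1[starts[k]]; o1e <- p1[ends[k]]
    if (o1s <= b1 && b1 <= o1e) {
      best <- list(a1 = o1s, b1 = o1e, a2 = p2[starts[k]], b2 = p2[ends[k]],
                   width = o1e - o1s + 1)
      break
    }
  }
  best
}

# homeologous ORF pair generated by codon-safe substitution at a target
# identity, for interval-location tests
make_orf_pair <- function(len = 1200, identity = 0.85, seed = 1) {
  ref <- build_reference(genome_spec(chromosomes_per_subgenome = 1,
                                     chromosome_lengths = len + 12000,
                                     n_homolog_pairs = 1,
                                     homolog_length_range = c(len, len),
                                     target_identity = identity, seed = seed))
  h <- ref$homologs[1, ]
  list(orf1 = substr(as.character(ref$sequences[[h$contig_b]]), h$start_b, h$end_b),
       orf2 = substr(as.character(ref$sequences[[h$contig_a]]), h$start_a, h$end_a))
}
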