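#' Specification for a synthetic allodiploid genome
#'
#' Describes a two-subgenome hybrid genome at desk scale: one contig per
#' chromosome per subgenome plus one mitochondrial contig per subgenome.
#' Subgenome B is derived from subgenome A by seeded substitutions so that
#' each homeologous ORF pair realizes approximately `target_identity`
#' nucleotide identity, emulating the 70-100 percent homology range of
#' homeologous genes in interspecies yeast hybrids.
#'
#' @param subgenome_labels character(2), short tags for the two subgenomes.
#' @param chromosomes_per_subgenome number of nuclear chromosomes per
#'   subgenome.
#' @param chromosome_lengths integer vector (recycled) of chromosome lengths
#'   in bp; homeologous chromosomes share a length because divergence is
#'   substitution-dominated.
#' @param mito_lengths numeric(2), mitochondrial contig length per subgenome.
#' @param n_homolog_pairs number of homeologous ORF pairs to embed.
#' @param homolog_length_range numeric(2) min/max ORF length in bp; values
#'   are rounded to multiples of 3 and must be >= 300.
#' @param target_identity fraction in [0.70, 1.00]: target nucleotide
#'   identity of each homeologous ORF pair (and of intergenic homeologous
#'   sequence).
#' @param gc_fraction genomic GC content in [0, 1].
#' @param seed integer seed; the same seed yields a byte-identical genome.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(subgenome_labels = c("A", "B"),
                        chromosomes_per_subgenome = 2,
                        chromosome_lengths = c(60000, 45000),
                        mito_lengths = c(6000, 6000),
                        n_homolog_pairs = 8,
                        homolog_length_range = c(900, 1800),
                        target_identity = 0.85,
                        gc_fraction = 0.40,
                        seed = 1L) {
  stopifnot(length(subgenome_labels) == 2, !anyDuplicated(subgenome_labels),
            chromosomes_per_subgenome >= 1,
            all(chromosome_lengths > 0),
            length(mito_lengths) == 2, all(mito_lengths > 0),
            n_homolog_pairs >= 0,
            length(homolog_length_range) == 2,
            homolog_length_range[1] >= 300,
            homolog_length_range[2] >= homolog_length_range[1],
            target_identity >= 0 && target_identity <= 1,
            gc_fraction >= 0 && gc_fraction <= 1)
  if (target_identity < 0.70)
    warning("target_identity below 0.70 is outside the homeolog range this simulator emulates")
  chromosome_lengths <- rep_len(as.integer(chromosome_lengths),
                                chromosomes_per_subgenome)
  homolog_length_range <- as.integer(round(homolog_length_range / 3) * 3)
  structure(list(subgenome_labels = subgenome_labels,
                 chromosomes_per_subgenome = as.integer(chromosomes_per_subgenome),
                 chromosome_lengths = chromosome_lengths,
                 mito_lengths = as.integer(mito_lengths),
                 n_homolog_pairs = as.integer(n_homolog_pairs),
                 homolog_length_range = homolog_length_range,
                 target_identity = target_identity,
                 gc_fraction = gc_fraction,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", x$chromosomes_per_subgenome, "chromosomes x 2 subgenomes (",
      paste(x$subgenome_labels, collapse = "/"), ")\n")
  cat("  chromosome lengths:", paste(x$chromosome_lengths, collapse = ", "), "bp\n")
  cat("  homeologous ORF pairs:", x$n_homolog_pairs,
      sprintf("(target identity %.2f)\n", x$target_identity))
  invisible(x)
}

# a random ORF: ATG + sense codons + TAA, total length len (multiple of 3)
random_orf <- function(len, gc) {
  stopifnot(len %% 3 == 0, len >= 9)
  n_inner <- len / 3 - 2
  codons <- character(n_inner)
  i <- 1
  while (i <= n_inner) {
    cd <- rand_dna(3, gc)
    if (!cd %in% STOP_CODONS) {
      codons[i] <- cd
      i <- i + 1
    }
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# Mutate a sequence at per-base rate m.  Within ORFs (frame known, positions
# relative) substitutions that would create an in-frame stop codon are
# resampled.  Returns the mutated character string.
mutate_seq <- function(seq, m, in_orf = FALSE) {
  if (m <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hit <- which(runif(n) < m)
  if (in_orf) {
    # protect start and stop codons
    hit <- hit[hit > 3 & hit <= n - 3]
  }
  for (p in hit) {
    alt <- sample(setdiff(BASES, chars[p]), 1)
    if (in_orf) {
      cstart <- ((p - 1) %/% 3) * 3 + 1
      codon <- chars[cstart:(cstart + 2)]
      codon[p - cstart + 1] <- alt
      tries <- 0
      while (paste(codon, collapse = "") %in% STOP_CODONS && tries < 10) {
        alt <- sample(setdiff(BASES, chars[p]), 1)
        codon[p - cstart + 1] <- alt
        tries <- tries + 1
      }
      if (paste(codon, collapse = "") %in% STOP_CODONS) next
    }
    chars[p] <- alt
  }
  paste(chars, collapse = "")
}

seq_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

#' Build a two-subgenome reference with homeologous ORF pairs
#'
#' Generates subgenome A chromosomes as random sequence with embedded ORFs,
#' then derives each subgenome-B chromosome from its A counterpart by seeded
#' per-base substitutions at rate `1 - target_identity` (codon-aware inside
#' ORFs, never creating in-frame stop codons), so homeologous chromosomes
#' share a coordinate system.  Contigs are named `<tag>_CHR<roman>` and
#' `<tag>_MT`.
#'
#' @param spec a [genome_spec()].
#' @return A list with elements `sequences` (named [Biostrings::DNAStringSet]),
#'   `homologs` (data.frame of homeologous ORF pairs with realized identity),
#'   `orfs` (ORF annotation data.frame usable by [annotate_effect()]),
#'   `homeology_map` (data.frame pairing homeologous contigs) and `spec`.
#' @export
build_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  tags <- spec$subgenome_labels
  nchr <- spec$chromosomes_per_subgenome
  with_seed(derive_seed(spec$seed, 1), {
    chr_names_a <- paste0(tags[1], "_CHR", as.character(utils::as.roman(seq_len(nchr))))
    chr_names_b <- paste0(tags[2], "_CHR", as.character(utils::as.roman(seq_len(nchr))))

    # subgenome A chromosomes
    seqs_a <- vapply(spec$chromosome_lengths, rand_dna, character(1),
                     gc = spec$gc_fraction)

    # homolog ORF placement: round-robin across chromosomes, evenly spaced
    homolog <- NULL
    if (spec$n_homolog_pairs > 0) {
      len_pool <- seq(spec$homolog_length_range[1],
                      spec$homolog_length_range[2], by = 3)
      lens <- len_pool[sample.int(length(len_pool), spec$n_homolog_pairs,
                                  replace = TRUE)]
      chr_of <- rep(seq_len(nchr), length.out = spec$n_homolog_pairs)
      homolog <- data.frame(gene_id = sprintf("g%03d", seq_len(spec$n_homolog_pairs)),
                            chr = chr_of, len = lens, start = NA_integer_)
      for (ci in seq_len(nchr)) {
        rows <- which(homolog$chr == ci)
        if (!length(rows)) next
        margin <- 3000L
        avail <- spec$chromosome_lengths[ci] - 2 * margin
        need <- sum(homolog$len[rows]) + (length(rows) - 1) * 2000L
        if (need > avail)
          stop("chromosome ", ci, " too short for its assigned homolog ORFs")
        gap <- (avail - sum(homolog$len[rows])) %/% (length(rows) + 1)
        pos <- margin + gap
        for (r in rows) {
          homolog$start[r] <- as.integer(pos)
          pos <- pos + homolog$len[r] + gap
        }
      }
      # write ORFs into subgenome A
      for (r in seq_len(nrow(homolog))) {
        orf <- random_orf(homolog$len[r], spec$gc_fraction)
        ci <- homolog$chr[r]
        substr(seqs_a[ci], homolog$start[r],
               homolog$start[r] + homolog$len[r] - 1L) <- orf
      }
    }

    # subgenome B: substituted copies, codon-aware within ORFs
    m <- 1 - spec$target_identity
    seqs_b <- character(nchr)
    realized <- numeric(if (is.null(homolog)) 0 else nrow(homolog))
    for (ci in seq_len(nchr)) {
      s <- seqs_a[ci]
      rows <- if (is.null(homolog)) integer(0) else which(homolog$chr == ci)
      # mutate intergenic stretches freely, ORFs codon-aware
      bounds <- if (length(rows))
        homolog[rows, c("start", "len")][order(homolog$start[rows]), , drop = FALSE]
      else data.frame(start = integer(0), len = integer(0))
      out <- character(0)
      cursor <- 1L
      for (r in seq_len(nrow(bounds))) {
        st <- bounds$start[r]; en <- st + bounds$len[r] - 1L
        if (st > cursor)
          out <- c(out, mutate_seq(substr(s, cursor, st - 1L), m))
        orf_a <- substr(s, st, en)
        ok <- FALSE
        for (try in 1:5) {
          orf_b <- mutate_seq(orf_a, m, in_orf = TRUE)
          id <- seq_identity(orf_a, orf_b)
          if (abs(id - spec$target_identity) <= 0.03) { ok <- TRUE; break }
        }
        if (!ok) {
          gid <- homolog$gene_id[rows[order(homolog$start[rows])][r]]
          stop("could not realize identity ", spec$target_identity,
               " for gene ", gid, " without breaking ORF constraints")
        }
        out <- c(out, orf_b)
        cursor <- en + 1L
      }
      if (cursor <= nchar(s)) out <- c(out, mutate_seq(substr(s, cursor, nchar(s)), m))
      seqs_b[ci] <- paste(out, collapse = "")
    }

    # mitochondrial contigs (independent sequences, lower GC as in yeast mtDNA)
    mito_a <- rand_dna(spec$mito_lengths[1], max(0, spec$gc_fraction - 0.2))
    mito_b <- rand_dna(spec$mito_lengths[2], max(0, spec$gc_fraction - 0.2))

    seqs <- c(stats::setNames(seqs_a, chr_names_a),
              stats::setNames(seqs_b, chr_names_b),
              stats::setNames(c(mito_a, mito_b), paste0(tags, "_MT")))
    sequences <- Biostrings::DNAStringSet(seqs)

    homologs <- NULL
    orfs <- NULL
    if (!is.null(homolog)) {
      homologs <- data.frame(
        gene_id = homolog$gene_id,
        contig_a = chr_names_a[homolog$chr],
        start_a = homolog$start,
        end_a = homolog$start + homolog$len - 1L,
        strand_a = "+",
        contig_b = chr_names_b[homolog$chr],
        start_b = homolog$start,
        end_b = homolog$start + homolog$len - 1L,
        strand_b = "+",
        length = homolog$len,
        stringsAsFactors = FALSE)
      for (r in seq_len(nrow(homologs))) {
        oa <- substr(seqs[homologs$contig_a[r]], homologs$start_a[r], homologs$end_a[r])
        ob <- substr(seqs[homologs$contig_b[r]], homologs$start_b[r], homologs$end_b[r])
        realized[r] <- seq_identity(oa, ob)
      }
      homologs$realized_identity <- realized
      orfs <- rbind(
        data.frame(orf_id = paste0(tags[1], homologs$gene_id),
                   contig = homologs$contig_a, start = homologs$start_a,
                   end = homologs$end_a, strand = "+", subgenome = tags[1],
                   gene_id = homologs$gene_id, stringsAsFactors = FALSE),
        data.frame(orf_id = paste0(tags[2], homologs$gene_id),
                   contig = homologs$contig_b, start = homologs$start_b,
                   end = homologs$end_b, strand = "+", subgenome = tags[2],
                   gene_id = homologs$gene_id, stringsAsFactors = FALSE))
    }

    homeology_map <- data.frame(contig_a = c(chr_names_a, paste0(tags[1], "_MT")),
                                contig_b = c(chr_names_b, paste0(tags[2], "_MT")),
                                length = c(spec$chromosome_lengths, NA, NA)[
                                  seq_len(nchr + 1)],
                                stringsAsFactors = FALSE)
    homeology_map$length <- c(spec$chromosome_lengths, spec$mito_lengths[1])

    list(sequences = sequences, homologs = homologs, orfs = orfs,
         homeology_map = homeology_map, spec = spec)
  })
}

#' The genome actually carried by the hybrid
#'
#' The reference carries a mitochondrial contig for each parental
#' subgenome, but a hybrid cell carries only one mitochondrial genome
#' (inherited from one parent).  This helper drops the other
#' mitochondrial contig, yielding the parent-strain genome that reads are
#' simulated from; isolate genomes are derived from it with
#' [inject_events()].
#'
#' @param reference output of [build_reference()].
#' @param carried_mito which subgenome's mitochondrial genome the hybrid
#'   carries (index into `subgenome_labels`; default the second,
#'   emulating inheritance from the cryotolerant parent).
#' @return Named [Biostrings::DNAStringSet].
#' @export
parent_genome <- function(reference, carried_mito = 2L) {
  tags <- reference$spec$subgenome_labels
  drop <- paste0(tags[-carried_mito], "_MT")
  reference$sequences[setdiff(names(reference$sequences), drop)]
}

#' Extract the sequence of an ORF from a genome
#'
#' @param sequences named DNAStringSet or character vector.
#' @param orf one-row data.frame with contig/start/end/strand.
#' @return Character string (reverse-complemented for minus-strand ORFs).
#' @export
orf_sequence <- function(sequences, orf) {
  s <- as.character(sequences[[orf$contig]])
  sq <- substr(s, orf$start, orf$end)
  if (identical(orf$strand, "-")) sq <- rc(sq)
  sq
}
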