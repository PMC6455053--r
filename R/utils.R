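#' @useDynLib hybriddyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom IRanges IRanges coverage Views viewMeans
#' @importFrom S4Vectors Rle runValue runLength
#' @importFrom stats median rnorm runif lm coef setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a deterministic sub-seed for an operation-specific generator stream.
# Keeps results independent across streams while everything flows from one
# user-visible integer seed.  Result always fits in a 32-bit signed integer.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# random DNA with a target GC fraction
rand_dna <- function(n, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reference length consumed by a CIGAR string
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_query_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# split "TAG_NAME" contig ids into subgenome tag and chromosome label
split_contig_name <- function(contig) {
  tag <- sub("_.*$", "", contig)
  label <- sub("^[^_]*_", "", contig)
  list(tag = tag, label = label)
}

is_mito_contig <- function(contig) grepl("_MT$", contig)
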