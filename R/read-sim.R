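#' Paired-end read simulation parameters
#'
#' @param read_length read length in bp (150 bp paired-end by default,
#'   matching short-read resequencing of evolved isolates).
#' @param insert_mean,insert_sd fragment (insert) size distribution in bp.
#' @param depth target fold-coverage.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return `read_sim_params` object.
#' @export
read_sim_params <- function(read_length = 150L, insert_mean = 450L,
                            insert_sd = 50L, depth = 30, error_rate = 0,
                            seed = 1L) {
  stopifnot(read_length <= insert_mean, depth > 0, error_rate >= 0,
            error_rate < 1, insert_sd >= 0)
  structure(list(read_length = as.integer(read_length),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.integer(insert_sd),
                 depth = depth, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n <- nchar(seqs[1])
  m <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = n)
  hits <- which(matrix(runif(n * m) < error_rate, nrow = n))
  if (length(hits)) {
    cur <- chars[hits]
    sub <- vapply(cur, function(b) sample(setdiff(BASES, b), 1), character(1))
    chars[hits] <- sub
  }
  apply(chars, 2, paste, collapse = "")
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn uniformly along each contig with normally
#' distributed insert sizes; mate 1 is the fragment prefix, mate 2 the
#' reverse complement of the fragment suffix (FR orientation).  Per-base
#' substitution errors are applied at `error_rate`.  The origin contig and
#' fragment start are recorded in the read name
#' (`r<idx>:<contig>:<start>:<insert>`), so mapping accuracy can be scored
#' against the simulation truth.
#'
#' @param genome named DNAStringSet or character vector of contigs.
#' @param params a [read_sim_params()].
#' @return data.frame of class `read_set` with columns read_id, seq1, seq2,
#'   contig, start, insert; `params` stored as an attribute.
#' @export
simulate_reads <- function(genome, params = read_sim_params()) {
  seqs <- stats::setNames(as.character(genome), names(genome))
  if (!length(seqs) || any(!nzchar(seqs))) stop("genome must be non-empty")
  lens <- nchar(seqs)
  if (params$insert_mean > min(lens))
    stop("insert_mean (", params$insert_mean,
         ") exceeds shortest contig (", min(lens), ")")
  L <- params$read_length
  with_seed(derive_seed(params$seed, 11), {
    out <- vector("list", length(seqs))
    idx0 <- 0L
    for (ci in seq_along(seqs)) {
      clen <- lens[ci]
      n_pairs <- max(1L, as.integer(round(params$depth * clen / (2 * L))))
      ins <- as.integer(round(rnorm(n_pairs, params$insert_mean, params$insert_sd)))
      ins <- pmin(pmax(ins, L), clen)
      start <- floor(runif(n_pairs) * (clen - ins + 1)) + 1L
      frag_end <- start + ins - 1L
      s <- seqs[ci]
      r1 <- substring(s, start, start + L - 1L)
      r2 <- rc(substring(s, frag_end - L + 1L, frag_end))
      r1 <- apply_errors(r1, params$error_rate)
      r2 <- apply_errors(r2, params$error_rate)
      out[[ci]] <- data.frame(
        read_id = sprintf("r%07d:%s:%d:%d", idx0 + seq_len(n_pairs),
                          names(seqs)[ci], start, ins),
        seq1 = r1, seq2 = r2, contig = names(seqs)[ci], start = start,
        insert = ins, stringsAsFactors = FALSE)
      idx0 <- idx0 + n_pairs
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "params") <- params
    class(res) <- c("read_set", class(res))
    res
  })
}

#' Write / read paired FASTQ
#'
#' Sanger-encoded qualities at a fixed Q30.
#'
#' @param reads a `read_set` from [simulate_reads()].
#' @param file1,file2 output FASTQ paths for mate 1 and mate 2.
#' @export
write_fastq <- function(reads, file1, file2) {
  q <- strrep("?", nchar(reads$seq1[1]))  # Q30 in Sanger encoding
  l1 <- as.vector(rbind(paste0("@", reads$read_id, "/1"), reads$seq1, "+",
                        strrep("?", nchar(reads$seq1))))
  l2 <- as.vector(rbind(paste0("@", reads$read_id, "/2"), reads$seq2, "+",
                        strrep("?", nchar(reads$seq2))))
  writeLines(l1, file1)
  writeLines(l2, file2)
  invisible(c(file1, file2))
}

#' @rdname write_fastq
#' @export
read_fastq <- function(file1, file2) {
  l1 <- readLines(file1); l2 <- readLines(file2)
  ids <- sub("^@", "", sub("/1$", "", l1[seq(1, length(l1), by = 4)]))
  data.frame(read_id = ids,
             seq1 = l1[seq(2, length(l1), by = 4)],
             seq2 = l2[seq(2, length(l2), by = 4)],
             stringsAsFactors = FALSE)
}

#' Write genome sequences as FASTA
#' @param sequences named DNAStringSet or character vector.
#' @param file path.
#' @export
write_fasta <- function(sequences, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as.character(sequences)),
                              file)
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  Biostrings::readDNAStringSet(file)
}
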