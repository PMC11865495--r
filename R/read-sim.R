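## Paired-end read simulator with planted per-interval enrichment, emulating
## CUT&RUN target vs IgG libraries over a toy genome. Fragment start
## positions are drawn with per-base sampling weight 1 outside enrichment
## intervals and w inside; mates are the two ends of the fragment, mate 2
## reverse-complemented.

#' Configure a read simulation
#'
#' @param n_pairs number of read pairs.
#' @param read_length read length in bp (must not exceed the shortest
#'   fragment; fragment draws are clamped at `read_length`).
#' @param fragment_mean,fragment_sd fragment-length distribution (truncated
#'   normal, minimum `read_length`). Defaults 180/30 bp, typical of CUT&RUN
#'   mononucleosomal fragments.
#' @param enrichment GRanges of enrichment intervals with a numeric `weight`
#'   metadata column (weight >= 0; bases outside any interval have weight 1),
#'   or `NULL` for a uniform library (IgG-like).
#' @param error_rate per-base substitution error probability (default 0 so
#'   exact-match k-mer analyses are noise-free).
#' @param seed integer seed; same seed, same output.
#' @return object of class `read_sim_config`.
#' @export
read_sim_config <- function(n_pairs = 50000L, read_length = 75L,
                            fragment_mean = 180, fragment_sd = 30,
                            enrichment = NULL, error_rate = 0,
                            seed = 1L) {
  stopifnot_scalar_count(n_pairs, "n_pairs")
  stopifnot_scalar_count(read_length, "read_length", min = 1L)
  if (!is.null(enrichment)) {
    stopifnot(is(enrichment, "GRanges"))
    w <- S4Vectors::mcols(enrichment)$weight
    if (is.null(w) || any(w < 0))
      stop("enrichment intervals need a non-negative 'weight' column")
  }
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0,1]")
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 enrichment = enrichment, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate paired-end reads from a toy genome
#'
#' Fragment lengths are drawn from a normal truncated below at
#' `read_length`; start positions are sampled with per-base weight 1 outside
#' the enrichment intervals and `weight` inside (weights apply to the
#' fragment start base). Fragments running off the chromosome end are
#' shifted left to fit. Mate 1 is the fragment's left end on the forward
#' strand; mate 2 is the reverse complement of its right end.
#'
#' @param genome a `toy_genome` (single chromosome).
#' @param cfg a [read_sim_config()].
#' @return object of class `read_pairs`: list with `mate1`, `mate2`
#'   (character vectors), `fragments` (data.table: start0, length) and `cfg`.
#' @export
simulate_reads <- function(genome, cfg) {
  stopifnot(inherits(genome, "toy_genome"), inherits(cfg, "read_sim_config"))
  L <- nchar(genome$seq)
  rl <- cfg$read_length
  if (rl > L) stop("read_length exceeds genome length")
  wvec <- rep(1, L)
  if (!is.null(cfg$enrichment)) {
    enr <- cfg$enrichment
    if (any(GenomicRanges::end(enr) > L) ||
        any(GenomicRanges::start(enr) < 1L))
      stop("enrichment interval out of genome bounds")
    for (i in seq_along(enr)) {
      idx <- GenomicRanges::start(enr)[i]:GenomicRanges::end(enr)[i]
      wvec[idx] <- S4Vectors::mcols(enr)$weight[i]
    }
  }
  with_seed(cfg$seed, {
    flen <- pmax(rl, round(rnorm(cfg$n_pairs, cfg$fragment_mean,
                                 cfg$fragment_sd)))
    flen <- pmin(flen, L)
    start1 <- sample.int(L, cfg$n_pairs, replace = TRUE, prob = wvec)
    start1 <- pmin(start1, L - flen + 1L)
    frag <- substring(genome$seq, start1, start1 + flen - 1L)
    mate1 <- substring(frag, 1L, rl)
    mate2 <- revcomp(substring(frag, flen - rl + 1L, flen))
    if (cfg$error_rate > 0) {
      mate1 <- inject_errors(mate1, cfg$error_rate)
      mate2 <- inject_errors(mate2, cfg$error_rate)
    }
    structure(list(mate1 = mate1, mate2 = mate2,
                   fragments = data.table::data.table(start0 = start1 - 1L,
                                                      length = flen),
                   chrom = genome$chrom, cfg = cfg),
              class = "read_pairs")
  })
}

## Per-base substitution errors at rate `rate` across a character vector.
inject_errors <- function(reads, rate) {
  n <- sum(nchar(reads))
  nerr <- stats::rbinom(1L, n, rate)
  if (nerr == 0L) return(reads)
  pos <- sort(sample.int(n, nerr))
  offsets <- cumsum(c(0L, head(nchar(reads), -1L)))
  ridx <- findInterval(pos - 1L, offsets)
  within <- pos - offsets[ridx]
  for (j in seq_along(pos)) {
    cur <- substr(reads[ridx[j]], within[j], within[j])
    substr(reads[ridx[j]], within[j], within[j]) <-
      sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  }
  reads
}

#' All reads of a pair set as one character vector (both mates)
#' @param pairs a `read_pairs` object.
#' @return character vector of reads.
#' @export
all_reads <- function(pairs) {
  stopifnot(inherits(pairs, "read_pairs"))
  c(pairs$mate1, pairs$mate2)
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("read_pairs: %d pairs of %d bp (%s)\n", length(x$mate1),
              x$cfg$read_length, x$chrom))
  invisible(x)
}

#' Write read pairs to FASTQ files
#'
#' @param pairs a `read_pairs` object.
#' @param prefix output path prefix; writes `<prefix>_1.fastq[.gz]` and
#'   `<prefix>_2.fastq[.gz]`.
#' @param gzip compress output.
#' @return invisibly, the two paths.
#' @export
write_fastq <- function(pairs, prefix, gzip = FALSE) {
  stopifnot(inherits(pairs, "read_pairs"))
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_1", "_2"), ext)
  ids <- sprintf("read%d", seq_along(pairs$mate1))
  for (m in 1:2) {
    reads <- if (m == 1) pairs$mate1 else pairs$mate2
    ss <- Biostrings::DNAStringSet(reads)
    names(ss) <- paste0(ids, "/", m)
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(ss, paths[m], format = "fastq",
                                qualities = qual, compress = gzip)
  }
  invisible(paths)
}

#' Read a FASTQ file into a plain character vector of sequences
#' @param path FASTQ(.gz) path.
#' @return character vector.
#' @export
read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
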