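## Canonical k-mer counting. The counter is exact and hash-based
## (data.table grouping over extracted windows): desk-scale replicates make
## probabilistic sketches unnecessary, and exactness is what the oracle
## tests assert.

#' K-mer pipeline configuration
#'
#' Defaults follow the reference-free centromeric CUT&RUN analysis: 51-mers
#' kept when seen at least twice per replicate, missing values floored at a
#' raw count of 1 before normalisation, a per-replicate normalised-count
#' filter of 5e-09, and an enrichment call requiring fold change > 2 over
#' the averaged IgG in at least 2 replicates.
#'
#' @param k k-mer length in bp (odd recommended so no k-mer is its own
#'   reverse complement).
#' @param min_count minimum per-replicate raw count retained.
#' @param missing_floor raw count substituted for k-mers absent from a
#'   replicate (applied before normalisation, so floored values differ
#'   between replicates with different base counts).
#' @param norm_threshold per-replicate normalised-count eligibility filter.
#' @param fc_threshold fold-change threshold versus the averaged control.
#' @param min_enriched_replicates replicates that must pass both filters.
#' @return object of class `kmer_config`.
#' @export
kmer_config <- function(k = 51L, min_count = 2L, missing_floor = 1L,
                        norm_threshold = 5e-09, fc_threshold = 2,
                        min_enriched_replicates = 2L) {
  stopifnot_scalar_count(k, "k")
  stopifnot_scalar_count(min_count, "min_count")
  if (norm_threshold <= 0 || fc_threshold <= 0)
    stop("thresholds must be positive")
  structure(list(k = as.integer(k), min_count = as.integer(min_count),
                 missing_floor = as.numeric(missing_floor),
                 norm_threshold = norm_threshold,
                 fc_threshold = fc_threshold,
                 min_enriched_replicates = as.integer(min_enriched_replicates)),
            class = "kmer_config")
}

#' Canonicalise k-mers
#'
#' The canonical form is the lexicographic minimum of a k-mer and its
#' reverse complement, so counting is strand-neutral.
#'
#' @param kmers character vector of equal-length DNA k-mers (ACGT only).
#' @return character vector of canonical forms.
#' @export
canonical_kmer <- function(kmers) {
  if (!length(kmers)) return(character(0))
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Count canonical k-mers in a replicate
#'
#' Every length-`k` window of every read contributes one count to its
#' canonical k-mer; windows containing non-ACGT characters are skipped
#' entirely; k-mers with total count below `min_count` are dropped.
#'
#' @param reads character vector (or DNAStringSet) of reads, or a
#'   `read_pairs` object (both mates are used).
#' @param cfg a [kmer_config()].
#' @return object of class `kmer_table`: data.table with columns `kmer`
#'   (canonical) and `count`, keyed by kmer; attribute `k`.
#' @examples
#' count_kmers(c("ACGTAC"), kmer_config(k = 3, min_count = 2))
#' @export
count_kmers <- function(reads, cfg = kmer_config()) {
  if (inherits(reads, "read_pairs")) reads <- all_reads(reads)
  reads <- as.character(reads)
  k <- cfg$k
  reads <- toupper(reads[nchar(reads) >= k])
  if (!length(reads)) return(empty_kmer_table(k))
  n_win <- nchar(reads) - k + 1L
  idx <- rep.int(seq_along(reads), n_win)
  starts <- sequence(n_win)
  windows <- substring(reads[idx], starts, starts + k - 1L)
  dt <- data.table::data.table(kmer = windows)[, list(count = .N),
                                               by = "kmer"]
  dt <- dt[!grepl("[^ACGT]", kmer)]
  if (!nrow(dt)) return(empty_kmer_table(k))
  dt[, kmer := canonical_kmer(kmer)]
  dt <- dt[, list(count = sum(count)), by = "kmer"]
  dt <- dt[count >= cfg$min_count]
  data.table::setkey(dt, kmer)
  structure(dt, class = c("kmer_table", class(dt)), k = k)
}

empty_kmer_table <- function(k) {
  dt <- data.table::data.table(kmer = character(0), count = integer(0))
  data.table::setkey(dt, kmer)
  structure(dt, class = c("kmer_table", class(dt)), k = k)
}

#' Total base count of a replicate
#'
#' Sum of read lengths over the replicate's full read set (both mates),
#' the normalisation denominator of the k-mer pipeline.
#'
#' @param reads character vector, DNAStringSet, or `read_pairs`.
#' @return numeric scalar (bp).
#' @export
total_base_count <- function(reads) {
  if (inherits(reads, "read_pairs")) reads <- all_reads(reads)
  sum(as.numeric(nchar(as.character(reads))))
}
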