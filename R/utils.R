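## Internal helpers shared across modules.

#' Reverse complement of character DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' stays in plain character space, which is what the k-mer ledger uses.
#'
#' @param x character vector of DNA sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Run code with a private RNG stream; restores the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Draw n random DNA bases as a single string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single number >= %s", name, min),
         call. = FALSE)
  invisible(TRUE)
}

## GRanges from 0-based half-open (BED-style) coordinates.
granges_from_bed0 <- function(chrom, start0, end0, name = NULL, ...) {
  gr <- GenomicRanges::GRanges(rep_len(chrom, length(start0)),
                               IRanges::IRanges(start = start0 + 1L,
                                                end = end0))
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  gr
}

## 0-based starts of a GRanges (BED convention).
bed0_start <- function(gr) GenomicRanges::start(gr) - 1L

midpoints <- function(gr) {
  floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
}
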