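## Interval algebra for peak-level analyses: replicate consensus, overlap
## summaries, peak categorisation, the relative-distance statistic, signal
## matrices and feature distributions. Containers are GRanges throughout;
## all text I/O is BED-convention 0-based half-open.

#' Replicate-consensus intervals
#'
#' Returns the maximal intervals over bases covered by at least
#' `min_support` of the supplied replicate sets (each set is reduced first
#' so overlapping calls within one replicate count once), the interval
#' analogue of a multiinter-then-merge consensus of peaks called in >= 2
#' replicates.
#'
#' @param replicate_sets list of GRanges (one per replicate).
#' @param min_support minimum number of supporting replicates per base.
#' @return GRanges of consensus intervals.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' consensus_intervals(list(a, b), min_support = 2)
#' @export
consensus_intervals <- function(replicate_sets, min_support = 2L) {
  if (min_support < 1L) stop("min_support must be >= 1")
  stopifnot(all(vapply(replicate_sets, is, TRUE, "GRanges")))
  covs <- lapply(replicate_sets, function(gr)
    GenomicRanges::coverage(GenomicRanges::reduce(gr,
                                                  ignore.strand = TRUE)))
  all_chroms <- unique(unlist(lapply(covs, names)))
  out <- list()
  for (ch in all_chroms) {
    len <- max(vapply(covs, function(cv)
      if (ch %in% names(cv)) length(cv[[ch]]) else 0L, integer(1)))
    total <- Reduce(`+`, lapply(covs, function(cv) {
      r <- if (ch %in% names(cv)) cv[[ch]] else S4Vectors::Rle(0L, 0L)
      c(r, S4Vectors::Rle(0L, len - length(r)))
    }))
    ir <- IRanges::ranges(IRanges::slice(total, lower = min_support))
    if (length(ir))
      out[[ch]] <- GenomicRanges::GRanges(ch, ir)
  }
  if (!length(out))
    return(GenomicRanges::GRanges())
  sort(do.call(c, unname(out)))
}

#' Pairwise interval overlap summary (Venn counts)
#'
#' `A_only`/`B_only` count intervals with no cross-set overlap. `shared`
#' counts merged overlap events: many-to-many overlaps collapse to
#' connected components of the bipartite overlap graph, so an A interval
#' spanned by two B intervals is one shared event. The raw per-set counts
#' (`A_in_overlap`, `B_in_overlap`) are also reported since plotting tools
#' differ in convention.
#'
#' @param setA,setB GRanges.
#' @return named list with `A_only`, `B_only`, `shared`, `A_in_overlap`,
#'   `B_in_overlap`.
#' @export
overlap_venn <- function(setA, setB) {
  stopifnot(is(setA, "GRanges"), is(setB, "GRanges"))
  ov <- GenomicRanges::findOverlaps(setA, setB, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  a_in <- length(unique(qh)); b_in <- length(unique(sh))
  shared <- 0L
  if (length(ov)) {
    edges <- cbind(paste0("A", qh), paste0("B", sh))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    shared <- as.integer(igraph::components(g)$no)
  }
  list(A_only = length(setA) - a_in, B_only = length(setB) - b_in,
       shared = shared, A_in_overlap = a_in, B_in_overlap = b_in)
}

#' Categorise consensus peaks into specific / non-specific / KO-specific
#'
#' Splits a primary factor's consensus peaks by whether a second factor
#' still shows them after knockout of the first: peaks of `pbrm1` with no
#' overlap in `smarca4_ko` are "specific", those overlapping `smarca4_ko`
#' are "non-specific", and `smarca4_ko` peaks overlapping neither parental
#' set are "KO-specific". With `strict = FALSE` the KO-specific test only
#' excludes overlap with parental `smarca4_parental`.
#'
#' @param pbrm1,smarca4_parental,smarca4_ko consensus GRanges.
#' @param strict require KO-specific peaks to avoid both parental sets.
#' @return list of GRanges: `PBRM1_specific`, `PBRM1_non_specific`,
#'   `KO_specific`.
#' @export
categorize_peaks <- function(pbrm1, smarca4_parental, smarca4_ko,
                             strict = TRUE) {
  stopifnot(is(pbrm1, "GRanges"), is(smarca4_parental, "GRanges"),
            is(smarca4_ko, "GRanges"))
  hit_ko <- GenomicRanges::findOverlaps(pbrm1, smarca4_ko,
                                        ignore.strand = TRUE)
  in_ko <- unique(S4Vectors::queryHits(hit_ko))
  ko_vs_par <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(smarca4_ko, smarca4_parental,
                                ignore.strand = TRUE)))
  ko_excl <- ko_vs_par
  if (strict) {
    ko_vs_pbrm1 <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(smarca4_ko, pbrm1,
                                  ignore.strand = TRUE)))
    ko_excl <- union(ko_excl, ko_vs_pbrm1)
  }
  list(PBRM1_specific = pbrm1[setdiff(seq_along(pbrm1), in_ko)],
       PBRM1_non_specific = pbrm1[in_ko],
       KO_specific = smarca4_ko[setdiff(seq_along(smarca4_ko), ko_excl)])
}

#' Relative distance of query locations between reference locations
#'
#' For each query location lying between two flanking reference locations
#' on the same chromosome, computes `min(d1, d2) / (d1 + d2)` where d1 and
#' d2 are the distances to the two nearest flanking reference locations —
#' uniform on `[0, 0.5]` when query and reference are independent.
#' Locations are interval midpoints by default (`use = "midpoint"`;
#' `use = "start"` switches to start coordinates); query locations outside
#' the outermost reference locations are skipped; a query coincident with a
#' reference location scores 0.
#'
#' @param query,reference GRanges. Reference needs >= 2 locations on a
#'   chromosome for that chromosome to contribute.
#' @param use `"midpoint"` or `"start"`.
#' @param grid_step grid spacing for the cumulative fraction curve.
#' @return object of class `reldist_result`: list with `reldist` (numeric
#'   vector), `per_query` (data.table: chrom, location, d1, d2, reldist)
#'   and `curve` (data.table: grid, cum_fraction).
#' @export
relative_distance <- function(query, reference, use = c("midpoint", "start"),
                              grid_step = 0.01) {
  use <- match.arg(use)
  stopifnot(is(query, "GRanges"), is(reference, "GRanges"))
  loc <- function(gr) if (use == "midpoint") midpoints(gr) else
    GenomicRanges::start(gr)
  qdt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(query)), x = loc(query))
  rdt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(reference)),
    x = loc(reference))
  rows <- list()
  for (ch in unique(qdt$chrom)) {
    ref <- sort(unique(rdt$x[rdt$chrom == ch]))
    if (length(ref) < 2L) next
    qx <- qdt$x[qdt$chrom == ch]
    qx <- qx[qx >= ref[1L] & qx <= ref[length(ref)]]
    if (!length(qx)) next
    # left flank index; queries on a reference point get d = 0 either way
    i <- findInterval(qx, ref, rightmost.closed = TRUE)
    d1 <- qx - ref[i]
    d2 <- ref[i + 1L] - qx
    r <- d1 + d2
    rel <- ifelse(r == 0, 0, pmin(d1, d2) / r)
    rows[[ch]] <- data.table::data.table(chrom = ch, location = qx,
                                         d1 = d1, d2 = d2, reldist = rel)
  }
  if (!length(rows)) {
    warning("reference has < 2 locations on every chromosome used")
    per <- data.table::data.table(chrom = character(0),
                                  location = numeric(0), d1 = numeric(0),
                                  d2 = numeric(0), reldist = numeric(0))
  } else per <- data.table::rbindlist(rows)
  grid <- seq(0, 0.5, by = grid_step)
  cum <- if (nrow(per))
    vapply(grid, function(g) mean(per$reldist <= g), numeric(1)) else
      rep(NA_real_, length(grid))
  structure(list(reldist = per$reldist, per_query = per,
                 curve = data.table::data.table(grid = grid,
                                                cum_fraction = cum)),
            class = "reldist_result")
}

#' Signal matrix around interval centres
#'
#' Bins fragment-depth coverage over `[centre - flank, centre + flank)` for
#' each interval (centre = floor of the interval midpoint). Bins must
#' divide the window evenly. Rows are ordered by descending row sum of
#' `order_by` (another signal matrix over the same intervals, or the matrix
#' itself), matching heatmaps ordered by the signal of a designated track.
#'
#' @param intervals GRanges of regions (e.g. peaks).
#' @param coverage GRanges of fragments (per-base depth = number of
#'   fragments overlapping the base), or a named RleList of per-base
#'   coverage.
#' @param flank half-window in bp.
#' @param bins number of bins across the 2*flank window.
#' @param order_by optional matrix supplying the row order.
#' @return object of class `signal_matrix`: list with `matrix` (rows in
#'   the ordered orientation), `profile` (column means), `order` (original
#'   row indices in plotted order).
#' @export
signal_matrix <- function(intervals, coverage, flank = 5000L, bins = 100L,
                          order_by = NULL) {
  stopifnot(is(intervals, "GRanges"))
  if ((2 * flank) %% bins != 0)
    stop("bins must divide the 2*flank window evenly")
  binw <- (2L * flank) %/% bins
  cov <- if (is(coverage, "GRanges"))
    GenomicRanges::coverage(coverage) else coverage
  centers <- midpoints(intervals)
  chroms <- as.character(GenomicRanges::seqnames(intervals))
  m <- matrix(0, nrow = length(intervals), ncol = bins)
  for (i in seq_along(intervals)) {
    ch <- chroms[i]
    r <- if (ch %in% names(cov)) cov[[ch]] else S4Vectors::Rle(0L, 0L)
    from <- centers[i] - flank + 1L   # window is [centre-flank, centre+flank)
    to <- centers[i] + flank
    win <- numeric(2L * flank)        # out-of-genome bases count as zero
    ss <- max(1L, from); ee <- min(length(r), to)
    if (ee >= ss)
      win[(ss - from + 1L):(ee - from + 1L)] <- as.numeric(r[ss:ee])
    m[i, ] <- colMeans(matrix(win, nrow = binw))
  }
  key <- if (is.null(order_by)) m else order_by
  ord <- order(rowSums(key), decreasing = TRUE)
  structure(list(matrix = m[ord, , drop = FALSE], profile = colMeans(m),
                 order = ord, binsize = binw, flank = flank),
            class = "signal_matrix")
}

#' Assign peaks to genomic features by priority
#'
#' Each peak is assigned the single highest-priority feature overlapping
#' its centre; peaks whose centre overlaps nothing are intergenic.
#'
#' @param peaks GRanges.
#' @param features GRanges with a `name` metadata column of feature labels.
#' @param priority character vector, highest priority first. Labels absent
#'   from `features` are allowed; `"intergenic"` is implicit last.
#' @return named numeric vector of fractions (sums to 1) over
#'   `c(priority, "intergenic")`.
#' @export
feature_distribution <- function(peaks, features,
                                 priority = c("promoter", "exon", "intron",
                                              "downstream")) {
  stopifnot(is(peaks, "GRanges"), is(features, "GRanges"))
  if (anyDuplicated(priority)) stop("duplicate priority labels")
  labs <- S4Vectors::mcols(features)$name
  if (is.null(labs)) stop("features need a 'name' column")
  centers <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                    IRanges::IRanges(midpoints(peaks),
                                                     width = 1L))
  ov <- GenomicRanges::findOverlaps(centers, features,
                                    ignore.strand = TRUE)
  assigned <- rep("intergenic", length(peaks))
  if (length(ov)) {
    dt <- data.table::data.table(
      peak = S4Vectors::queryHits(ov),
      pri = match(labs[S4Vectors::subjectHits(ov)], priority))
    dt <- dt[!is.na(pri)]
    if (nrow(dt)) {
      best <- dt[, list(pri = min(pri)), by = "peak"]
      assigned[best$peak] <- priority[best$pri]
    }
  }
  lev <- c(priority, "intergenic")
  frac <- table(factor(assigned, levels = lev)) / length(peaks)
  setNames(as.numeric(frac), lev)
}

#' Read a BED3/BED4 peak file into GRanges
#' @param path BED path (0-based half-open).
#' @return GRanges.
#' @export
read_peaks_bed <- function(path) read_annotation_bed(path)

#' Write a GRanges as BED3/BED4
#' @param gr GRanges (a `name` column is written when present).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bed <- function(gr, path) {
  dt <- data.table::data.table(chrom = as.character(seqnames(gr)),
                               start = bed0_start(gr),
                               end = GenomicRanges::end(gr))
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) dt[, name := nm]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
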