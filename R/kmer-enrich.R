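## Normalisation, salt-fraction pooling, IgG averaging and the enrichment
## call. A normalised table carries its own floor value (missing_floor /
## total bases) so that later unions — pooling, control averaging, the
## final join against the control — can fill absent k-mers with the
## replicate-specific floored rate, exactly as the floor-then-divide rule
## implies.

new_norm_table <- function(dt, replicate, total_bases, floor_value) {
  data.table::setkey(dt, kmer)
  structure(dt, class = c("norm_kmer_table", class(dt)),
            replicate = replicate, total_bases = total_bases,
            floor_value = floor_value)
}

#' Normalise k-mer counts by total base counts
#'
#' Joins the replicate tables over the union of their k-mers, floors
#' missing raw counts at `missing_floor` (absence could mean a count of 0
#' or 1, so the floor deliberately underestimates enrichment while keeping
#' fold changes defined), then divides by each replicate's total base
#' count.
#'
#' @param tables named list of [count_kmers()] tables (names are replicate
#'   ids), or a single table.
#' @param base_counts named numeric vector of total base counts (bp) per
#'   replicate, aligned with `tables` by name or position.
#' @param cfg a [kmer_config()].
#' @return named list of `norm_kmer_table` objects (data.table columns
#'   `kmer`, `value`; attributes `replicate`, `total_bases`, `floor_value`).
#' @export
normalize_counts <- function(tables, base_counts, cfg = kmer_config()) {
  if (inherits(tables, "kmer_table")) tables <- list(tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- paste0("rep", seq_along(tables))
  if (is.null(names(base_counts))) names(base_counts) <- names(tables)
  if (any(base_counts <= 0) || any(is.na(base_counts)))
    stop("total base counts must be positive for normalisation")
  if (!all(names(tables) %in% names(base_counts)))
    stop("base_counts missing for some replicates")
  union_kmers <- sort(unique(unlist(lapply(tables, function(t) t$kmer),
                                    use.names = FALSE)))
  out <- lapply(names(tables), function(id) {
    B <- as.numeric(base_counts[[id]])
    tab <- tables[[id]]
    raw <- rep(cfg$missing_floor, length(union_kmers))
    if (nrow(tab)) {
      m <- match(union_kmers, tab$kmer)
      raw[!is.na(m)] <- tab$count[m[!is.na(m)]]
    }
    new_norm_table(data.table::data.table(kmer = union_kmers,
                                          value = raw / B),
                   replicate = id, total_bases = B,
                   floor_value = cfg$missing_floor / B)
  })
  names(out) <- names(tables)
  out
}

## Value lookup with floor fill over an arbitrary k-mer union.
norm_values_at <- function(tab, kmers) {
  v <- rep(attr(tab, "floor_value"), length(kmers))
  m <- match(kmers, tab$kmer)
  v[!is.na(m)] <- tab$value[m[!is.na(m)]]
  v
}

#' Pool low- and high-salt fractions of one replicate
#'
#' Each fraction is normalised by its own base count first; pooling sums
#' the normalised values over the union of k-mers, filling a k-mer absent
#' from one fraction with that fraction's floored rate.
#'
#' @param low,high `norm_kmer_table` objects with the same replicate id.
#' @return a pooled `norm_kmer_table`.
#' @export
pool_salt_fractions <- function(low, high) {
  stopifnot(inherits(low, "norm_kmer_table"),
            inherits(high, "norm_kmer_table"))
  if (!identical(attr(low, "replicate"), attr(high, "replicate")))
    stop("salt fractions belong to different replicates: ",
         attr(low, "replicate"), " vs ", attr(high, "replicate"))
  u <- sort(unique(c(low$kmer, high$kmer)))
  new_norm_table(
    data.table::data.table(kmer = u,
                           value = norm_values_at(low, u) +
                                   norm_values_at(high, u)),
    replicate = attr(low, "replicate"),
    total_bases = attr(low, "total_bases") + attr(high, "total_bases"),
    floor_value = attr(low, "floor_value") + attr(high, "floor_value"))
}

#' Average IgG control replicates
#'
#' Arithmetic mean of normalised counts per k-mer over the union; a control
#' replicate lacking a k-mer contributes its floored rate.
#'
#' @param igg_tables list of `norm_kmer_table` control replicates.
#' @return a `norm_kmer_table` whose replicate id is `"control_avg"`.
#' @export
average_control <- function(igg_tables) {
  if (!length(igg_tables)) stop("need at least one control replicate")
  stopifnot(all(vapply(igg_tables, inherits, TRUE, "norm_kmer_table")))
  u <- sort(unique(unlist(lapply(igg_tables, function(t) t$kmer),
                          use.names = FALSE)))
  vals <- vapply(igg_tables, norm_values_at, numeric(length(u)), kmers = u)
  avg <- if (length(u)) rowMeans(matrix(vals, nrow = length(u))) else
    numeric(0)
  new_norm_table(
    data.table::data.table(kmer = u, value = avg),
    replicate = "control_avg",
    total_bases = mean(vapply(igg_tables, attr, numeric(1), "total_bases")),
    floor_value = mean(vapply(igg_tables, attr, numeric(1), "floor_value")))
}

#' Call k-mer enrichment against an averaged control
#'
#' Per replicate, a k-mer is eligible iff its normalised count exceeds
#' `norm_threshold` (the filter acts per replicate: a replicate below the
#' threshold cannot contribute to the call). Fold change is the replicate's
#' normalised count over the averaged control's. A replicate "passes" for a
#' k-mer when it is both eligible and has fold change above `fc_threshold`;
#' the k-mer is called enriched when at least `min_enriched_replicates`
#' replicates pass.
#'
#' @param targets named list of target `norm_kmer_table` replicates.
#' @param control_avg averaged control from [average_control()].
#' @param cfg a [kmer_config()].
#' @return object of class `enrichment_result`: data.table with `kmer`,
#'   one `value_<rep>` and `fc_<rep>` column per replicate, `control_avg`,
#'   `n_passing` and logical `enriched`.
#' @export
call_enrichment <- function(targets, control_avg, cfg = kmer_config()) {
  if (inherits(targets, "norm_kmer_table")) targets <- list(targets)
  stopifnot(all(vapply(targets, inherits, TRUE, "norm_kmer_table")),
            inherits(control_avg, "norm_kmer_table"))
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    names(targets) <- vapply(targets, attr, "", "replicate")
  u <- sort(unique(c(unlist(lapply(targets, function(t) t$kmer),
                            use.names = FALSE), control_avg$kmer)))
  ctrl <- norm_values_at(control_avg, u)
  if (any(ctrl <= 0)) stop("control contains non-positive values")
  res <- data.table::data.table(kmer = u)
  n_pass <- integer(length(u))
  for (id in names(targets)) {
    v <- norm_values_at(targets[[id]], u)
    fc <- v / ctrl
    res[, paste0("value_", id) := v]
    res[, paste0("fc_", id) := fc]
    n_pass <- n_pass + as.integer(v > cfg$norm_threshold &
                                    fc > cfg$fc_threshold)
  }
  res[, control_avg := ctrl]
  res[, n_passing := n_pass]
  res[, enriched := n_pass >= cfg$min_enriched_replicates]
  structure(res, class = c("enrichment_result", class(res)),
            cfg = cfg, replicates = names(targets))
}

#' Enriched k-mer sequences of an enrichment result
#' @param result an `enrichment_result`.
#' @return character vector of canonical k-mers called enriched.
#' @export
enriched_kmers <- function(result) {
  stopifnot(inherits(result, "enrichment_result"))
  result$kmer[result$enriched]
}

#' Write enriched k-mers as FASTA with sequential integer headers
#'
#' Headers are ">1", ">2", ... in table order, matching the downstream
#' mapping convention where the k-mer id is its rank.
#'
#' @param result an `enrichment_result` (or character vector of k-mers).
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
write_enriched_fasta <- function(result, path) {
  kmers <- if (is.character(result)) result else enriched_kmers(result)
  ss <- Biostrings::DNAStringSet(kmers)
  names(ss) <- as.character(seq_along(kmers))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write the full enrichment table as TSV
#' @param result an `enrichment_result`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_enrichment_tsv <- function(result, path) {
  data.table::fwrite(as.data.table(result), path, sep = "\t")
  invisible(path)
}
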