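## Protein-abundance panel statistics: per-clone log2 fold changes versus
## the parental mean, column-median centering, per-protein one-sample
## t-tests, and the median log2FC of an annotated protein panel (e.g.
## centromere- and pericentromere-associated proteins).

#' Per-clone log2 fold changes versus the parental mean
#'
#' The parental reference is the arithmetic mean of the parental samples'
#' abundances per protein; each knockout clone's abundance is expressed as
#' log2(clone / parental mean). Abundances must be positive (sum-normalised
#' upstream). Proteins quantified in fewer than `min_fraction` of samples
#' are dropped; remaining missing values propagate as `NA` per
#' protein-clone pair (no imputation).
#'
#' @param abundance numeric matrix, proteins x samples (rownames = protein
#'   ids).
#' @param design character vector over samples: `"parental"` for parental
#'   samples, any other label names the knockout clone. Replicate samples
#'   of one clone are averaged (mean abundance) before the ratio.
#' @param min_fraction minimum fraction of samples a protein must be
#'   quantified in.
#' @return numeric matrix, proteins x clones, of log2 fold changes.
#' @export
log2fc_vs_parental <- function(abundance, design, min_fraction = 0.5) {
  abundance <- as.matrix(abundance)
  if (length(design) != ncol(abundance))
    stop("design must label every sample column")
  if (!any(design == "parental")) stop("need at least one parental sample")
  if (all(design == "parental")) stop("need at least one KO clone sample")
  if (any(abundance <= 0, na.rm = TRUE))
    stop("abundances must be positive")
  keep <- rowMeans(!is.na(abundance)) >= min_fraction
  abundance <- abundance[keep, , drop = FALSE]
  par_mean <- rowMeans(abundance[, design == "parental", drop = FALSE],
                       na.rm = TRUE)
  clones <- setdiff(unique(design), "parental")
  out <- vapply(clones, function(cl) {
    v <- rowMeans(abundance[, design == cl, drop = FALSE], na.rm = TRUE)
    log2(v / par_mean)
  }, numeric(nrow(abundance)))
  out <- matrix(out, nrow = nrow(abundance),
                dimnames = list(rownames(abundance), clones))
  out[is.nan(out)] <- NA_real_
  out
}

#' Subtract the column median from each clone column
#'
#' Centers each clone's log2FC distribution at zero so panel shifts are
#' read against the proteome-wide background; idempotent.
#'
#' @param log2fc numeric matrix, proteins x clones.
#' @return centered matrix (every column has median 0 over non-missing
#'   values).
#' @export
median_center <- function(log2fc) {
  log2fc <- as.matrix(log2fc)
  if (!nrow(log2fc)) stop("need at least one protein")
  meds <- apply(log2fc, 2L, stats::median, na.rm = TRUE)
  sweep(log2fc, 2L, meds)
}

#' Per-protein mean log2FC and one-sample t-test
#'
#' Two-sided one-sample t-test of each protein's centered log2FCs against
#' zero, computed from the formula: t = mean / (sd / sqrt(n)), df = n - 1.
#' Proteins with fewer than 2 non-missing values or zero variance get a
#' missing p-value.
#'
#' @param centered numeric matrix, proteins x clones (from
#'   [median_center()]).
#' @return data.table with `protein`, `mean_log2fc`, `n`, `t`, `p_value`.
#' @export
protein_tests <- function(centered) {
  centered <- as.matrix(centered)
  rows <- lapply(seq_len(nrow(centered)), function(i) {
    v <- centered[i, ]
    v <- v[!is.na(v)]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    if (n < 2L) return(data.table::data.table(
      protein = rownames(centered)[i], mean_log2fc = m, n = n,
      t = NA_real_, p_value = NA_real_))
    s <- stats::sd(v)
    if (s == 0) return(data.table::data.table(
      protein = rownames(centered)[i], mean_log2fc = m, n = n,
      t = NA_real_, p_value = NA_real_))
    tval <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tval), df = n - 1)
    data.table::data.table(protein = rownames(centered)[i],
                           mean_log2fc = m, n = n, t = tval, p_value = p)
  })
  data.table::rbindlist(rows)
}

#' Median log2FC of a protein panel per clone
#'
#' @param centered numeric matrix, proteins x clones.
#' @param panel character vector of panel protein ids; ids absent from the
#'   matrix are reported as dropped via an attribute.
#' @return named numeric vector of per-clone panel medians, with attribute
#'   `dropped` listing panel ids not present in the matrix.
#' @export
panel_median <- function(centered, panel) {
  centered <- as.matrix(centered)
  present <- intersect(panel, rownames(centered))
  dropped <- setdiff(panel, rownames(centered))
  if (!length(present)) stop("no panel proteins present in the matrix")
  med <- apply(centered[present, , drop = FALSE], 2L, stats::median,
               na.rm = TRUE)
  attr(med, "dropped") <- dropped
  med
}

#' Simulate a protein-abundance matrix with a planted panel shift
#'
#' Log-normal abundances for parental and clone samples; panel proteins are
#' shifted by `delta` log2 units in the clones over a median-zero
#' background; per-value log2 noise of s.d. `noise_sd`. Used to test
#' end-to-end recovery of the panel median.
#'
#' @param n_proteins,panel_size matrix and panel sizes.
#' @param n_clones,n_parental sample counts.
#' @param delta planted panel shift in log2 units.
#' @param noise_sd per-measurement log2 noise s.d.
#' @param seed integer seed.
#' @return list with `abundance` (matrix), `design` (character vector),
#'   `panel` (protein ids carrying the shift), `delta`.
#' @export
simulate_abundance_matrix <- function(n_proteins = 1000L, panel_size = 100L,
                                      n_clones = 3L, n_parental = 2L,
                                      delta = -0.4, noise_sd = 0.1,
                                      seed = 1L) {
  with_seed(seed, {
    prot <- sprintf("P%04d", seq_len(n_proteins))
    panel <- sample(prot, panel_size)
    base <- 2^rnorm(n_proteins, mean = 20, sd = 2)  # log-normal abundances
    design <- c(rep("parental", n_parental),
                paste0("KO", seq_len(n_clones)))
    m <- vapply(design, function(s) {
      shift <- if (s == "parental") 0 else
        ifelse(prot %in% panel, delta, 0)
      base * 2^(shift + rnorm(n_proteins, 0, noise_sd))
    }, numeric(n_proteins))
    dimnames(m) <- list(prot, paste0("S", seq_along(design)))
    list(abundance = m, design = design, panel = panel, delta = delta)
  })
}
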