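## End-to-end driver: simulate a CUT&RUN-like experiment over a toy repeat
## genome (target replicates with planted enrichment vs uniform IgG
## replicates), run the k-mer enrichment call, and map enriched k-mers back
## to the genome with class attribution.

#' Run a planted-enrichment experiment end to end
#'
#' Simulates `n_target` target replicates whose fragment starts are
#' up-weighted by `target_weight` over the selected annotation segment and
#' `n_igg` uniform IgG replicates, counts canonical k-mers per replicate,
#' normalises by total base counts, calls enrichment against the averaged
#' IgG, maps the enriched k-mers back by exact match and attributes the
#' sites to annotation classes.
#'
#' @param genome a `toy_genome` (e.g. `build_toy_genome(genome_spec())`).
#' @param enrich_class annotation class to up-weight (default the HOR
#'   array, the active-centromere stand-in).
#' @param target_weight fragment-start weight inside the enriched segment.
#' @param n_target,n_igg replicate counts.
#' @param n_pairs read pairs per replicate.
#' @param read_length read length (must exceed `cfg$k` for any k-mer
#'   windows to exist).
#' @param cfg a [kmer_config()].
#' @param seed integer seed; replicate seeds are derived from it.
#' @return list with `result` (enrichment_result), `hits` (GRanges),
#'   `pivot`, `percentages`, `enriched` (k-mer ids), the `genome` and the
#'   per-replicate `base_counts`.
#' @export
run_planted_experiment <- function(genome, enrich_class = "hor",
                                   target_weight = 10, n_target = 3L,
                                   n_igg = 3L, n_pairs = 50000L,
                                   read_length = 75L,
                                   cfg = kmer_config(), seed = 1L) {
  ann <- genome$annotation
  seg <- ann[S4Vectors::mcols(ann)$class == enrich_class]
  if (!length(seg)) stop("no annotation segment of class ", enrich_class)
  seg <- seg[1L]
  enr <- GenomicRanges::granges(seg)
  S4Vectors::mcols(enr)$weight <- target_weight
  sim_one <- function(weighted, s) {
    cfg_r <- read_sim_config(n_pairs = n_pairs, read_length = read_length,
                             enrichment = if (weighted) enr else NULL,
                             seed = s)
    simulate_reads(genome, cfg_r)
  }
  reps <- list()
  base_counts <- numeric(0)
  tables <- list()
  for (i in seq_len(n_target)) {
    id <- paste0("target", i)
    pr <- sim_one(TRUE, seed + i)
    tables[[id]] <- count_kmers(pr, cfg)
    base_counts[id] <- total_base_count(pr)
  }
  igg_ids <- paste0("igg", seq_len(n_igg))
  for (i in seq_len(n_igg)) {
    pr <- sim_one(FALSE, seed + 1000L + i)
    tables[[igg_ids[i]]] <- count_kmers(pr, cfg)
    base_counts[igg_ids[i]] <- total_base_count(pr)
  }
  norm <- normalize_counts(tables, base_counts, cfg)
  target_ids <- setdiff(names(norm), igg_ids)
  ctrl <- average_control(norm[igg_ids])
  result <- call_enrichment(norm[target_ids], ctrl, cfg)
  enriched <- enriched_kmers(result)
  hits <- if (length(enriched))
    map_exact(setNames(enriched, enriched), genome) else
      GenomicRanges::GRanges()
  pivot <- if (length(hits)) pivot_regions(hits, genome$annotation) else
    structure(matrix(integer(0), 0, 0), class = c("region_pivot",
                                                  "matrix"))
  pct <- if (length(enriched) && ncol(pivot))
    region_percentages(pivot, enriched) else setNames(numeric(0),
                                                      character(0))
  list(result = result, hits = hits, pivot = pivot, percentages = pct,
       enriched = enriched, genome = genome, base_counts = base_counts,
       enriched_segment = seg)
}

#' Canonical k-mers unique to one annotation segment
#'
#' Enumerates the canonical k-mers of a genome segment and keeps those
#' whose every exact occurrence in the genome lies inside that segment —
#' the ground-truth positive set for planted-enrichment recovery.
#'
#' @param genome a `toy_genome`.
#' @param segment GRanges of length 1 (e.g. the HOR array annotation row).
#' @param k k-mer length.
#' @return character vector of canonical k-mers unique to the segment.
#' @export
segment_unique_kmers <- function(genome, segment, k = 51L) {
  s <- GenomicRanges::start(segment)[1L]
  e <- GenomicRanges::end(segment)[1L]
  seq <- substr(genome$seq, s, e)
  if (nchar(seq) < k) return(character(0))
  starts <- seq_len(nchar(seq) - k + 1L)
  inside <- unique(canonical_kmer(substring(seq, starts,
                                            starts + k - 1L)))
  gstarts <- seq_len(nchar(genome$seq) - k + 1L)
  outside_idx <- gstarts < s | gstarts > e - k + 1L
  outside <- unique(canonical_kmer(substring(genome$seq,
                                             gstarts[outside_idx],
                                             gstarts[outside_idx] + k - 1L)))
  setdiff(inside, outside)
}
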