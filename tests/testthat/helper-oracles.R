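## Independent brute-force oracles. These deliberately avoid the package's
## implementation paths (no canonical_kmer, no PDict, no coverage/slice):
## plain loops and per-base arithmetic only.

## Reverse complement by explicit character table + reversal.
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(s, function(x) {
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

## Enumerate every k-window of every read, canonicalise by explicit
## comparison, tabulate, drop windows with N and counts < min_count.
oracle_count_kmers <- function(reads, k, min_count = 2L) {
  counts <- new.env(hash = TRUE)
  for (r in reads) {
    if (nchar(r) < k) next
    for (i in seq_len(nchar(r) - k + 1L)) {
      km <- substr(r, i, i + k - 1L)
      if (grepl("[^ACGT]", km)) next
      rc <- oracle_revcomp(km)
      canon <- if (km <= rc) km else rc
      counts[[canon]] <- (if (is.null(counts[[canon]])) 0L else
        counts[[canon]]) + 1L
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) out <- integer(0)
  out <- out[out >= min_count]
  out[order(names(out))]
}

## Two-strand exact substring scan: every position checked directly.
oracle_map_exact <- function(kmer, genome_seq) {
  k <- nchar(kmer)
  L <- nchar(genome_seq)
  hits <- list()
  rc <- oracle_revcomp(kmer)
  for (s in seq_len(max(0L, L - k + 1L))) {
    win <- substr(genome_seq, s, s + k - 1L)
    if (win == kmer)
      hits[[length(hits) + 1L]] <- c(start = s, strand = "+")
    if (win == rc && kmer != rc)
      hits[[length(hits) + 1L]] <- c(start = s, strand = "-")
  }
  if (!length(hits))
    return(data.frame(start = integer(0), strand = character(0)))
  df <- as.data.frame(do.call(rbind, hits), stringsAsFactors = FALSE)
  df$start <- as.integer(df$start)
  df[order(df$start, df$strand), ]
}

## Per-base coverage sweep over a single chromosome of length L:
## count supporting replicate sets per base, return maximal runs >= k.
oracle_consensus <- function(sets, L, min_support) {
  depth <- integer(L)
  for (gr in sets) {
    covered <- logical(L)
    for (i in seq_along(gr)) {
      s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
      covered[s:min(e, L)] <- TRUE
    }
    depth <- depth + as.integer(covered)
  }
  ok <- depth >= min_support
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  data.frame(start = starts[runs$values], end = ends[runs$values])
}

## Connected components of the bipartite overlap graph by label
## propagation over a per-base union-of-events scan.
oracle_shared_events <- function(a, b) {
  ov <- list()
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (GenomicRanges::start(a)[i] <= GenomicRanges::end(b)[j] &&
        GenomicRanges::start(b)[j] <= GenomicRanges::end(a)[i])
      ov[[length(ov) + 1L]] <- c(i, j)
  }
  if (!length(ov)) return(0L)
  edges <- do.call(rbind, ov)
  # union-find over A-nodes and B-nodes
  parent <- seq_len(length(a) + length(b))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(edges))) {
    pa <- find(edges[r, 1]); pb <- find(length(a) + edges[r, 2])
    if (pa != pb) parent[pa] <- pb
  }
  touched <- unique(c(edges[, 1], length(a) + edges[, 2]))
  length(unique(vapply(touched, find, integer(1))))
}

## Ground-truth ring averages: evaluate the radial function at every
## in-nucleus pixel centre and average per ring, mirroring the stated
## geometry but independently of ring_profile's grouping code.
oracle_ring_means <- function(img, radial_fun, cfg) {
  h <- nrow(img$channels$measure); w <- ncol(img$channels$measure)
  out <- list()
  for (n in seq_len(nrow(img$nuclei))) {
    fsub <- img$foci[img$foci$nucleus == n, ]
    sums <- matrix(0, nrow(fsub), cfg$n_rings)
    cnts <- matrix(0L, nrow(fsub), cfg$n_rings)
    for (x in seq_len(w)) for (y in seq_len(h)) {
      if (img$nucleus_labels[y, x] != n) next
      d <- sqrt((x - fsub$cx)^2 + (y - fsub$cy)^2)
      j <- which.min(d)
      dum <- d[j] * cfg$pixel_size
      if (dum > cfg$max_radius) next
      ring <- max(1L, ceiling(dum / (cfg$max_radius / cfg$n_rings)))
      sums[j, ring] <- sums[j, ring] + radial_fun(dum) +
        img$spec$background
      cnts[j, ring] <- cnts[j, ring] + 1L
    }
    for (j in seq_len(nrow(fsub)))
      out[[length(out) + 1L]] <- data.frame(
        nucleus = n, focus = fsub$focus[j], ring = seq_len(cfg$n_rings),
        mean = ifelse(cnts[j, ] > 0, sums[j, ] / cnts[j, ], NA_real_),
        n_pixels = cnts[j, ])
  }
  do.call(rbind, out)
}

## Rotate a matrix 90 degrees clockwise.
rotate90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

## Small random GRanges on one chromosome.
random_intervals <- function(n, L, max_width = 500L, chrom = "chr1") {
  s <- sample.int(L - 1L, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, pmin(s + w, L)))
}

## Random read set for counting oracles.
random_reads <- function(total_bases, read_len = 50L) {
  n <- max(1L, floor(total_bases / read_len))
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), read_len, replace = TRUE),
          collapse = ""), "")
}

## Small shared fixtures (built once per test run).
tiny_genome <- function(seed = 11) {
  plan <- data.frame(
    class = c("arm", "ct", "hor", "hsat2", "ct", "arm"),
    length = c(1500, 800, NA, 600, 800, 1500),
    monomers = c(NA, NA, 10, NA, NA, NA),
    detail = c("", "p_arm", "S1C1H1L", "", "q_arm", ""))
  build_toy_genome(genome_spec(segments = plan, seed = seed))
}
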