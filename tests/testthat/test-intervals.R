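gr1 <- function(s, e, chrom = "chr1")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))

test_that("consensus worked examples", {
  # 0-based half-open [0,100),[50,150),[120,200) are 1-based [1,100],...
  a <- gr1(1, 100); b <- gr1(51, 150); c <- gr1(121, 200)
  cons <- consensus_intervals(list(a, b, c), min_support = 2)
  expect_identical(GenomicRanges::start(cons), c(51L, 121L))
  expect_identical(GenomicRanges::end(cons), c(100L, 150L))
  cons <- consensus_intervals(list(a, a, a), min_support = 2)
  expect_identical(GenomicRanges::start(cons), 1L)
  expect_identical(GenomicRanges::end(cons), 100L)
  expect_length(consensus_intervals(list(a), min_support = 2), 0L)
  expect_error(consensus_intervals(list(a, b), min_support = 0),
               "min_support")
})

test_that("consensus equals the per-base coverage sweep on random sets", {
  set.seed(13)
  for (trial in 1:30) {
    L <- 10000L
    nsets <- sample(2:5, 1)
    sets <- lapply(seq_len(nsets), function(i)
      random_intervals(sample(1:20, 1), L))
    ms <- sample(1:nsets, 1)
    got <- consensus_intervals(sets, min_support = ms)
    want <- oracle_consensus(sets, L, ms)
    expect_identical(GenomicRanges::start(got), as.integer(want$start))
    expect_identical(GenomicRanges::end(got), as.integer(want$end))
  }
})

test_that("venn counts: identical, disjoint, many-to-one", {
  a <- gr1(c(1, 200, 400), c(100, 300, 500))
  v <- overlap_venn(a, a)
  expect_equal(v[c("A_only", "B_only", "shared")],
               list(A_only = 0L, B_only = 0L, shared = 3L))
  b <- gr1(c(1000, 2000), c(1100, 2100))
  v <- overlap_venn(a, b)
  expect_equal(v[c("A_only", "B_only", "shared")],
               list(A_only = 3L, B_only = 2L, shared = 0L))
  # one A interval overlapped by two B intervals: one merged event
  a1 <- gr1(1, 100)
  b2 <- gr1(c(1, 60), c(50, 120))
  v <- overlap_venn(a1, b2)
  expect_equal(v[c("A_only", "B_only", "shared")],
               list(A_only = 0L, B_only = 0L, shared = 1L))
  expect_identical(v$B_in_overlap, 2L)
})

test_that("venn shared events equal the connected-components oracle", {
  set.seed(29)
  for (trial in 1:20) {
    a <- random_intervals(sample(1:15, 1), 5000L)
    b <- random_intervals(sample(1:15, 1), 5000L)
    expect_identical(overlap_venn(a, b)$shared,
                     oracle_shared_events(a, b))
  }
})

test_that("peak categorisation partitions and respects the rules", {
  pbrm1 <- gr1(c(1, 200, 400), c(100, 300, 500))
  par_smarca4 <- gr1(1, 100)
  ko <- gr1(c(250, 1000), c(320, 1100))
  cats <- categorize_peaks(pbrm1, par_smarca4, ko)
  expect_identical(GenomicRanges::start(cats$PBRM1_specific), c(1L, 400L))
  expect_identical(GenomicRanges::start(cats$PBRM1_non_specific), 200L)
  expect_identical(GenomicRanges::start(cats$KO_specific), 1000L)
  # partition identity
  expect_identical(length(cats$PBRM1_specific) +
                     length(cats$PBRM1_non_specific), length(pbrm1))
  # empty KO set: everything specific
  cats <- categorize_peaks(pbrm1, par_smarca4, GenomicRanges::GRanges())
  expect_identical(length(cats$PBRM1_specific), 3L)
  expect_length(cats$KO_specific, 0L)
  # lax definition keeps KO peaks that overlap pbrm1 but not parental
  ko2 <- gr1(450, 520)
  strictcats <- categorize_peaks(pbrm1, par_smarca4, ko2, strict = TRUE)
  laxcats <- categorize_peaks(pbrm1, par_smarca4, ko2, strict = FALSE)
  expect_length(strictcats$KO_specific, 0L)
  expect_length(laxcats$KO_specific, 1L)
})

test_that("reldist closed-form examples", {
  ref <- gr1(c(0, 100), c(0, 100)) # midpoints 0 and 100
  rd <- relative_distance(gr1(50, 50), ref)
  expect_equal(rd$reldist, 0.5)
  rd <- relative_distance(gr1(0, 0), ref)
  expect_equal(rd$reldist, 0)
  rd <- relative_distance(gr1(25, 25), ref)
  expect_equal(rd$reldist, 0.25)
  # query outside the outermost reference midpoints is skipped
  rd <- relative_distance(gr1(c(25, 500), c(25, 500)), ref)
  expect_length(rd$reldist, 1L)
  # reference with < 2 locations warns and returns empty
  expect_warning(rd <- relative_distance(gr1(10, 10), gr1(5, 5)),
                 "< 2 locations")
  expect_length(rd$reldist, 0L)
})

test_that("reldist is invariant under coordinate reflection", {
  set.seed(41)
  L <- 100000L
  # point locations so every midpoint reflects exactly as x -> L - x
  rp <- sort(sample.int(L, 20)); qp <- sample.int(L, 200)
  ref <- gr1(rp, rp); q <- gr1(qp, qp)
  fwd <- relative_distance(q, ref)$reldist
  rev <- relative_distance(gr1(L - qp, L - qp), gr1(L - rp, L - rp))$reldist
  expect_equal(sort(fwd), sort(rev))
})

test_that("reldist uniform null has mean 0.25 and uniform distribution", {
  ref_mid <- seq(5000, by = 10000, length.out = 200)
  ref <- gr1(ref_mid, ref_mid)
  set.seed(99)
  q <- round(runif(10000, min(ref_mid), max(ref_mid)))
  rd <- relative_distance(gr1(q, q), ref)
  expect_lt(abs(mean(rd$reldist) - 0.25), 0.01)
  ks <- suppressWarnings(stats::ks.test(rd$reldist, "punif", 0, 0.5))
  expect_gt(ks$p.value, 0.01)
  # cumulative curve is monotone, ends at 1
  expect_true(all(diff(rd$curve$cum_fraction) >= 0))
  expect_equal(tail(rd$curve$cum_fraction, 1), 1)
})

test_that("signal matrix bins coverage around interval centres", {
  peaks <- gr1(c(10000, 30000), c(10000, 30000))
  # uniform coverage c everywhere -> all cells c
  frags <- gr1(1, 60000)
  sm <- signal_matrix(peaks, c(frags, frags, frags), flank = 5000,
                      bins = 10)
  expect_true(all(abs(sm$matrix - 3) < 1e-12))
  expect_equal(sm$profile, rep(3, 10))
  # single fragment exactly covering one bin of one interval
  binw <- 1000L
  frag1 <- gr1(10000 - 5000 + 1, 10000 - 5000 + binw)
  sm <- signal_matrix(peaks, frag1, flank = 5000, bins = 10)
  m_orig <- sm$matrix[order(sm$order), , drop = FALSE]
  expect_equal(m_orig[1, 1], 1)
  expect_equal(sum(m_orig), 1)
  # ordering: row with larger sum first
  fragA <- gr1(rep(25001, 9), rep(35000, 9))
  sm <- signal_matrix(peaks, c(frag1, fragA), flank = 5000, bins = 10)
  expect_identical(sm$order, c(2L, 1L))
  expect_error(signal_matrix(peaks, frag1, flank = 5000, bins = 3),
               "divide")
})

test_that("feature distribution assigns by priority at the peak centre", {
  feats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 1, 500, 900), c(200, 400, 600, 1000)),
    name = c("promoter", "intron", "exon", "downstream"))
  # centre in promoter AND intron -> promoter wins
  fd <- feature_distribution(gr1(50, 150), feats)
  expect_equal(fd[["promoter"]], 1)
  # no features -> all intergenic
  fd <- feature_distribution(gr1(50, 150), GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    name = character(0)))
  expect_equal(fd[["intergenic"]], 1)
  # 4 peaks, one per category
  peaks <- gr1(c(300, 520, 920, 5000), c(350, 580, 980, 5100))
  fd <- feature_distribution(peaks, feats)
  expect_equal(unname(fd[c("intron", "exon", "downstream", "intergenic")]),
               rep(0.25, 4))
  expect_equal(sum(fd), 1)
  expect_error(feature_distribution(peaks, feats,
                                    priority = c("exon", "exon")),
               "duplicate")
})
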