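test_that("exact mapping finds forward and reverse hits", {
  # on this genome ACGTT occurs at 0-based 4 (+) and its reverse
  # complement AACGT at 0-based 3 (giving a - hit), as the brute-force
  # scan confirms: the A-run makes both strands match
  genome <- c(chrU = "AAAAACGTTAAAA")
  h <- map_exact(c(a = "ACGTT"), genome)
  want <- oracle_map_exact("ACGTT", genome[[1]])
  expect_identical(GenomicRanges::start(h), want$start)
  expect_identical(as.character(GenomicRanges::strand(h)), want$strand)
  expect_identical(GenomicRanges::start(h), c(4L, 5L))  # 0-based 3, 4
  expect_identical(as.character(GenomicRanges::strand(h)), c("-", "+"))
  h <- map_exact(c(b = "AACGT"), genome)  # revcomp of ACGTT
  want <- oracle_map_exact("AACGT", genome[[1]])
  expect_identical(GenomicRanges::start(h), want$start)
  expect_identical(as.character(GenomicRanges::strand(h)), want$strand)
  expect_length(map_exact(c(x = "GGGGG"), genome), 0L)
  # unambiguous single-hit versions of the same examples
  genome2 <- c(chrU = "GGGGACGTTGGGG")
  h <- map_exact(c(a = "ACGTT"), genome2)
  expect_identical(GenomicRanges::start(h), 5L)  # 0-based 4
  expect_identical(as.character(GenomicRanges::strand(h)), "+")
  h <- map_exact(c(b = "AACGT"), genome2)
  expect_identical(GenomicRanges::start(h), 5L)
  expect_identical(as.character(GenomicRanges::strand(h)), "-")
})

test_that("palindromic k-mers collapse coincident +/- hits to one + hit", {
  genome <- c(chrU = "TTACGTTT")
  h <- map_exact(c(p = "ACGT"), genome)
  expect_length(h, 1L)
  expect_identical(as.character(GenomicRanges::strand(h)), "+")
})

test_that("every hit substring-verifies and matches the brute-force scan", {
  g <- tiny_genome()
  set.seed(5)
  # probe with k-mers drawn from the genome (hor windows map many times)
  starts <- sample(nchar(g$seq) - 20L, 30)
  probes <- substring(g$seq, starts, starts + 20L)
  probes <- c(probes, revcomp(probes[1:5]), "ACGTACGTACGTACGTACGTA")
  names(probes) <- as.character(seq_along(probes))
  hits <- map_exact(probes, g)
  expect_gt(length(hits), 0L)
  for (i in seq_along(hits)) {
    s <- GenomicRanges::start(hits)[i]; e <- GenomicRanges::end(hits)[i]
    km <- S4Vectors::mcols(hits)$kmer[i]
    sub <- substr(g$seq, s, e)
    if (as.character(GenomicRanges::strand(hits))[i] == "+")
      expect_identical(sub, km)
    else expect_identical(sub, oracle_revcomp(km))
  }
  # set equality against the two-strand substring scan, per k-mer
  for (id in unique(S4Vectors::mcols(hits)$kmer_id)) {
    km <- probes[[id]]
    want <- oracle_map_exact(km, g$seq)
    got <- hits[S4Vectors::mcols(hits)$kmer_id == id]
    expect_identical(GenomicRanges::start(got), want$start)
    expect_identical(as.character(GenomicRanges::strand(got)),
                     want$strand)
  }
})

test_that("max_hits truncates left-to-right and flags saturated k-mers", {
  genome <- c(chrU = strrep("AC", 50))
  h <- map_exact(c(k = "ACACA"), genome, max_hits = 10)
  expect_length(h, 10L)
  expect_true(all(S4Vectors::mcols(h)$truncated))
  expect_identical(GenomicRanges::start(h), seq(1L, by = 2L, length.out = 10L))
  h2 <- map_exact(c(k = "ACACA"), genome, max_hits = 5000)
  expect_false(any(S4Vectors::mcols(h2)$truncated))
})

test_that("non-ACGT k-mers are skipped with a warning", {
  expect_warning(h <- map_exact(c(a = "ACGNT", b = "ACGTT"),
                                c(chrU = "AAAAACGTTAAAA")),
                 "skipped")
  expect_identical(unique(S4Vectors::mcols(h)$kmer_id), "b")
})

test_that("split_class truncates at the first underscore", {
  expect_identical(split_class("ct_1_1(p_arm)"), "ct")
  expect_identical(split_class("hor_1_1(S1C1H1L)"), "hor")
  expect_identical(split_class("arm"), "arm")
  expect_error(split_class(""), "empty")
})

test_that("region pivot counts hits per class, dropping unannotated", {
  ann <- GenomicRanges::GRanges(
    "chrU", IRanges::IRanges(c(1, 101), c(100, 200)),
    name = c("ct_1_1(p_arm)", "hor_1_1(x)"))
  mk_hits <- function(starts, id = "1") {
    GenomicRanges::GRanges("chrU", IRanges::IRanges(starts, starts + 9L),
                           kmer_id = id)
  }
  # 10 hits all inside hor
  piv <- pivot_regions(mk_hits(seq(101, 191, by = 10)), ann)
  expect_identical(piv["1", "hor"], 10L)
  # hit straddling the ct/hor boundary counts once per interval
  piv <- pivot_regions(mk_hits(96), ann)
  expect_identical(piv["1", ], c(ct = 1L, hor = 1L))
  # hits outside the annotation vanish
  piv <- pivot_regions(mk_hits(500), ann)
  expect_identical(nrow(piv), 0L)
})

test_that("region percentages follow the stated conventions", {
  piv <- matrix(c(1L, 0L, 2L, 0L, 0L, 3L, 1L, 0L, 0L, 5L, 0L, 0L, 0L, 4L),
                nrow = 7,
                dimnames = list(as.character(1:7), c("ct", "hor")))
  # 7 enriched k-mers of 10; k-mers 1,3,7(ct col? check below)
  enr <- as.character(1:10)
  pct <- region_percentages(piv, enr)
  expect_equal(pct[["ct"]], 100 * sum(piv[, "ct"] > 0) / 10)
  expect_equal(pct[["hor"]], 100 * sum(piv[, "hor"] > 0) / 10)
  # a k-mer hitting both classes contributes to both
  piv2 <- matrix(c(1L, 1L), nrow = 1,
                 dimnames = list("1", c("ct", "hor")))
  pct2 <- region_percentages(piv2, "1")
  expect_equal(unname(pct2), c(100, 100))
  # majority attribution picks the modal class only
  piv3 <- matrix(c(3L, 1L), nrow = 1,
                 dimnames = list("1", c("ct", "hor")))
  pct3 <- region_percentages(piv3, "1", attribution = "majority")
  expect_equal(pct3[["ct"]], 100); expect_equal(pct3[["hor"]], 0)
  expect_error(region_percentages(piv, character(0)), "empty")
})

test_that("genome-extracted hor k-mers map back inside the hor array", {
  g <- tiny_genome()
  hor <- g$annotation[S4Vectors::mcols(g$annotation)$class == "hor"]
  uniq <- segment_unique_kmers(g, hor, k = 31)
  expect_gt(length(uniq), 100L)
  set.seed(8)
  sel <- sample(uniq, 20)
  hits <- map_exact(setNames(sel, sel), g)
  expect_true(all(table(S4Vectors::mcols(hits)$kmer_id) >= 1))
  ov <- GenomicRanges::findOverlaps(hits, hor, ignore.strand = TRUE)
  expect_identical(length(unique(S4Vectors::queryHits(ov))), length(hits))
})
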