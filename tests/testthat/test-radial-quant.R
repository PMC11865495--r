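three_disk_image <- function() {
  simulate_nucleus_image(image_spec(
    size = 128, pixel_size = 0.1,
    nuclei = data.frame(cx = c(30, 95, 40), cy = c(30, 40, 95),
                        r = c(15, 18, 16)),
    foci = data.frame(nucleus = 1:3, cx = c(30, 95, 40),
                      cy = c(30, 40, 95), amplitude = 500, sigma = 2),
    seed = 2))
}

test_that("nucleus segmentation recovers disjoint disks", {
  img <- three_disk_image()
  lab <- segment_nuclei(img$channels$dna, min_area = 50)
  expect_identical(max(lab), 3L)
  # labels may be permuted relative to ground truth; Otsu on a binary
  # image recovers each rasterized disk mask exactly
  expect_identical(sort(tabulate(lab)), sort(tabulate(img$nucleus_labels)))
  expect_identical(lab > 0L, img$nucleus_labels > 0L)
  areas <- tabulate(lab)
  truth <- pi * img$nuclei$r^2
  # labels may be permuted; compare sorted areas
  expect_true(all(abs(sort(areas) / sort(truth) - 1) < 0.02))
})

test_that("provided masks pass through; blank images give zero nuclei", {
  img <- three_disk_image()
  expect_identical(segment_nuclei(img$channels$dna,
                                  masks = img$nucleus_labels),
                   img$nucleus_labels)
  expect_warning(lab <- segment_nuclei(matrix(0, 32, 32)), "zero nuclei")
  expect_identical(max(lab), 0L)
})

test_that("hole filling closes interior gaps", {
  mask <- matrix(FALSE, 21, 21)
  mask[5:15, 5:15] <- TRUE
  mask[9:11, 9:11] <- FALSE  # interior hole
  dna <- matrix(0, 21, 21); dna[mask] <- 100
  lab <- segment_nuclei(dna, min_area = 10)
  expect_identical(max(lab), 1L)
  expect_identical(sum(lab == 1L), 11L * 11L)
})

test_that("foci detection finds planted Gaussian spots", {
  img <- simulate_nucleus_image(image_spec(
    size = 96, pixel_size = 0.1,
    nuclei = data.frame(cx = 48, cy = 48, r = 35),
    foci = data.frame(nucleus = 1, cx = c(40, 50), cy = c(40, 40),
                      amplitude = 800, sigma = 1.5),
    seed = 3))
  det <- detect_foci(img$channels$foci, img$nucleus_labels)
  expect_identical(nrow(det$foci), 2L)  # two spots 10 px apart
  d <- sqrt((sort(det$foci$x) - c(40, 50))^2 +
              (det$foci$y[order(det$foci$x)] - 40)^2)
  expect_true(all(d < 1))  # centres within 1 px of ground truth
  # noise-only channel: no foci
  set.seed(6)
  noise <- matrix(rnorm(96 * 96, 100, 5), 96, 96)
  det0 <- detect_foci(noise, img$nucleus_labels)
  expect_identical(nrow(det0$foci), 0L)
})

test_that("ring profile: uniform channel gives every ring its value", {
  img <- three_disk_image()
  cfg <- ring_config(pixel_size = 0.1)
  uni <- matrix(100, 128, 128)
  rp <- ring_profile(uni, img$foci, img$nucleus_labels, cfg)
  expect_true(all(rp$intensity[rp$n_pixels > 0] == 100))
  # empty rings are NA, not zero (outer rings fall outside small nuclei)
  expect_true(all(is.na(rp$intensity[rp$n_pixels == 0])))
})

test_that("ring profile recovers a step ground truth within tolerance", {
  f <- function(r) ifelse(r < 1, 200, 50)
  img <- simulate_nucleus_image(image_spec(
    size = 128, pixel_size = 0.1,
    nuclei = data.frame(cx = 64, cy = 64, r = 50),
    # off-grid focus centre so no pixel sits exactly on a ring boundary
    foci = data.frame(nucleus = 1, cx = 64.3, cy = 63.6, amplitude = 500,
                      sigma = 2),
    radial_fun = f, background = 0, noise_sd = 0, seed = 4))
  cfg <- ring_config(pixel_size = 0.1)
  rp <- ring_profile(img$channels$measure, img$foci, img$nucleus_labels,
                     cfg)
  # rings 1-2 cover (0, 1] um -> 200; rings 3-8 -> 50 (2% boundary slack)
  expect_true(all(abs(rp$intensity[rp$ring <= 2] / 200 - 1) < 0.02))
  expect_true(all(abs(rp$intensity[rp$ring >= 3] / 50 - 1) < 0.02))
  # and the exact per-pixel oracle agrees ring by ring
  want <- oracle_ring_means(img, f, cfg)
  expect_equal(rp$intensity, want$mean)
  expect_identical(rp$n_pixels, as.integer(want$n_pixels))
})

test_that("pixel conservation: ring counts sum to assigned pixels", {
  img <- three_disk_image()
  cfg <- ring_config(pixel_size = 0.1)
  rp <- ring_profile(img$channels$measure, img$foci, img$nucleus_labels,
                     cfg)
  for (n in 1:3) {
    in_reach <- sum(rp$n_pixels[rp$nucleus == n])
    # every in-nucleus pixel within max_radius of its nearest focus
    px <- which(img$nucleus_labels == n)
    h <- nrow(img$nucleus_labels)
    xs <- ((px - 1L) %/% h) + 1L; ys <- ((px - 1L) %% h) + 1L
    fsub <- img$foci[img$foci$nucleus == n, ]
    dmin <- rep(Inf, length(px))
    for (j in seq_len(nrow(fsub)))
      dmin <- pmin(dmin, sqrt((xs - fsub$cx[j])^2 + (ys - fsub$cy[j])^2))
    expect_identical(in_reach, sum(dmin * 0.1 <= cfg$max_radius))
  }
})

test_that("ring means are invariant under 90-degree rotation", {
  f <- function(r) 150 * exp(-r / 1.5)
  img <- simulate_nucleus_image(image_spec(
    size = 100, pixel_size = 0.1,
    nuclei = data.frame(cx = 40, cy = 55, r = 30),
    foci = data.frame(nucleus = 1, cx = c(35, 50), cy = c(50, 60),
                      amplitude = 500, sigma = 2),
    radial_fun = f, background = 10, noise_sd = 0, seed = 5))
  cfg <- ring_config(pixel_size = 0.1)
  rp <- ring_profile(img$channels$measure, img$foci, img$nucleus_labels,
                     cfg)
  # rotate image and transform focus coordinates accordingly:
  # (x, y) -> (H + 1 - y, x) under clockwise rotation of the matrix
  H <- nrow(img$channels$measure)
  rot_measure <- rotate90(img$channels$measure)
  rot_labels <- rotate90(img$nucleus_labels)
  rot_foci <- data.frame(nucleus = img$foci$nucleus,
                         focus = img$foci$focus,
                         x = H + 1 - img$foci$cy, y = img$foci$cx)
  rp_rot <- ring_profile(rot_measure, rot_foci, rot_labels, cfg)
  expect_equal(rp_rot$intensity, rp$intensity)
  expect_identical(rp_rot$n_pixels, rp$n_pixels)
})

test_that("shape metrics: disk, 2:1 ellipse, physical area", {
  xs <- matrix(rep(1:101, each = 101), 101)
  ys <- matrix(rep(1:101, times = 101), 101)
  disk <- (xs - 51)^2 + (ys - 51)^2 <= 10^2
  m <- shape_metrics(disk, pixel_size = 0.1)
  expect_lt(m$eccentricity, 0.1)
  expect_lt(abs(m$area / pi - 1), 0.02)  # r = 10 px at 0.1 um -> pi um^2
  ell <- ((xs - 51) / 40)^2 + ((ys - 51) / 20)^2 <= 1
  m <- shape_metrics(ell, pixel_size = 0.1)
  expect_lt(abs(m$eccentricity - sqrt(1 - 1 / 4)), 0.03)
  expect_error(shape_metrics(matrix(FALSE, 5, 5)), "empty")
})

test_that("mutual-nearest-neighbour pairing and distances", {
  centers <- data.frame(x = c(0, 3), y = c(0, 4))
  pd <- paired_focus_distance(centers, pixel_size = 0.1)
  expect_equal(pd$pairs$distance, 0.5)
  # 3 collinear equally spaced foci: ties broken to one pair + 1 unpaired
  centers <- data.frame(x = c(0, 10, 20), y = 0)
  pd <- paired_focus_distance(centers, pixel_size = 0.1)
  expect_identical(nrow(pd$pairs), 1L)
  expect_length(pd$unpaired, 1L)
  # coincident centres pair at distance 0
  centers <- data.frame(x = c(5, 5), y = c(5, 5))
  expect_equal(paired_focus_distance(centers)$pairs$distance, 0)
  expect_length(paired_focus_distance(data.frame(x = 1, y = 1))$pairs$i,
                0L)
})

test_that("nuclear intensity normalises to the reference cohort median", {
  img <- three_disk_image()
  ch <- img$channels$measure
  ni <- nuclear_intensity(ch, img$nucleus_labels)
  expect_equal(stats::median(ni$normalized), 1)
  # single nucleus of uniform value v has mean v
  lab1 <- matrix(0L, 10, 10); lab1[3:6, 3:6] <- 1L
  ch1 <- matrix(7, 10, 10)
  ni1 <- nuclear_intensity(ch1, lab1)
  expect_equal(ni1$mean, 7)
  # doubling pixels and reference leaves normalised values unchanged
  niA <- nuclear_intensity(ch, img$nucleus_labels, reference = ni$mean)
  niB <- nuclear_intensity(2 * ch, img$nucleus_labels,
                           reference = 2 * ni$mean)
  expect_equal(niA$normalized, niB$normalized)
  expect_error(nuclear_intensity(ch, img$nucleus_labels,
                                 reference = numeric(0)), "empty")
})
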