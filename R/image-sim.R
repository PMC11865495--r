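## Synthetic nucleus images with known radial ground truth. Convention:
## images are numeric matrices indexed [row = y, col = x]; pixel centres
## sit at integer coordinates (x = 1..width, y = 1..height); physical
## distances are pixel distances times pixel_size (micrometres per pixel).

#' Specify a synthetic multi-channel nucleus image
#'
#' Channel 1 ("dna") contains uniform disk nuclei, channel 2 ("foci")
#' Gaussian foci, and channel 3 ("measure") a background plus a known
#' radial intensity function of the distance to the nearest focus, plus
#' Gaussian noise — the ground truth the ring-profiling pipeline is tested
#' against.
#'
#' @param size image size in pixels, `c(height, width)` or a scalar.
#' @param pixel_size micrometres per pixel.
#' @param nuclei data.frame with columns `cx`, `cy`, `r` (pixels), or
#'   `NULL` for one centred nucleus of radius 0.35 * min(size).
#' @param foci data.frame with columns `nucleus`, `cx`, `cy`, `amplitude`,
#'   `sigma` (pixels), or `NULL` to place `foci_per_nucleus` seeded random
#'   foci within half the nuclear radius (amplitude 500, sigma 2 px).
#' @param foci_per_nucleus used when `foci` is `NULL`.
#' @param radial_fun vectorised function of distance in micrometres giving
#'   the measured channel's focus-centred intensity; default a 150 *
#'   exp(-r / 1.5) decay.
#' @param background additive background of the measured channel.
#' @param noise_sd Gaussian noise s.d. of the measured channel.
#' @param seed integer seed.
#' @return object of class `image_spec`.
#' @export
image_spec <- function(size = 256L, pixel_size = 0.1, nuclei = NULL,
                       foci = NULL, foci_per_nucleus = 3L,
                       radial_fun = function(r) 150 * exp(-r / 1.5),
                       background = 50, noise_sd = 0, seed = 1L) {
  if (length(size) == 1L) size <- c(size, size)
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (is.null(nuclei))
    nuclei <- data.frame(cx = (size[2] + 1) / 2, cy = (size[1] + 1) / 2,
                         r = 0.35 * min(size))
  structure(list(size = as.integer(size), pixel_size = pixel_size,
                 nuclei = nuclei, foci = foci,
                 foci_per_nucleus = as.integer(foci_per_nucleus),
                 radial_fun = radial_fun, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "image_spec")
}

#' Simulate a multi-channel nucleus image with ground truth
#'
#' @param spec an [image_spec()]. Foci must lie inside their nucleus.
#' @return object of class `nucleus_image`: list with `channels` (named
#'   list of matrices: dna, foci, measure), `nuclei` and `foci` ground-truth
#'   tables, `nucleus_labels` (integer matrix), `pixel_size` and `spec`.
#' @export
simulate_nucleus_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  nuclei <- spec$nuclei
  with_seed(spec$seed, {
    foci <- spec$foci
    if (is.null(foci)) {
      foci <- do.call(rbind, lapply(seq_len(nrow(nuclei)), function(i) {
        ang <- runif(spec$foci_per_nucleus, 0, 2 * pi)
        rad <- nuclei$r[i] * 0.5 * sqrt(runif(spec$foci_per_nucleus))
        data.frame(nucleus = i, cx = nuclei$cx[i] + rad * cos(ang),
                   cy = nuclei$cy[i] + rad * sin(ang),
                   amplitude = 500, sigma = 2)
      }))
    }
    dcheck <- sqrt((foci$cx - nuclei$cx[foci$nucleus])^2 +
                     (foci$cy - nuclei$cy[foci$nucleus])^2)
    if (any(dcheck > nuclei$r[foci$nucleus]))
      stop("focus centre outside its nucleus")
    labels <- matrix(0L, h, w)
    for (i in seq_len(nrow(nuclei))) {
      inside <- (xs - nuclei$cx[i])^2 + (ys - nuclei$cy[i])^2 <=
        nuclei$r[i]^2
      labels[inside] <- i
    }
    dna <- matrix(0, h, w); dna[labels > 0L] <- 1000
    foci_ch <- matrix(0, h, w)
    for (j in seq_len(nrow(foci))) {
      d2 <- (xs - foci$cx[j])^2 + (ys - foci$cy[j])^2
      foci_ch <- foci_ch + foci$amplitude[j] *
        exp(-d2 / (2 * foci$sigma[j]^2))
    }
    dmin_px <- matrix(Inf, h, w)
    for (j in seq_len(nrow(foci))) {
      d <- sqrt((xs - foci$cx[j])^2 + (ys - foci$cy[j])^2)
      dmin_px <- pmin(dmin_px, d)
    }
    measure <- matrix(spec$background, h, w)
    if (nrow(foci))
      measure <- measure + spec$radial_fun(dmin_px * spec$pixel_size)
    if (spec$noise_sd > 0)
      measure <- measure + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    foci$focus <- seq_len(nrow(foci))
    structure(list(channels = list(dna = dna, foci = foci_ch,
                                   measure = measure),
                   nuclei = cbind(nucleus = seq_len(nrow(nuclei)), nuclei),
                   foci = foci, nucleus_labels = labels,
                   pixel_size = spec$pixel_size, spec = spec),
              class = "nucleus_image")
  })
}

#' @export
print.nucleus_image <- function(x, ...) {
  cat(sprintf("nucleus_image: %dx%d px (%.3g um/px), %d nuclei, %d foci\n",
              nrow(x$channels$dna), ncol(x$channels$dna), x$pixel_size,
              nrow(x$nuclei), nrow(x$foci)))
  invisible(x)
}

#' Write an image matrix as plain-text PGM (P2)
#'
#' Text-only interchange format for single-channel images (no binary image
#' libraries are assumed). Values are rounded and clipped to `[0, maxval]`.
#'
#' @param img numeric matrix.
#' @param path output path.
#' @param maxval maximum grey value.
#' @return invisibly, the path.
#' @export
write_pgm <- function(img, path, maxval = 65535L) {
  v <- pmin(pmax(round(img), 0L), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)),
             con)
  apply(v, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read a plain-text PGM (P2) image
#' @param path PGM path.
#' @return numeric matrix.
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  toks <- scan(text = paste(lines[-1], collapse = " "), quiet = TRUE)
  dims <- toks[1:2]
  matrix(toks[-(1:3)], nrow = dims[2], ncol = dims[1], byrow = TRUE)
}
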