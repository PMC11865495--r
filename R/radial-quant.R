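## Radial ring quantification of immunofluorescence foci: segment nuclei,
## detect foci, expand concentric rings to a fixed physical distance around
## each focus centre, and measure a second channel per ring — plus focus
## shape metrics, paired-focus distances and whole-nucleus intensities.

#' Ring-profiling configuration
#'
#' Defaults mirror the centromere quantification: rings expand to a total
#' distance of 4 micrometres from each focus centre, divided into 8 rings
#' of 0.5 um each; intensity per ring defaults to the mean over assigned
#' pixels (integrated intensity by flag).
#'
#' @param max_radius outer ring radius in micrometres.
#' @param n_rings number of rings.
#' @param pixel_size micrometres per pixel.
#' @param statistic `"mean"` or `"integrated"` per-ring intensity.
#' @return object of class `ring_config`.
#' @export
ring_config <- function(max_radius = 4, n_rings = 8L, pixel_size = 0.1,
                        statistic = c("mean", "integrated")) {
  statistic <- match.arg(statistic)
  if (max_radius <= 0 || n_rings < 1L) stop("invalid ring geometry")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(max_radius = max_radius, n_rings = as.integer(n_rings),
                 ring_width = max_radius / n_rings,
                 pixel_size = pixel_size, statistic = statistic),
            class = "ring_config")
}

## Otsu's threshold over a 256-bin histogram.
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257L)
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE), 256L)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p); w1 <- 1 - w0
  mu0 <- cumsum(p * mids) / pmax(w0, .Machine$double.eps)
  muT <- sum(p * mids)
  mu1 <- (muT - cumsum(p * mids)) / pmax(w1, .Machine$double.eps)
  between <- w0 * w1 * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  mids[which.max(between)]
}

## Label 4-connected components of a logical matrix (frontier BFS).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  todo <- which(mask)
  cur <- 0L
  neighbors <- function(idx) {
    r <- ((idx - 1L) %% h) + 1L
    up <- idx - 1L; up[r == 1L] <- NA
    dn <- idx + 1L; dn[r == h] <- NA
    lf <- idx - h; lf[idx <= h] <- NA
    rt <- idx + h; rt[idx > h * (w - 1L)] <- NA
    nb <- c(up, dn, lf, rt)
    nb[!is.na(nb)]
  }
  while (length(todo)) {
    seedpx <- todo[lab[todo] == 0L]
    if (!length(seedpx)) break
    cur <- cur + 1L
    frontier <- seedpx[1L]
    lab[frontier] <- cur
    while (length(frontier)) {
      nb <- unique(neighbors(frontier))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
    todo <- todo[lab[todo] == 0L]
  }
  lab
}

## Fill holes: background components not touching the image border become
## foreground.
fill_holes <- function(mask) {
  bg <- label_components(!mask)
  h <- nrow(mask); w <- ncol(mask)
  border_labels <- unique(c(bg[1, ], bg[h, ], bg[, 1], bg[, w]))
  holes <- bg > 0L & !(bg %in% border_labels)
  mask | holes
}

#' Segment nuclei from a DNA-stain channel
#'
#' Global Otsu threshold, hole filling, 4-connected labeling and a minimum
#' area filter. Supplying pre-computed label masks passes them through
#' unchanged.
#'
#' @param dna_channel numeric matrix (ignored when `masks` is given).
#' @param min_area minimum nucleus area in pixels.
#' @param masks optional integer label matrix to pass through.
#' @return integer label matrix (0 = background, 1..n = nuclei, relabeled
#'   contiguously after filtering).
#' @export
segment_nuclei <- function(dna_channel, min_area = 200L, masks = NULL) {
  if (!is.null(masks)) return(masks)
  thr <- otsu_threshold(dna_channel)
  mask <- dna_channel > thr
  if (!any(mask)) {
    warning("no foreground above Otsu threshold; zero nuclei")
    return(matrix(0L, nrow(dna_channel), ncol(dna_channel)))
  }
  mask <- fill_holes(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Detect foci within segmented nuclei
#'
#' Per nucleus, candidate pixels exceed background + `k_sd` standard
#' deviations (background and s.d. estimated from the nucleus pixels via
#' median and MAD); local maxima among candidates seed foci, thinned
#' greedily so kept peaks are at least `min_distance` pixels apart; focus
#' masks are the candidate pixels assigned to their nearest kept peak, and
#' centres are intensity-weighted centroids. Foci outside nuclei are
#' impossible by construction (candidates are nucleus pixels).
#'
#' @param focus_channel numeric matrix.
#' @param nuclei integer label matrix from [segment_nuclei()].
#' @param k_sd detection threshold in robust s.d. units above background.
#' @param min_distance minimum peak separation in pixels.
#' @return list with `foci` (data.table: nucleus, focus, x, y) and `masks`
#'   (integer matrix labeling each focus mask by focus id).
#' @export
detect_foci <- function(focus_channel, nuclei, k_sd = 5, min_distance = 5) {
  h <- nrow(focus_channel); w <- ncol(focus_channel)
  masks <- matrix(0L, h, w)
  rows <- list()
  fid <- 0L
  for (n in seq_len(max(nuclei, 0L))) {
    px <- which(nuclei == n)
    if (!length(px)) next
    vals <- focus_channel[px]
    bg <- stats::median(vals)
    s <- stats::mad(vals)
    if (s == 0) s <- stats::sd(vals)
    if (is.na(s) || s == 0) next
    thr <- bg + k_sd * s
    cand <- px[vals > thr]
    if (!length(cand)) next
    ## local maxima over the 8-neighborhood
    cx <- ((cand - 1L) %/% h) + 1L
    cy <- ((cand - 1L) %% h) + 1L
    is_max <- vapply(seq_along(cand), function(i) {
      x0 <- cx[i]; y0 <- cy[i]; v <- focus_channel[cand[i]]
      nbx <- pmax(1L, x0 - 1L):pmin(w, x0 + 1L)
      nby <- pmax(1L, y0 - 1L):pmin(h, y0 + 1L)
      v >= max(focus_channel[nby, nbx])
    }, logical(1))
    peaks <- cand[is_max]
    if (!length(peaks)) next
    peaks <- peaks[order(focus_channel[peaks], decreasing = TRUE)]
    keepx <- numeric(0); keepy <- numeric(0); kept <- integer(0)
    for (p in peaks) {
      x0 <- ((p - 1L) %/% h) + 1L; y0 <- ((p - 1L) %% h) + 1L
      if (!length(kept) ||
          all(sqrt((keepx - x0)^2 + (keepy - y0)^2) >= min_distance)) {
        kept <- c(kept, p); keepx <- c(keepx, x0); keepy <- c(keepy, y0)
      }
    }
    ## assign candidate pixels to the nearest kept peak
    dmat <- outer(cy, keepy, function(a, b) (a - b)^2) +
      outer(cx, keepx, function(a, b) (a - b)^2)
    nearest <- max.col(-dmat, ties.method = "first")
    for (j in seq_along(kept)) {
      fid <- fid + 1L
      sel <- cand[nearest == j]
      masks[sel] <- fid
      wgt <- focus_channel[sel]
      rows[[fid]] <- data.table::data.table(
        nucleus = n, focus = fid,
        x = sum((((sel - 1L) %/% h) + 1L) * wgt) / sum(wgt),
        y = sum((((sel - 1L) %% h) + 1L) * wgt) / sum(wgt))
    }
  }
  foci <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(nucleus = integer(0), focus = integer(0),
                           x = numeric(0), y = numeric(0))
  list(foci = foci, masks = masks)
}

#' Radial ring intensity profiles around foci
#'
#' Every in-nucleus pixel is assigned to the nearest focus centre of its
#' nucleus (ties to the lower focus id); the pixel joins ring
#' `ceiling(d / ring_width)` where d is the Euclidean distance from the
#' centre in micrometres (a pixel at the centre joins ring 1; ring 1 covers
#' (0, 0.5] um at the defaults). The configured statistic is computed per
#' ring over assigned pixels clipped to the nucleus mask and capped at
#' `max_radius`; rings with no pixels are reported as `NA`, not zero.
#'
#' @param measure_channel numeric matrix to quantify.
#' @param foci data.table with columns `nucleus`, `focus`, `x`, `y`
#'   (from [detect_foci()] or ground truth).
#' @param nuclei integer nucleus label matrix.
#' @param cfg a [ring_config()].
#' @return data.table with columns `nucleus`, `focus`, `ring`, `n_pixels`,
#'   `intensity` (one row per focus and ring, rings 1..n_rings).
#' @export
ring_profile <- function(measure_channel, foci, nuclei, cfg = ring_config()) {
  stopifnot(inherits(cfg, "ring_config"))
  foci <- data.table::as.data.table(foci)
  ## ground-truth tables carry cx/cy, detect_foci() emits x/y: accept both
  if (!"x" %in% names(foci) && "cx" %in% names(foci))
    data.table::setnames(foci, c("cx", "cy"), c("x", "y"))
  if (!all(c("nucleus", "focus", "x", "y") %in% names(foci)))
    stop("foci table needs columns nucleus, focus, x, y (or cx/cy)")
  h <- nrow(measure_channel)
  out <- list()
  for (n in unique(foci$nucleus)) {
    fsub <- foci[foci$nucleus == n]
    data.table::setorder(fsub, focus)
    px <- which(nuclei == n)
    if (!length(px) || !nrow(fsub)) next
    pxx <- ((px - 1L) %/% h) + 1L
    pxy <- ((px - 1L) %% h) + 1L
    dmat <- outer(pxy, fsub$y, function(a, b) (a - b)^2) +
      outer(pxx, fsub$x, function(a, b) (a - b)^2)
    nearest <- max.col(-dmat, ties.method = "first")  # lower id wins ties
    dpx <- sqrt(dmat[cbind(seq_along(px), nearest)])
    dum <- dpx * cfg$pixel_size
    ring <- pmax(1L, as.integer(ceiling(dum / cfg$ring_width)))
    keep <- dum <= cfg$max_radius
    vals <- measure_channel[px]
    dt <- data.table::data.table(focus = fsub$focus[nearest[keep]],
                                 ring = ring[keep], value = vals[keep])
    agg <- dt[, list(n_pixels = .N,
                     intensity = if (cfg$statistic == "mean") mean(value)
                                 else sum(value)),
              by = c("focus", "ring")]
    full <- data.table::CJ(focus = fsub$focus, ring = seq_len(cfg$n_rings))
    agg <- agg[full, on = c("focus", "ring")]
    agg[is.na(n_pixels), n_pixels := 0L]
    agg[, nucleus := n]
    out[[length(out) + 1L]] <- agg[, c("nucleus", "focus", "ring",
                                       "n_pixels", "intensity"),
                                   with = FALSE]
  }
  if (!length(out))
    return(data.table::data.table(nucleus = integer(0), focus = integer(0),
                                  ring = integer(0), n_pixels = integer(0),
                                  intensity = numeric(0)))
  data.table::rbindlist(out)
}

#' Area and eccentricity of a mask
#'
#' Eccentricity is `sqrt(1 - lambda2/lambda1)` from the eigenvalues of the
#' mask's second central moment matrix: 0 for a disk, approaching 1 for
#' elongated objects.
#'
#' @param mask logical (or 0/1) matrix; must contain foreground pixels.
#' @param pixel_size micrometres per pixel.
#' @return list with `area` (um^2), `eccentricity`, `centroid` (x, y px).
#' @export
shape_metrics <- function(mask, pixel_size = 0.1) {
  px <- which(mask != 0)
  if (!length(px)) stop("empty mask")
  h <- nrow(mask)
  x <- ((px - 1L) %/% h) + 1L
  y <- ((px - 1L) %% h) + 1L
  cx <- mean(x); cy <- mean(y)
  mxx <- mean((x - cx)^2); myy <- mean((y - cy)^2)
  mxy <- mean((x - cx) * (y - cy))
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2L), symmetric = TRUE)$values
  ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  list(area = length(px) * pixel_size^2, eccentricity = ecc,
       centroid = c(x = cx, y = cy))
}

#' Distances between mutual-nearest-neighbour focus pairs
#'
#' Pairs foci by mutual nearest neighbour and reports Euclidean
#' centre-to-centre distances in micrometres; foci without a mutual partner
#' are listed separately.
#'
#' @param centers matrix or data.frame with columns `x`, `y` (pixels).
#' @param pixel_size micrometres per pixel.
#' @return list with `pairs` (data.table: i, j, distance) and `unpaired`
#'   (integer indices). Fewer than 2 foci give an empty result.
#' @export
paired_focus_distance <- function(centers, pixel_size = 0.1) {
  centers <- as.data.frame(centers)
  n <- nrow(centers)
  if (n < 2L)
    return(list(pairs = data.table::data.table(i = integer(0),
                                               j = integer(0),
                                               distance = numeric(0)),
                unpaired = seq_len(n)))
  d <- as.matrix(stats::dist(centers[, c("x", "y")]))
  diag(d) <- Inf
  nn <- apply(d, 1L, which.min)
  is_pair <- nn[nn] == seq_len(n) & seq_len(n) < nn
  pairs <- data.table::data.table(i = which(is_pair), j = nn[is_pair])
  pairs[, distance := d[cbind(i, j)] * pixel_size]
  unpaired <- setdiff(seq_len(n), c(pairs$i, pairs$j))
  list(pairs = pairs, unpaired = unpaired)
}

#' Per-nucleus intensity, normalised to a reference cohort median
#'
#' @param channel numeric matrix.
#' @param nuclei integer label matrix.
#' @param reference numeric vector of reference-cohort per-nucleus values
#'   (same statistic); defaults to the measured cohort itself, whose
#'   normalised median is then 1 by construction.
#' @param stat `"mean"` or `"total"` per-nucleus statistic to normalise.
#' @return data.table with `nucleus`, `total`, `mean`, `normalized`.
#' @export
nuclear_intensity <- function(channel, nuclei, reference = NULL,
                              stat = c("mean", "total")) {
  stat <- match.arg(stat)
  ids <- sort(setdiff(unique(as.integer(nuclei)), 0L))
  dt <- data.table::rbindlist(lapply(ids, function(n) {
    v <- channel[nuclei == n]
    data.table::data.table(nucleus = n, total = sum(v), mean = mean(v))
  }))
  if (!nrow(dt)) stop("no nuclei in label matrix")
  vals <- if (stat == "mean") dt$mean else dt$total
  ref <- if (is.null(reference)) vals else reference
  if (!length(ref)) stop("empty reference cohort")
  dt[, normalized := vals / stats::median(ref)]
  dt
}
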