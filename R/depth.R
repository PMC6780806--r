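# Multiple depth from defocus (MDFD). A defocused cell's blur diameter
# D_n grows linearly as the imaging plane moves away from the focal
# plane, so with the focused diameter D and two blur diameters measured a
# known step d apart, the depth follows from the similar-triangles
# relation d_n = (D_n - D) / (D_n1 - D_n) * d. Because blur is symmetric
# about the focal plane, a third image and the trend of the contrast
# statistic c disambiguate which side the cell is on.

#' ROI preprocessing: grayscale transform and Gaussian filtering
#'
#' The grayscale transform reads the fluorescence channel of the target
#' (taking the maximum over channels would inflate and distort the
#' background, since the maximum of independently noisy channels is
#' biased upward).
#'
#' @param roi_image RGB array or grayscale matrix.
#' @param sigma Smoothing spread, px.
#' @param channel Fluorescence channel to read from an RGB input.
#' @return Smoothed grayscale matrix.
#' @export
preprocess_roi <- function(roi_image, sigma = 1, channel = "red") {
  g <- if (is.matrix(roi_image)) roi_image
       else image_channel(roi_image, channel)
  if (sigma > 0) g <- .smooth2(g, gaussian_psf(sigma))
  g
}

#' Grayscale k-means segmentation of an ROI
#'
#' Clusters pixels by grey value into `k` groups — with the default
#' `k = 3` these represent background, cell blur edge and cell body.
#' Initial centers are spread over the quantiles of the distinct grey
#' values, making the clustering deterministic.
#'
#' @param gray Grayscale matrix.
#' @param k Number of clusters (>= 2); reduced (and flagged) when the
#'   image has fewer distinct values.
#' @param seed Unused (kept for interface stability); clustering is
#'   deterministic by construction.
#' @return Integer label matrix, 0 .. k-1 ordered by ascending cluster
#'   mean, with attributes `k_effective`, `reduced` and `centers`.
#' @export
kmeans_segment <- function(gray, k = 3, seed = 1L) {
  stopifnot(k >= 2)
  v <- as.vector(gray)
  uq <- sort(unique(v))
  k_eff <- min(k, length(uq))
  reduced <- k_eff < k
  if (k_eff == 1) {
    out <- matrix(0L, nrow(gray), ncol(gray))
    attr(out, "k_effective") <- 1L; attr(out, "reduced") <- TRUE
    attr(out, "centers") <- uq
    return(out)
  }
  init <- stats::quantile(uq, (seq_len(k_eff) - 0.5) / k_eff,
                          type = 1, names = FALSE)
  init <- unique(init)
  k_eff <- length(init)
  km <- tryCatch(
    stats::kmeans(v, centers = matrix(init, ncol = 1),
                  iter.max = 100, algorithm = "Lloyd"),
    error = function(e)
      stats::kmeans(v, centers = matrix(init, ncol = 1), iter.max = 100,
                    algorithm = "MacQueen"))
  ord <- order(km$centers[, 1])
  relab <- integer(k_eff); relab[ord] <- seq_len(k_eff) - 1L
  out <- matrix(relab[km$cluster], nrow(gray), ncol(gray))
  attr(out, "k_effective") <- k_eff
  attr(out, "reduced") <- reduced || k_eff < k
  attr(out, "centers") <- sort(km$centers[, 1])
  out
}

# scan-line fill of the convex hull of a set of (row, col) points
.fill_hull <- function(idx, H, W) {
  out <- matrix(0L, H, W)
  if (nrow(idx) < 3) { out[idx] <- 1L; return(out) }
  ch <- grDevices::chull(idx[, 2], idx[, 1])     # (x, y) order
  hx <- idx[ch, 2]; hy <- idx[ch, 1]
  n <- length(hx)
  for (r in seq(min(hy), max(hy))) {
    xs <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- hy[i]; y2 <- hy[j]
      if ((y1 <= r && y2 >= r) || (y2 <= r && y1 >= r)) {
        if (y1 == y2) xs <- c(xs, hx[i], hx[j])
        else xs <- c(xs, hx[i] + (r - y1) / (y2 - y1) * (hx[j] - hx[i]))
      }
    }
    if (length(xs) >= 2) {
      out[r, max(1, ceiling(min(xs))):min(W, floor(max(xs)))] <- 1L
    } else if (length(xs) == 1) out[r, round(xs)] <- 1L
  }
  out
}

#' Extract the cell region from k-means labels
#'
#' Merges the blur-edge and body clusters into a binary mask, removes
#' small spurious components, keeps the largest, and returns the convex
#' hull of its contour (the minimum-area convex encirclement).
#'
#' @param labels Label matrix from [kmeans_segment()].
#' @param min_area Components smaller than this (px) are discarded.
#' @return Binary convex mask. Errors when no foreground survives.
#' @export
extract_cell_region <- function(labels, min_area = 9) {
  mask <- (labels >= 1) * 1L
  if (!any(mask > 0)) stop("no cell found in ROI")
  lab <- .uneb(EBImage::bwlabel(.eb(mask)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes == max(sizes))[1]
  if (sizes[keep] < min_area) stop("no cell found in ROI")
  idx <- which(lab == keep, arr.ind = TRUE)
  .fill_hull(idx, nrow(mask), ncol(mask))
}

#' Pixel grayscale distribution curve (PGDC)
#'
#' Extracts the grey profile along the horizontal line through the cell
#' center; the curve's range gives the contrast statistic and curves from
#' different planes intersect at the focused boundary.
#'
#' @param gray Grayscale matrix.
#' @param center Numeric `(x, y)`, 0-based px; must lie inside the image.
#' @param rows Odd number of adjacent rows averaged into the profile
#'   (1 = the bare center row; a small average suppresses read noise
#'   while changing the disc chord negligibly).
#' @return List `profile`, `center_x`, `row_y` of class `pgdc`.
#' @export
extract_pgdc <- function(gray, center, rows = 1L) {
  cx <- center[1]; cy <- center[2]
  if (cx < 0 || cy < 0 || cx > ncol(gray) - 1 || cy > nrow(gray) - 1)
    stop("center outside image")
  row_y <- as.integer(round(cy))
  half <- (as.integer(rows) - 1L) %/% 2L
  r0 <- max(0L, row_y - half); r1 <- min(nrow(gray) - 1L, row_y + half)
  prof <- colMeans(gray[(r0:r1) + 1L, , drop = FALSE])
  structure(list(profile = as.numeric(prof), center_x = cx, row_y = row_y),
            class = "pgdc")
}

#' Image contrast from a PGDC
#'
#' The sharpness statistic: the difference between the maximum and the
#' minimum of the profile. Larger `c` means a clearer (better focused)
#' image.
#'
#' @param pgdc A [extract_pgdc()] result (or bare numeric profile).
#' @return Non-negative scalar.
#' @export
contrast <- function(pgdc) {
  p <- if (inherits(pgdc, "pgdc")) pgdc$profile else as.numeric(pgdc)
  if (length(p) == 0) stop("empty profile")
  max(p) - min(p)
}

#' Blur measurement of a segmented cell
#'
#' The center comes from the first-order moments of the mask; the blur
#' diameter D_n is the mask width along the horizontal line through the
#' center, refined to sub-pixel precision by locating where the grey
#' profile through the center crosses a fixed isophote a small offset
#' above the background (a level in the energy-spreading tail, where the
#' refined width grows linearly with defocus).
#'
#' @param mask Binary cell mask (e.g. from [extract_cell_region()]).
#' @param gray The grayscale ROI the mask was derived from.
#' @param level_offset Height of the width-measurement isophote above the
#'   background, grey levels.
#' @param background Background grey level; estimated from outside the
#'   mask when `NULL`.
#' @return List `D_n` (px), `center` (x, y), `contrast_c`, `level`,
#'   `D_mask` (integer mask-row width).
#' @export
measure_blur <- function(mask, gray, level_offset = 10,
                         background = NULL) {
  if (!any(mask > 0)) stop("no cell found in ROI")
  idx <- which(mask > 0, arr.ind = TRUE)
  cy <- mean(idx[, 1]) - 1; cx <- mean(idx[, 2]) - 1
  ry <- as.integer(round(cy)) + 1L
  row_mask <- mask[ry, ] > 0
  cols <- which(row_mask)
  if (!length(cols)) stop("no cell found in ROI")
  j0 <- min(cols); j1 <- max(cols)
  D_int <- j1 - j0 + 1
  if (is.null(background))
    background <- if (any(mask == 0)) stats::median(gray[mask == 0])
                  else min(gray)
  prof <- as.numeric(extract_pgdc(gray, c(cx, cy), rows = 5L)$profile)
  level <- background + level_offset
  jc <- as.integer(round(cx)) + 1L
  left <- .cross_level(prof, level, jc, -1L)
  right <- .cross_level(prof, level, jc, +1L)
  D_n <- if (is.na(left) || is.na(right)) D_int else right - left
  # local profile slope at the crossings: the width's precision scale
  grad <- NA_real_
  if (!is.na(left) && !is.na(right)) {
    gl <- .local_slope(prof, left); gr <- .local_slope(prof, right)
    grad <- mean(c(abs(gl), abs(gr)), na.rm = TRUE)
  }
  pg <- extract_pgdc(gray, c(cx, cy))
  list(D_n = D_n, center = c(x = cx, y = cy),
       contrast_c = contrast(pg), level = level, D_mask = D_int,
       edge_grad = grad)
}

# central-difference profile slope around a fractional 0-based position
.local_slope <- function(prof, x0) {
  i <- as.integer(round(x0)) + 1L
  lo <- max(2L, i - 2L); hi <- min(length(prof) - 1L, i + 2L)
  if (hi <= lo) return(NA_real_)
  mean(abs(prof[(lo + 1L):(hi + 1L)] - prof[(lo - 1L):(hi - 1L)])) / 2
}

# sub-pixel crossing of `level` walking outward from inside column j
# (1-based); dir = -1 left, +1 right; returns 0-based x or NA. The
# outward tail is monotone in truth, so it is replaced by its isotonic
# (monotone-decreasing) regression before the crossing is interpolated;
# a first-raw-crossing rule would be biased inward under correlated
# noise.
.cross_level <- function(prof, level, j, dir) {
  n <- length(prof)
  idx <- if (dir > 0) j:n else j:1
  seg <- prof[idx]
  if (length(seg) < 2 || seg[1] < level) return(NA_real_)
  fit <- -stats::isoreg(seq_along(seg), -seg)$yf   # monotone decreasing
  below <- which(fit < level)
  if (!length(below)) return(NA_real_)
  k <- below[1]
  if (k == 1) return(NA_real_)
  f <- (fit[k - 1] - level) / (fit[k - 1] - fit[k])
  f <- min(max(f, 0), 1)
  (j - 1) + dir * ((k - 2) + f)
}

#' Trend-based sharpness judgement over a defocus series
#'
#' Classifies the contrast series of three (or more) planes: a contrast
#' above `focus_threshold` declares the focused plane; an interior
#' maximum flags the symmetric case (the focal plane was crossed between
#' the bracketing planes) and such data is screened out of the plain
#' two-plane depth formula; otherwise a rising trend means the planes are
#' moving toward focus and a falling trend away from it.
#'
#' @param c_series Numeric contrast values in capture order (length >= 3).
#' @param focus_threshold Optional absolute contrast above which a plane
#'   counts as focused.
#' @return List `focused_at` (index or `NA`), `direction`
#'   (`"toward"`/`"away"`), `screened` (logical), `bracket` (indices
#'   bracketing the crossing when screened).
#' @export
sharpness_judgement <- function(c_series, focus_threshold = NULL) {
  if (length(c_series) < 3) stop("need at least 3 contrast values")
  n <- length(c_series)
  focused_at <- NA_integer_
  if (!is.null(focus_threshold) && max(c_series) >= focus_threshold)
    focused_at <- which.max(c_series)
  imax <- which.max(c_series)
  screened <- imax > 1 && imax < n
  bracket <- if (screened) c(imax - 1L, imax + 1L) else NULL
  direction <- if (c_series[n] >= c_series[1]) "toward" else "away"
  list(focused_at = focused_at, direction = direction,
       screened = screened, bracket = bracket)
}

#' Focused diameter from intersecting grey profiles
#'
#' Energy conservation makes the grey profiles of one cell taken at
#' different planes intersect at two fixed points — the cell's focused
#' boundary. The distance between the outermost pair of intersections,
#' located by sign change of the profile difference with linear
#' interpolation, is the focused diameter D. With more than two profiles
#' the estimate is averaged over all pairs.
#'
#' @param pgdcs List of two or more [extract_pgdc()] objects of the same
#'   cell (profiles aligned on the cell center).
#' @param min_gap Crossings require the profile difference to reach this
#'   amplitude on both sides (noise guard), grey levels.
#' @return Focused diameter in px.
#' @export
focused_diameter <- function(pgdcs, min_gap = 1.5) {
  stopifnot(length(pgdcs) >= 2)
  prof <- lapply(pgdcs, function(p)
    if (inherits(p, "pgdc")) p$profile else as.numeric(p))
  ctr <- vapply(seq_along(pgdcs), function(i) {
    p <- pgdcs[[i]]
    if (inherits(p, "pgdc")) p$center_x else which.max(prof[[i]]) - 1
  }, 0)
  n <- length(prof)
  est <- numeric(0)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    # orient as sharper minus blurrier: positive inside the focused
    # boundary, negative just outside
    if (diff(range(prof[[a]])) >= diff(range(prof[[b]]))) {
      d <- prof[[a]] - prof[[b]]
    } else {
      d <- prof[[b]] - prof[[a]]
    }
    cx <- mean(ctr[c(a, b)])
    right <- .edge_crossing(d, cx, +1L, min_gap)
    left <- .edge_crossing(d, cx, -1L, min_gap)
    if (!is.na(right) && !is.na(left) && right > left)
      est <- c(est, right - left)
  }
  if (!length(est))
    stop("profiles yield fewer than 2 intersections; cannot estimate D")
  mean(est)
}

# locate the + -> - sign change of d (walking outward from the center in
# direction dir) with the largest swing; returns 0-based x or NA
.edge_crossing <- function(d, cx, dir, min_gap) {
  n <- length(d)
  k <- 5L
  sm <- stats::filter(d, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  sm[is.na(sm)] <- 0
  j0 <- as.integer(round(cx)) + 1L
  best <- NA_real_; best_swing <- -Inf
  i <- j0
  while (i + dir >= 1 && i + dir <= n) {
    if (sm[i] > 0 && sm[i + dir] <= 0) {
      inner <- if (dir > 0) sm[j0:i] else sm[i:j0]
      outer_lo <- if (dir > 0) (i + 1):min(n, i + 30) else max(1, i - 30):(i - 1)
      swing <- max(inner) - min(sm[outer_lo])
      if (swing > best_swing && swing >= min_gap) {
        # sub-pixel crossing interpolated on the smoothed difference
        f <- if (sm[i] > sm[i + dir]) sm[i] / (sm[i] - sm[i + dir]) else 0.5
        f <- min(max(f, 0), 1)
        best <- (i - 1) + dir * f
        best_swing <- swing
      }
    }
    i <- i + dir
  }
  best
}

#' Depth from defocus (two-plane relation)
#'
#' \eqn{d_n = \frac{D_n - D}{D_{n+1} - D_n} d}: with the focused diameter
#' D and the blur diameters of two planes a step d apart, the distance of
#' the first plane from the focal plane follows from similar triangles.
#' The sign of the result carries the travel direction.
#'
#' @param D Focused diameter, px.
#' @param D_n,D_n1 Blur diameters at consecutive planes, px.
#' @param d Step interval, micrometres.
#' @return Depth of plane n relative to the focal plane, micrometres.
#' @export
depth_from_defocus <- function(D, D_n, D_n1, d) {
  if (abs(D_n1 - D_n) < 1e-12)
    stop("degenerate geometry: equal blur diameters")
  if (D_n < D - 1e-9)
    stop("negative blur: measured D_n smaller than focused diameter")
  (D_n - D) / (D_n1 - D_n) * d
}

#' Relative error of a depth estimate
#'
#' \eqn{e = |d_n - d_i| / (|d_n| + D) \times 100\%}; the experimental
#' focused diameter enters the denominator as a correction factor.
#'
#' @param d_n Estimated depth, micrometres.
#' @param d_i True (initial) depth, micrometres.
#' @param D Experimental focused diameter, micrometres.
#' @return Error in percent.
#' @export
relative_error <- function(d_n, d_i, D) {
  den <- abs(d_n) + D
  if (den <= 0) stop("zero denominator in relative error")
  abs(d_n - d_i) / den * 100
}

# measure one plane of an ROI: returns list(D_n, center, c, pgdc) or NULL
.measure_plane <- function(img, optics, smooth_sigma = 1) {
  g <- preprocess_roi(img, smooth_sigma)
  # detectability guard: beyond the valid range the fluorescence is too
  # weak to be recognized
  if (max(g) < optics$background_level + 4 * max(optics$noise_sigma, 0.5))
    return(NULL)
  labs <- kmeans_segment(g, 3)
  mask <- tryCatch(extract_cell_region(labs), error = function(e) NULL)
  if (is.null(mask)) return(NULL)
  mb <- tryCatch(measure_blur(mask, g), error = function(e) NULL)
  if (is.null(mb)) return(NULL)
  mb$pgdc <- extract_pgdc(g, mb$center, rows = 3L)
  mb
}

# cache for the blur-growth calibration
.favf_cache <- new.env(parent = emptyenv())

# instrument calibration of the measurement pipeline: render reference
# cells of several diameters noise-free across the working depth range
# and record, per diameter, the measured width in excess of the focused
# width g(z), the focused-width offset u0 = W(0) - D_true, and the
# reference grey profiles (used to tabulate the geometry-dependent bias
# of the intersection-based focused diameter). The growth curve is
# nearly cell-size independent; the residual dependence is handled by
# interpolating between reference diameters.
.blur_calibration <- function(optics, smooth_sigma = 1) {
  key <- paste(optics$pixel_size, optics$psf_sigma_per_blur,
               optics$blur_slope, optics$background_level,
               smooth_sigma, sep = "|")
  if (!is.null(.favf_cache[[key]])) return(.favf_cache[[key]])
  o2 <- optics
  o2$noise_sigma <- 0
  dias <- c(10, 12, 14)
  zmax <- ceiling(optics$valid_depth_range) + 6
  master <- new.env(parent = emptyenv())
  master$dias <- dias
  master$cals <- lapply(dias, function(dia) {
    prov <- .cell_stack_provider(cell_spec(1, 25, 25, 0, dia, "red"), o2,
                                 roi_um = 50, seed = 1L)
    zs <- seq(0, zmax, by = 1)
    meas <- lapply(zs, function(z) .measure_plane(prov(z), o2, smooth_sigma))
    ok <- !vapply(meas, is.null, TRUE)
    zs <- zs[ok]; meas <- meas[ok]
    W <- vapply(meas, `[[`, 0, "D_n")
    g <- cummax(W - W[1])          # enforce monotone growth
    base <- stats::approxfun(zs, g, rule = 2)
    zend <- max(zs)
    end_slope <- (g[length(g)] - g[length(g) - 4]) /
      (zs[length(zs)] - zs[length(zs) - 4])
    cal <- new.env(parent = emptyenv())
    cal$g <- function(z) {
      z <- abs(z)
      ifelse(z <= zend, base(z), base(zend) + end_slope * (z - zend))
    }
    cal$u0 <- W[1] - dia / optics$pixel_size
    cal$zend <- zend
    cal$zs <- zs
    cal$profiles <- lapply(meas, `[[`, "pgdc")
    cal$D_ref_px <- dia / optics$pixel_size
    cal$bias_memo <- new.env(parent = emptyenv())
    cal
  })
  .favf_cache[[key]] <- master
  master
}

# bias of the intersection-based focused diameter on one reference, at
# an integer grid pair; memoized
.bias_at <- function(cal, za, zb) {
  if (za == zb) {
    if (za >= cal$zend) za <- za - 1L else zb <- za + 1L
  }
  key <- paste(min(za, zb), max(za, zb))
  memo <- cal$bias_memo
  if (!is.null(memo[[key]])) return(memo[[key]])
  ia <- match(min(za, zb), cal$zs); ib <- match(max(za, zb), cal$zs)
  b <- if (is.na(ia) || is.na(ib)) 0 else tryCatch(
    focused_diameter(list(cal$profiles[[ia]], cal$profiles[[ib]])) -
      cal$D_ref_px,
    error = function(e) 0)
  memo[[key]] <- b
  b
}

# bilinear interpolation of the bias surface at fractional defocus pair
.ref_intersection_bias <- function(cal, za, zb) {
  za <- min(max(abs(za), 0), cal$zend); zb <- min(max(abs(zb), 0), cal$zend)
  a0 <- floor(za); b0 <- floor(zb)
  a1 <- min(a0 + 1, cal$zend); b1 <- min(b0 + 1, cal$zend)
  fa <- za - a0; fb <- zb - b0
  (1 - fa) * (1 - fb) * .bias_at(cal, a0, b0) +
    fa * (1 - fb) * .bias_at(cal, a1, b0) +
    (1 - fa) * fb * .bias_at(cal, a0, b1) +
    fa * fb * .bias_at(cal, a1, b1)
}

# calibration interpolated to an estimated cell diameter (um)
.cal_interp <- function(master, dia_um) {
  dias <- master$dias
  dia_um <- min(max(dia_um, dias[1]), dias[length(dias)])
  hi <- which(dias >= dia_um)[1]
  if (hi == 1) return(.cal_single(master$cals[[1]]))
  lo <- hi - 1
  w <- (dia_um - dias[lo]) / (dias[hi] - dias[lo])
  ca <- master$cals[[lo]]; cb <- master$cals[[hi]]
  list(g = function(z) (1 - w) * ca$g(z) + w * cb$g(z),
       u0 = (1 - w) * ca$u0 + w * cb$u0,
       bias = function(za, zb) (1 - w) * .ref_intersection_bias(ca, za, zb) +
         w * .ref_intersection_bias(cb, za, zb))
}

.cal_single <- function(cal) {
  list(g = cal$g, u0 = cal$u0,
       bias = function(za, zb) .ref_intersection_bias(cal, za, zb))
}

# fit the three measured widths to W_i = W0 + g(|t_i - zeta|), where
# zeta is the focal-plane position relative to plane 0 (signed). The
# anchor W0 (the cell's focused width at the measurement isophote) is
# tied to the intersection-based focused diameter, corrected by the
# reference bias for the candidate geometry; without that anchor the
# problem is degenerate wherever g is locally linear. Grid search plus
# local refinement; when no intersection estimate is available the
# anchor floats (last resort).
.fit_depth_from_widths <- function(W, t, cal, z_range, D_int = NA,
                                   pair = c(1L, 3L), weights = NULL) {
  anchored <- is.finite(D_int)
  if (is.null(weights) || any(!is.finite(weights))) weights <- rep(1, length(W))
  weights <- weights / sum(weights)
  gssq <- function(zeta) {
    gi <- cal$g(t - zeta)
    if (anchored) {
      b <- cal$bias(t[pair[1]] - zeta, t[pair[2]] - zeta)
      w0 <- (D_int - b) + cal$u0
    } else {
      w0 <- sum(weights * (W - gi))
    }
    sum(weights * (W - w0 - gi)^2)
  }
  zg <- seq(-z_range, max(t) + z_range, by = 0.25)
  ss <- vapply(zg, gssq, 0)
  z0 <- zg[which.min(ss)]
  opt <- stats::optimize(gssq, c(z0 - 0.4, z0 + 0.4))
  zeta <- opt$minimum
  gi <- cal$g(t - zeta)
  w0 <- if (anchored) {
    (D_int - cal$bias(t[pair[1]] - zeta, t[pair[2]] - zeta)) + cal$u0
  } else sum(weights * (W - gi))
  list(zeta = zeta, W0 = w0, ss = opt$objective, anchored = anchored)
}

# one MDFD pass: three planes at current, current+d, current+2d. The
# three measured blur diameters are matched against the calibrated
# growth curve, which linearizes them; the returned `move` is the plane
# displacement that reaches the focal plane (the depth relation of
# depth_from_defocus() applied to the linearized diameters). The
# contrast trend over the planes flags the symmetric (focal plane
# crossed) case.
.mdfd_pass <- function(stack_provider, z0, d, optics, smooth_sigma = 1) {
  zs <- z0 + c(0, d, 2 * d)
  meas <- lapply(zs, function(z) .measure_plane(stack_provider(z), optics,
                                                smooth_sigma))
  if (any(vapply(meas, is.null, TRUE)))
    return(list(status = "out_of_range", d_n = NA_real_, D_px = NA_real_,
                screened = FALSE, measurements = meas))
  Dn_raw <- vapply(meas, function(m) m$D_n, 0)
  cc <- vapply(meas, function(m) m$contrast_c, 0)
  master <- .blur_calibration(optics, smooth_sigma)
  # focused diameter from the two least-blurred planes (their profiles
  # carry the sharpest, least bias-prone intersections)
  ord <- order(Dn_raw)
  pair <- sort(ord[1:2])
  D_int <- tryCatch(
    focused_diameter(list(meas[[pair[1]]]$pgdc, meas[[pair[2]]]$pgdc)),
    error = function(e) NA_real_)
  grads <- vapply(meas, function(m)
    if (is.finite(m$edge_grad)) m$edge_grad else 1, 0)
  t_planes <- c(0, d, 2 * d)
  zr <- optics$valid_depth_range + 6
  # first round with the mid reference, second with the calibration
  # interpolated to the estimated cell diameter
  cal <- .cal_interp(master, 12)
  fit <- .fit_depth_from_widths(Dn_raw, t_planes, cal, z_range = zr,
                                D_int = D_int, pair = pair,
                                weights = grads^2)
  dia_est <- (fit$W0 - cal$u0) * optics$pixel_size
  if (is.finite(dia_est)) {
    cal <- .cal_interp(master, dia_est)
    fit <- .fit_depth_from_widths(Dn_raw, t_planes, cal, z_range = zr,
                                  D_int = D_int, pair = pair,
                                  weights = grads^2)
  }
  zeta <- fit$zeta                  # focal plane relative to plane 0
  sj <- sharpness_judgement(cc)
  screened <- sj$screened || (zeta * (zeta - 2 * d) < 0)
  # experimental focused diameter: the fit's anchor minus the
  # calibration's focused-width offset (bias-corrected)
  D_px <- max(fit$W0 - cal$u0, 1)
  list(status = "estimated", d_n = abs(zeta), move = zeta, D_px = D_px,
       W0 = fit$W0, Dn_raw = Dn_raw, c_series = cc,
       screened = screened, sharp = sj, measurements = meas)
}

#' Iterative MDFD depth estimation
#'
#' Repeats the three-image cycle — capture planes a step `d` apart, judge
#' sharpness from the contrast trend, screen the symmetric (crossed)
#' case, measure the blur diameters and focused diameter, apply the
#' depth-from-defocus relation — moving the imaging plane by each
#' estimate until the target is focused. Estimates beyond the valid
#' fluorescence range are reported out of range.
#'
#' @param stack_provider Function `z -> image` rendering or capturing the
#'   ROI at imaging-plane position `z` (micrometres).
#' @param d Step interval, micrometres.
#' @param optics An [optics_config()].
#' @param start_z Initial imaging-plane position, micrometres.
#' @param max_iter Maximum number of three-image cycles.
#' @param focus_tol Residual plane motion (micrometres) below which the
#'   target counts as focused.
#' @param smooth_sigma Preprocessing blur, px.
#' @return List of class `depth_estimate`: `d_n` (estimated depth of the
#'   cell relative to `start_z`, µm), `D_px` and `D_um` (focused
#'   diameter), `iterations`, `status` (`"focused"`, `"estimated"`,
#'   `"out_of_range"`), `screened_any`, `trace` (per-iteration moves).
#' @export
mdfd_estimate <- function(stack_provider, d = 6, optics = optics_config(),
                          start_z = 0, max_iter = 4, focus_tol = 0.6,
                          smooth_sigma = 1) {
  z <- start_z
  total <- 0
  screened_any <- FALSE
  trace <- numeric(0)
  D_px <- NA_real_
  status <- "estimated"
  for (it in seq_len(max_iter)) {
    pass <- .mdfd_pass(stack_provider, z, d, optics, smooth_sigma)
    if (pass$status == "out_of_range") {
      status <- "out_of_range"
      if (it == 1) return(structure(list(d_n = NA_real_, D_px = NA_real_,
        D_um = NA_real_, iterations = it, status = status,
        screened_any = screened_any, trace = trace),
        class = "depth_estimate"))
      break
    }
    D_px <- pass$D_px
    screened_any <- screened_any || pass$screened
    move <- pass$move
    trace <- c(trace, move)
    if (abs(total + move) > optics$valid_depth_range) {
      status <- "out_of_range"
      total <- total + move
      break
    }
    z <- z + move
    total <- total + move
    if (abs(move) < focus_tol) { status <- "focused"; break }
  }
  structure(list(d_n = total, D_px = D_px,
                 D_um = D_px * optics$pixel_size,
                 iterations = length(trace), status = status,
                 screened_any = screened_any, trace = trace),
            class = "depth_estimate")
}

#' Single-pass MDFD estimate
#'
#' One three-image cycle without plane motion, as used in the error
#' sweeps: returns the signed depth of the imaging plane relative to the
#' cell's focal plane.
#'
#' @inheritParams mdfd_estimate
#' @return List `d_n` (magnitude of the plane-to-focus distance, µm),
#'   `move` (signed), `D_px`, `D_um`, `screened`, `status`.
#' @export
mdfd_single_pass <- function(stack_provider, d = 6, optics = optics_config(),
                             start_z = 0, smooth_sigma = 1) {
  pass <- .mdfd_pass(stack_provider, start_z, d, optics, smooth_sigma)
  if (pass$status == "out_of_range")
    return(list(d_n = NA_real_, move = NA_real_, D_px = NA_real_,
                D_um = NA_real_, screened = FALSE, status = "out_of_range"))
  d_n <- abs(pass$move)
  status <- if (d_n > optics$valid_depth_range) "out_of_range" else "estimated"
  list(d_n = d_n, move = pass$move, D_px = pass$D_px,
       D_um = pass$D_px * optics$pixel_size, screened = pass$screened,
       status = status)
}

# build a stack provider rendering a single-cell ROI at any plane
.cell_stack_provider <- function(cell, optics, roi_um = NULL, seed = 1L) {
  if (is.null(roi_um)) {
    max_blur <- cell$focused_diameter +
      optics$blur_slope * optics$pixel_size * optics$valid_depth_range * 1.2
    roi_um <- 2.4 * max_blur
  }
  sc <- scene(list(cell), fov_width = roi_um, fov_height = roi_um,
              rng_seed = seed)
  function(z) render_scene(sc, z, optics)
}

#' Error sweep of single-pass MDFD over initial depths and step intervals
#'
#' For every combination of initial depth and step interval, simulates
#' `n_cells` cells at that depth, runs one MDFD pass and averages the
#' relative error; estimates beyond the valid range are recorded as out
#' of range (OOR).
#'
#' @param optics An [optics_config()].
#' @param d_i_list Initial depths, micrometres.
#' @param d_list Step intervals, micrometres.
#' @param n_cells Cells per combination.
#' @param seed Base RNG seed.
#' @return List `table` (matrix of mean errors, rows d_i, columns d; `NA`
#'   where all runs were OOR) and `long` (data frame d_i, d, cell, e,
#'   status).
#' @export
run_error_sweep <- function(optics, d_i_list = c(4, 6, 8),
                            d_list = c(2, 4, 6, 8, 10, 12),
                            n_cells = 10, seed = 1L) {
  stopifnot(length(d_i_list) > 0, length(d_list) > 0)
  long <- NULL
  tab <- matrix(NA_real_, length(d_i_list), length(d_list),
                dimnames = list(paste0(d_i_list, "um"), paste0(d_list, "um")))
  for (i in seq_along(d_i_list)) for (j in seq_along(d_list)) {
    d_i <- d_i_list[i]; d <- d_list[j]
    errs <- numeric(0)
    for (cix in seq_len(n_cells)) {
      cseed <- seed + 7919L * cix + 101L * i + j
      dia <- .with_seed(cseed, pmax(9, stats::rnorm(1, 12, 0.8)))
      prov <- .cell_stack_provider(
        cell_spec(1, 25, 25, 0, dia, "red"), optics, roi_um = 50,
        seed = cseed)
      sp <- mdfd_single_pass(prov, d = d, optics = optics, start_z = d_i)
      st <- sp$status
      e <- if (st == "out_of_range") NA_real_
           else relative_error(sp$d_n, d_i, sp$D_um)
      long <- rbind(long, data.frame(d_i = d_i, d = d, cell = cix, e = e,
                                     status = st))
      if (!is.na(e)) errs <- c(errs, e)
    }
    if (length(errs)) tab[i, j] <- mean(errs)
  }
  list(table = tab, long = long)
}

#' Blur-linearity evaluation protocol
#'
#' Renders a set of synthetic cells, images each across several
#' unequally spaced planes, measures the blur diameter per plane with
#' the full measurement chain (k-means segmentation, convex-hull region,
#' moment center, sub-pixel width) and fits a first-order polynomial of
#' diameter versus depth per cell. Planes avoid the immediate focus
#' neighbourhood, where the measured width departs from the linear law.
#'
#' @param optics An [optics_config()].
#' @param n_cells Number of cells.
#' @param planes Image-plane depths, micrometres.
#' @param seed Base RNG seed.
#' @return List `per_cell` (data frame: cell, slope, intercept,
#'   r_squared) and `mean_r_squared`.
#' @export
evaluate_blur_linearity <- function(optics, n_cells = 10,
                                    planes = c(8, 12, 18, 24, 31, 38),
                                    seed = 1L) {
  res <- lapply(seq_len(n_cells), function(cix) {
    cseed <- seed + 977L * cix
    dia <- .with_seed(cseed, max(9, stats::rnorm(1, 12, 0.8)))
    prov <- .cell_stack_provider(cell_spec(1, 25, 25, 0, dia, "red"),
                                 optics, roi_um = 50, seed = cseed)
    W <- vapply(planes, function(z) {
      m <- .measure_plane(prov(z), optics)
      if (is.null(m)) NA_real_ else m$D_n
    }, 0)
    ok <- is.finite(W)
    fit <- fit_blur_linearity(planes[ok], W[ok])
    data.frame(cell = cix, slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared)
  })
  per_cell <- do.call(rbind, res)
  list(per_cell = per_cell, mean_r_squared = mean(per_cell$r_squared))
}

#' Iterative-depth accuracy protocol
#'
#' Simulates cells at initial depths across the convergent range, runs
#' the full iterative MDFD loop at one step interval, and reports the
#' relative error of each converged estimate.
#'
#' @param optics An [optics_config()].
#' @param n_cells Number of cells.
#' @param d Step interval, micrometres.
#' @param d_i_range Range initial depths are spread over, micrometres.
#' @param seed Base RNG seed.
#' @return List `per_cell` (data frame: cell, d_i, d_n, e, status,
#'   iterations) and `mean_error`.
#' @export
evaluate_depth_convergence <- function(optics, n_cells = 10, d = 6,
                                       d_i_range = c(4, 20), seed = 1L) {
  d_is <- seq(d_i_range[1], d_i_range[2], length.out = n_cells)
  res <- lapply(seq_len(n_cells), function(cix) {
    cseed <- seed + 1181L * cix
    dia <- .with_seed(cseed, max(9, stats::rnorm(1, 12, 0.8)))
    prov <- .cell_stack_provider(cell_spec(1, 25, 25, 0, dia, "red"),
                                 optics, roi_um = 50, seed = cseed)
    est <- mdfd_estimate(prov, d = d, optics = optics, start_z = d_is[cix])
    e <- if (is.na(est$d_n)) NA_real_
         else relative_error(abs(est$d_n), d_is[cix], est$D_um)
    data.frame(cell = cix, d_i = d_is[cix], d_n = est$d_n, e = e,
               status = est$status, iterations = est$iterations)
  })
  per_cell <- do.call(rbind, res)
  list(per_cell = per_cell, mean_error = mean(per_cell$e, na.rm = TRUE))
}

#' Linear fit of blur diameter versus depth
#'
#' Ordinary least squares first-order polynomial, as used to verify that
#' measured blur diameters follow the linear defocus law.
#'
#' @param depths Imaging-plane depths, micrometres.
#' @param D_n Measured blur diameters, px.
#' @return List `slope`, `intercept`, `r_squared`.
#' @export
fit_blur_linearity <- function(depths, D_n) {
  stopifnot(length(depths) == length(D_n))
  if (length(depths) < 3) stop("need at least 3 points")
  if (diff(range(depths)) < 1e-12) stop("degenerate: all depths equal")
  fit <- stats::lm(D_n ~ depths)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}
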