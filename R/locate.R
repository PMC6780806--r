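# Scalable correlation coefficient (SCC) matching. The score at (x, y) is
# the sum over the template of T'(x', y') * I'(x + x', y + y'), where T'
# and I' are the template and the image window with their means removed,
# divided by the product of their L2 norms so that scores live in [-1, 1]
# and one acceptance threshold transfers across template scales.

#' Create a matching template
#'
#' @param patch Grayscale matrix (values in grey-level units).
#' @param scale_index Position in the scale pyramid (0 = focused original).
#' @param blur_sigma Additional Gaussian blur this variant carries, px.
#' @return An object of class `favf_template`.
#' @export
template <- function(patch, scale_index = 0L, blur_sigma = 0) {
  patch <- as.matrix(patch)
  if (nrow(patch) < 3 || ncol(patch) < 3)
    stop("template must be at least 3 x 3")
  structure(list(patch = patch, w = ncol(patch), h = nrow(patch),
                 scale_index = as.integer(scale_index),
                 blur_sigma = blur_sigma),
            class = "favf_template")
}

# windowed box sums of a matrix via integral images
.box_sums <- function(m, h, w) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  H <- nrow(m); W <- ncol(m)
  Z <- matrix(0, H + 1, W + 1)
  Z[2:(H + 1), 2:(W + 1)] <- cs
  r <- seq_len(H - h + 1); c <- seq_len(W - w + 1)
  Z[r + h, c + w, drop = FALSE] - Z[r + h, c, drop = FALSE] -
    Z[r, c + w, drop = FALSE] + Z[r, c, drop = FALSE]
}

# raw cross-correlation of image with zero-mean template (valid region)
.cross_valid <- function(img, tp) {
  h <- nrow(tp); w <- ncol(tp)
  Hr <- nrow(img) - h + 1L; Wr <- ncol(img) - w + 1L
  if (as.double(Hr) * Wr * h * w <= 2^21) {
    acc <- matrix(0, Hr, Wr)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (tp[i, j] == 0) next
      acc <- acc + tp[i, j] * img[(i:(i + Hr - 1L)), (j:(j + Wr - 1L))]
    }
    acc
  } else {
    n1 <- stats::nextn(nrow(img), c(2, 3, 5))
    n2 <- stats::nextn(ncol(img), c(2, 3, 5))
    pi2 <- matrix(0, n1, n2); pi2[seq_len(nrow(img)), seq_len(ncol(img))] <- img
    pk <- matrix(0, n1, n2)
    pk[seq_len(h), seq_len(w)] <- tp
    out <- Re(stats::fft(stats::fft(pi2) * Conj(stats::fft(pk)),
                         inverse = TRUE)) / (n1 * n2)
    out[seq_len(Hr), seq_len(Wr), drop = FALSE]
  }
}

#' Normalized correlation coefficient map
#'
#' Slides the mean-subtracted template over the image and returns, for each
#' placement, the normalized correlation coefficient between template and
#' window. Higher scores mean better matches. Windows (or templates) with
#' zero variance score 0.
#'
#' @param image Grayscale matrix.
#' @param tmpl A [template()] (or plain matrix).
#' @return Matrix `R` of size `(H - h + 1) x (W - w + 1)`; `R[y + 1, x + 1]`
#'   is the score of placing the template's top-left corner at the 0-based
#'   pixel `(x, y)`.
#' @export
correlation_map <- function(image, tmpl) {
  if (inherits(tmpl, "favf_template")) tmpl <- tmpl$patch
  image <- unclass(image); attr(image, "pixel_size") <- NULL
  attr(image, "z_plane") <- NULL
  h <- nrow(tmpl); w <- ncol(tmpl)
  if (h > nrow(image) || w > ncol(image))
    stop("template larger than image")
  tp <- tmpl - mean(tmpl)
  tnorm <- sqrt(sum(tp^2))
  Hr <- nrow(image) - h + 1L; Wr <- ncol(image) - w + 1L
  if (tnorm < 1e-12) return(matrix(0, Hr, Wr))
  cross <- .cross_valid(image, tp)
  s1 <- .box_sums(image, h, w)
  s2 <- .box_sums(image^2, h, w)
  wvar <- pmax(s2 - s1^2 / (h * w), 0)
  wnorm <- sqrt(wvar)
  R <- cross / (tnorm * wnorm)
  R[wnorm < 1e-9] <- 0
  pmin(pmax(R, -1), 1)
}

# bilinear resize of a matrix to (nh, nw)
.resize_bilinear <- function(m, nh, nw) {
  H <- nrow(m); W <- ncol(m)
  ry <- (seq_len(nh) - 0.5) * H / nh - 0.5
  rx <- (seq_len(nw) - 0.5) * W / nw - 0.5
  y0 <- pmin(pmax(floor(ry), 0), H - 1); x0 <- pmin(pmax(floor(rx), 0), W - 1)
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c2 <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
  wfx <- matrix(fx, nh, nw, byrow = TRUE); wfy <- matrix(fy, nh, nw)
  a * (1 - wfx) * (1 - wfy) + b * wfx * (1 - wfy) +
    c2 * (1 - wfx) * wfy + d * wfx * wfy
}

# convolve with 'same' output size (zero padding)
.conv2_same <- function(m, k) {
  half <- (nrow(k) - 1L) %/% 2L
  full <- .conv2_full(m, k)
  full[half + seq_len(nrow(m)), half + seq_len(ncol(m)), drop = FALSE]
}

# smoothing with border renormalization: the kernel mass falling outside
# the image is divided out, so constant inputs stay constant
.smooth2 <- function(m, k) {
  num <- .conv2_same(m, k)
  den <- .conv2_same(matrix(1, nrow(m), ncol(m)), k)
  num / den
}

#' Build the scalable template pyramid
#'
#' The focused original is enlarged to a series of templates with
#' additional Gaussian blur, emulating how a cell looks at increasing
#' defocus; rough locating then matches each scale and keeps the best.
#'
#' @param original A [template()] holding the focused cell appearance.
#' @param n_scales Number of enlarged/blurred variants (>= 1).
#' @param size_step Multiplicative size growth per scale.
#' @param sigma_step Additional blur per scale, px.
#' @return A `template_set`: list with the `original` and `variants`
#'   (sizes strictly increasing).
#' @export
build_scalable_templates <- function(original, n_scales = 5,
                                     size_step = 1.13, sigma_step = 3.0) {
  stopifnot(inherits(original, "favf_template"), n_scales >= 1,
            size_step > 1, sigma_step > 0)
  variants <- vector("list", n_scales)
  for (k in seq_len(n_scales)) {
    f <- size_step^k
    nh <- round(original$h * f); nw <- round(original$w * f)
    p <- .resize_bilinear(original$patch, nh, nw)
    p <- .conv2_same(p, gaussian_psf(k * sigma_step))
    variants[[k]] <- template(p, scale_index = k, blur_sigma = k * sigma_step)
  }
  structure(list(original = original, variants = variants),
            class = "template_set")
}

# local maxima of a score map above a threshold; returns df of 0-based
# top-left positions and scores
.local_peaks <- function(R, threshold) {
  H <- nrow(R); W <- ncol(R)
  if (H == 0 || W == 0) return(NULL)
  P <- matrix(-Inf, H + 2, W + 2); P[2:(H + 1), 2:(W + 1)] <- R
  nb <- function(dy, dx) P[(2:(H + 1)) + dy, (2:(W + 1)) + dx]
  is_max <- R >= threshold &
    R >= nb(-1, -1) & R >= nb(-1, 0) & R >= nb(-1, 1) &
    R >= nb(0, -1) & R >= nb(0, 1) &
    R >= nb(1, -1) & R >= nb(1, 0) & R >= nb(1, 1)
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  data.frame(y = idx[, 1] - 1L, x = idx[, 2] - 1L,
             score = R[idx])
}

# greedy cross-scale non-maximum suppression; deterministic ordering:
# by score desc, ties broken by smallest x then y
.nms <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(df)
  ord <- order(-df$score, df$center_x, df$center_y)
  df <- df[ord, , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    if (any(keep)) {
      kept <- df[keep, , drop = FALSE]
      # duplicate detections of one cell sit at nearly the same center:
      # neighbouring scales suppress within half the smaller template
      # width, distant scales only within a quarter, so a large-scale
      # match on a merged cluster does not swallow its member cells
      rad <- ifelse(abs(kept$scale_index - df$scale_index[i]) <= 1,
                    pmin(kept$w, df$w[i]) / 2,
                    pmin(kept$w, df$w[i]) / 4)
      dd <- sqrt((kept$center_x - df$center_x[i])^2 +
                   (kept$center_y - df$center_y[i])^2)
      ok <- all(dd >= rad)
    }
    keep[i] <- ok
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

.empty_detections <- function() {
  data.frame(id = integer(), stage = character(), center_x = numeric(),
             center_y = numeric(), x = numeric(), y = numeric(),
             w = numeric(), h = numeric(), score = numeric(),
             scale_index = integer())
}

#' Rough planar locating with the scalable template pyramid
#'
#' Every template scale is matched against the image; local correlation
#' maxima above `accept_threshold` become candidate detections, and
#' cross-scale non-maximum suppression keeps one detection per cell at its
#' best-matching ("optimal") scale. Each detection also yields a region of
#' interest for depth detection, enlarged so the blur stays inside it
#' during the defocus sweep.
#'
#' @param image Grayscale matrix (typically the red channel).
#' @param templates A `template_set` from [build_scalable_templates()].
#' @param accept_threshold Minimum correlation score.
#' @param roi_margin ROI enlargement factor relative to the detection box.
#' @return List with `detections` (data frame: id, stage, center_x,
#'   center_y, x, y, w, h, score, scale_index; 0-based pixel coordinates)
#'   and `rois` (data frame: x, y, w, h, source_detection).
#' @export
rough_locate <- function(image, templates, accept_threshold = 0.6,
                         roi_margin = 1.5) {
  stopifnot(inherits(templates, "template_set"))
  image <- image_channel(image, "red")
  all_t <- c(list(templates$original), templates$variants)
  cand <- NULL
  for (tm in all_t) {
    if (tm$h > nrow(image) || tm$w > ncol(image)) next
    R <- correlation_map(image, tm)
    pk <- .local_peaks(R, accept_threshold)
    if (is.null(pk)) next
    pk$center_x <- pk$x + (tm$w - 1) / 2
    pk$center_y <- pk$y + (tm$h - 1) / 2
    pk$w <- tm$w; pk$h <- tm$h; pk$scale_index <- tm$scale_index
    cand <- rbind(cand, pk)
  }
  det <- .nms(cand)
  if (is.null(det) || nrow(det) == 0)
    return(list(detections = .empty_detections(),
                rois = data.frame(x = numeric(), y = numeric(),
                                  w = numeric(), h = numeric(),
                                  source_detection = integer())))
  det$id <- seq_len(nrow(det))
  det$stage <- "rough"
  det <- det[, c("id", "stage", "center_x", "center_y", "x", "y", "w", "h",
                 "score", "scale_index")]
  rw <- round(det$w * roi_margin); rh <- round(det$h * roi_margin)
  rx <- pmax(0, round(det$center_x - rw / 2))
  ry <- pmax(0, round(det$center_y - rh / 2))
  rw <- pmin(rw, ncol(image) - rx); rh <- pmin(rh, nrow(image) - ry)
  rois <- data.frame(x = rx, y = ry, w = rw, h = rh,
                     source_detection = det$id)
  list(detections = det, rois = rois)
}

# parabolic sub-pixel refinement of a peak along one axis
.subpix <- function(lo, ce, hi) {
  den <- lo - 2 * ce + hi
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (lo - hi) / den))
}

#' Precise planar locating of focused cells
#'
#' Matches the focused original template (the view after autofocus) at a
#' few pure size variants — cells vary in diameter, and a symmetric
#' template of the wrong size peaks on an edge-alignment ring rather
#' than at the center — keeps the optimal size per location, and
#' refines each correlation peak to sub-pixel accuracy with a parabolic
#' fit.
#'
#' @inheritParams rough_locate
#' @param original A [template()] of the focused cell.
#' @param size_factors Relative template sizes tried (no added blur).
#' @return Detections data frame with `stage = "precise"`.
#' @export
precise_locate <- function(image, original, accept_threshold = 0.6,
                           size_factors = c(0.85, 1, 1.15, 1.3)) {
  stopifnot(inherits(original, "favf_template"))
  image <- image_channel(image, "red")
  cand <- NULL
  maps <- list()
  for (k in seq_along(size_factors)) {
    f <- size_factors[k]
    p <- if (f == 1) original$patch else
      .resize_bilinear(original$patch, round(original$h * f),
                       round(original$w * f))
    tm <- template(p)
    if (tm$h > nrow(image) || tm$w > ncol(image)) next
    R <- correlation_map(image, tm)
    maps[[k]] <- R
    pk <- .local_peaks(R, accept_threshold)
    if (is.null(pk)) next
    pk$center_x <- pk$x + (tm$w - 1) / 2
    pk$center_y <- pk$y + (tm$h - 1) / 2
    pk$w <- tm$w; pk$h <- tm$h
    pk$scale_index <- 0L
    pk$size_k <- k
    cand <- rbind(cand, pk)
  }
  if (is.null(cand) || nrow(cand) == 0) return(.empty_detections())
  det <- .nms(cand)
  # sub-pixel refinement on the winning correlation surface
  for (i in seq_len(nrow(det))) {
    R <- maps[[det$size_k[i]]]
    yy <- det$y[i] + 1L; xx <- det$x[i] + 1L
    if (yy > 1 && yy < nrow(R)) {
      dy <- .subpix(R[yy - 1, xx], R[yy, xx], R[yy + 1, xx])
      det$center_y[i] <- det$center_y[i] + dy
    }
    if (xx > 1 && xx < ncol(R)) {
      dx <- .subpix(R[yy, xx - 1], R[yy, xx], R[yy, xx + 1])
      det$center_x[i] <- det$center_x[i] + dx
    }
  }
  det$id <- seq_len(nrow(det))
  det$stage <- "precise"
  det[, c("id", "stage", "center_x", "center_y", "x", "y", "w", "h",
          "score", "scale_index")]
}

#' Evaluate the correct-detection rate across depth groups
#'
#' Reproduces the planar-locating evaluation protocol: targets are
#' simulated at several defocus depths; a target counts as correctly
#' detected only when exactly one detection is returned (no split or
#' merge) and its center lies within `tol_px` of the ground truth.
#' Depth group 0 uses precise locating; defocused groups use rough
#' locating with the scalable pyramid.
#'
#' @param optics An [optics_config()].
#' @param depth_groups Vector of defocus depths, micrometres.
#' @param targets_per_group Targets simulated per group.
#' @param seed RNG seed for scene generation.
#' @param tol_px Center tolerance in pixels.
#' @param accept_threshold Correlation acceptance threshold.
#' @return List with `per_group` (data frame: depth, rate) and `average`.
#' @export
evaluate_detection_rate <- function(optics, depth_groups = seq(0, 40, 5),
                                    targets_per_group = 20, seed = 1L,
                                    tol_px = 5, accept_threshold = 0.6) {
  stopifnot(targets_per_group >= 1)
  tset <- build_scalable_templates(reference_template(optics))
  fov <- 256 * optics$pixel_size   # 256 px field regardless of sampling
  rates <- numeric(length(depth_groups))
  for (g in seq_along(depth_groups)) {
    depth <- depth_groups[g]
    ok <- 0L
    for (t in seq_len(targets_per_group)) {
      sseed <- seed + 1000L * g + t
      truth <- .with_seed(sseed, {
        list(x = stats::runif(1, 0.3 * fov, 0.7 * fov),
             y = stats::runif(1, 0.3 * fov, 0.7 * fov),
             d = pmax(8, stats::rnorm(1, 12, 0.8)))
      })
      sc <- scene(list(cell_spec(1, truth$x, truth$y, depth, truth$d, "red")),
                  fov_width = fov, fov_height = fov, rng_seed = sseed)
      img <- render_scene(sc, 0, optics)
      gray <- image_channel(img, "red")
      det <- if (depth == 0)
        precise_locate(gray, tset$original, accept_threshold)
      else
        rough_locate(gray, tset, accept_threshold)$detections
      if (nrow(det) == 1) {
        err <- sqrt((det$center_x - truth$x / optics$pixel_size)^2 +
                      (det$center_y - truth$y / optics$pixel_size)^2)
        if (err <= tol_px) ok <- ok + 1L
      }
    }
    rates[g] <- ok / targets_per_group
  }
  list(per_group = data.frame(depth = depth_groups, rate = rates),
       average = mean(rates))
}

#' Reference focused-cell template
#'
#' Renders a canonical in-focus cell with the given optics (noise-free)
#' and crops a tight patch around it, for use as the original template of
#' the scale pyramid.
#'
#' @param optics An [optics_config()].
#' @param diameter Cell focused diameter, micrometres.
#' @param peak Peak grey level.
#' @return A [template()].
#' @export
reference_template <- function(optics, diameter = 12, peak = 200) {
  ps <- optics$pixel_size
  pad <- 3
  half_px <- ceiling((diameter / ps) / 2) + pad
  fov <- (2 * half_px + 9) * ps
  sc <- scene(list(cell_spec(1, fov / 2, fov / 2, 0, diameter, "red", peak)),
              fov_width = fov, fov_height = fov, rng_seed = 1L)
  img <- render_scene(sc, 0, optics, noise = FALSE)
  gray <- image_channel(img, "red")
  cy <- round(fov / 2 / ps); cx <- cy
  rows <- (cy - half_px):(cy + half_px) + 1L
  template(gray[rows, rows], scale_index = 0L)
}
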