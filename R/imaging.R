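# Virtual fluorescence microscope: cells are uniform fluorescent discs; a
# defocused view is the focused image convolved with a Gaussian PSF whose
# spread grows linearly with defocus, so total brightness energy is
# conserved while the apparent blur diameter D_n grows linearly.

#' Discrete 2D Gaussian point spread function
#'
#' Samples the isotropic Gaussian
#' \eqn{h(x, y) = \frac{1}{2\pi\sigma^2} e^{-(x^2+y^2)/2\sigma^2}}
#' on an odd square support and renormalizes so the kernel sums to one
#' (energy conservation under convolution).
#'
#' @param sigma Spread in pixels; `sigma = 0` yields the identity (delta)
#'   kernel.
#' @param support_radius Half-width of the kernel in pixels; defaults to
#'   `max(1, ceiling(4 * sigma))`.
#' @return A `(2 * support_radius + 1)` square matrix summing to 1.
#' @export
gaussian_psf <- function(sigma, support_radius = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number")
  if (sigma == 0) return(matrix(1, 1, 1))
  if (is.null(support_radius)) support_radius <- max(1, ceiling(4 * sigma))
  stopifnot(support_radius >= 1)
  ax <- (-support_radius):support_radius
  g1 <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Ground-truth blur diameter under the linear defocus law
#'
#' The apparent (blur) diameter of a cell grows linearly with its distance
#' from the focal plane:
#' \eqn{D_n = D + s \cdot p \cdot |z - z_f|}, where \eqn{D} is the focused
#' diameter, \eqn{s} the blur slope (px/µm) and \eqn{p} the pixel size.
#' This is the analytic oracle that depth estimation is tested against.
#'
#' @param cell A [cell_spec()].
#' @param optics An [optics_config()].
#' @param focal_z Focal-plane position, micrometres.
#' @return Blur diameter in micrometres.
#' @export
model_blur_diameter <- function(cell, optics, focal_z = 0) {
  stopifnot(inherits(cell, "cell_spec"), inherits(optics, "optics_config"))
  cell$focused_diameter +
    optics$blur_slope * optics$pixel_size * abs(cell$z - focal_z)
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# full 2D convolution via FFT; exact up to ~1e-12
.conv2_full <- function(a, k) {
  na <- dim(a); nk <- dim(k)
  n1 <- na[1] + nk[1] - 1L; n2 <- na[2] + nk[2] - 1L
  p1 <- stats::nextn(n1, c(2, 3, 5)); p2 <- stats::nextn(n2, c(2, 3, 5))
  pa <- matrix(0, p1, p2); pa[seq_len(na[1]), seq_len(na[2])] <- a
  pk <- matrix(0, p1, p2); pk[seq_len(nk[1]), seq_len(nk[2])] <- k
  out <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    (p1 * p2)
  pmax(out[seq_len(n1), seq_len(n2), drop = FALSE], 0)
}

# focused appearance of a stained cell on an n x n grid: a uniformly
# dyed body with a sharp boundary (anti-aliased) plus a brighter,
# Gaussian-shaped central region (perinuclear dye accumulation). The
# sharp boundary pins the intersections of defocused grey profiles at
# the focused edge; the central peak makes image contrast decay
# immediately with defocus. Center (cy, cx) in 0-based px; peak value 1.
.cell_patch <- function(n, cy, cx, r, body = 0.72, core_frac = 0.45) {
  ax <- 0:(n - 1)
  dy <- matrix(ax - cy, n, n)
  dx <- matrix(ax - cx, n, n, byrow = TRUE)
  dist <- sqrt(dx^2 + dy^2)
  cover <- pmin(pmax(r + 0.5 - dist, 0), 1)
  core <- exp(-dist^2 / (2 * (core_frac * r)^2))
  cover * (body + (1 - body) * core)
}

# add patch into canvas with top-left (0-based) offset, clipping at borders
.add_patch <- function(canvas, patch, top, left) {
  H <- nrow(canvas); W <- ncol(canvas)
  ph <- nrow(patch); pw <- ncol(patch)
  r0 <- max(0L, top); r1 <- min(H - 1L, top + ph - 1L)
  c0 <- max(0L, left); c1 <- min(W - 1L, left + pw - 1L)
  if (r0 > r1 || c0 > c1) return(canvas)
  canvas[(r0:r1) + 1L, (c0:c1) + 1L] <-
    canvas[(r0:r1) + 1L, (c0:c1) + 1L] +
    patch[(r0:r1) - top + 1L, (c0:c1) - left + 1L]
  canvas
}

# PSF sigma (px) for a given defocus (um)
.defocus_sigma_px <- function(dz_um, optics) {
  blur_px <- optics$blur_slope * abs(dz_um)   # D_n - D in px
  optics$psf_sigma_per_blur * blur_px / 2
}

# render one cell into a channel canvas (grey-level float units)
.render_cell <- function(canvas, cell, focal_z, optics, ox_um = 0, oy_um = 0) {
  ps <- optics$pixel_size
  dz <- cell$z - focal_z
  r_px <- (cell$focused_diameter / ps) / 2
  sig <- .defocus_sigma_px(dz, optics)
  half <- ceiling(r_px + 1)
  n <- 2L * half + 1L
  cx_px <- (cell$x - ox_um) / ps
  cy_px <- (cell$y - oy_um) / ps
  fx <- cx_px - floor(cx_px); fy <- cy_px - floor(cy_px)
  patch <- cell$peak_intensity * .cell_patch(n, half + fy, half + fx, r_px)
  if (sig > 0) {
    k <- gaussian_psf(sig)
    patch <- .conv2_full(patch, k)
    half <- half + (nrow(k) - 1L) %/% 2L
  }
  if (abs(dz) > optics$valid_depth_range) {
    # beyond the fluorescence detectability range: render below the noise
    # floor so the cell cannot be recognized
    floor_peak <- if (optics$noise_sigma > 0) optics$noise_sigma else 0
    mx <- max(patch)
    patch <- if (mx > 0) patch * (floor_peak / mx) else patch
  }
  .add_patch(canvas, patch, as.integer(floor(cy_px) - half),
             as.integer(floor(cx_px) - half))
}

# render the pipette into a channel canvas (whole-window rasterization)
.render_pipette <- function(canvas, pip, focal_z, optics,
                            ox_um = 0, oy_um = 0) {
  ps <- optics$pixel_size
  H <- nrow(canvas); W <- ncol(canvas)
  tx <- (pip$tip_x - ox_um) / ps
  ty <- (pip$tip_y - oy_um) / ps
  th <- pip$shaft_angle * pi / 180
  ux <- cos(th); uy <- sin(th)
  w2 <- (pip$width / ps) / 2
  ax <- 0:(W - 1); ay <- 0:(H - 1)
  px <- matrix(ax, H, W, byrow = TRUE); py <- matrix(ay, H, W)
  relx <- px - tx; rely <- py - ty
  proj <- relx * ux + rely * uy
  projc <- pmax(proj, 0)
  dist <- sqrt((relx - projc * ux)^2 + (rely - projc * uy)^2)
  cov <- pmin(pmax(w2 + 0.5 - dist, 0), 1)
  shaft <- pip$peak_intensity * cov
  # dye accumulates at the tip: bright blob that anchors the tracker
  blob <- 0.45 * pip$peak_intensity *
    exp(-((px - tx)^2 + (py - ty)^2) / (2 * (w2 / 1.2)^2))
  img <- shaft + blob
  sig <- .defocus_sigma_px(pip$tip_z - focal_z, optics)
  if (sig > 0) {
    k <- gaussian_psf(sig)
    img <- .conv2_full(img, k)
    half <- (nrow(k) - 1L) %/% 2L
    img <- img[half + seq_len(H), half + seq_len(W)]
  }
  canvas + img
}

#' Render a scene as seen by the virtual microscope
#'
#' Each cell is drawn as a sharp-edged stained body with a brighter
#' central region, convolved with [gaussian_psf()], whose spread follows
#' the linear blur law of [model_blur_diameter()].
#' The unit-sum kernel conserves each cell's integrated brightness across
#' focal positions (before noise and clipping). Cells further than
#' `valid_depth_range` from the focal plane are attenuated below the noise
#' floor. Rendering is bit-deterministic for a fixed scene seed.
#'
#' @param sc A [scene()].
#' @param focal_z Focal-plane position, micrometres.
#' @param optics An [optics_config()].
#' @param origin Render-window origin `(x, y)` in micrometres (for
#'   field-of-view scanning of a larger scene).
#' @param size_um Render-window size `(width, height)` in micrometres;
#'   defaults to the scene's field of view.
#' @param noise If `FALSE`, additive noise is suppressed (pixels are still
#'   quantized to integer grey levels).
#' @return A `favf_image`: an `H x W x 3` integer-valued array (channels
#'   red, green, blue) with attributes `pixel_size` and `z_plane`.
#' @export
render_scene <- function(sc, focal_z, optics, origin = c(0, 0),
                         size_um = NULL, noise = TRUE) {
  stopifnot(inherits(sc, "favf_scene"), inherits(optics, "optics_config"))
  if (is.null(size_um)) size_um <- c(sc$fov_width, sc$fov_height)
  ps <- optics$pixel_size
  W <- as.integer(round(size_um[1] / ps))
  H <- as.integer(round(size_um[2] / ps))
  chan <- list(red = matrix(0, H, W), green = matrix(0, H, W))
  for (cl in sc$cells)
    chan[[cl$color]] <- .render_cell(chan[[cl$color]], cl, focal_z, optics,
                                     origin[1], origin[2])
  if (!is.null(sc$pipette))
    chan$red <- .render_pipette(chan$red, sc$pipette, focal_z, optics,
                                origin[1], origin[2])
  out <- array(0, dim = c(H, W, 3))
  out[, , 1] <- chan$red + optics$background_level
  out[, , 2] <- chan$green + optics$background_level
  out[, , 3] <- optics$background_level
  if (noise && optics$noise_sigma > 0) {
    seed <- (sc$rng_seed * 131L +
               round(focal_z * 997) + round(sum(origin) * 31)) %% 2147483647
    out <- out + .with_seed(seed,
      array(stats::rnorm(length(out), sd = optics$noise_sigma), dim = dim(out)))
  }
  out <- round(pmin(pmax(out, 0), optics$max_gray))
  structure(out, pixel_size = ps, z_plane = focal_z, class = "favf_image")
}

#' Extract one channel (or a grayscale view) of a rendered image
#'
#' @param img A `favf_image` (or plain array/matrix).
#' @param channel `"red"`, `"green"`, `"blue"`, or `"max"` for the
#'   channel-wise maximum (the standard grayscale transform for
#'   fluorescence, where signal lives in a single channel).
#' @return A matrix with the image's `pixel_size`/`z_plane` attributes.
#' @export
image_channel <- function(img, channel = c("red", "green", "blue", "max")) {
  channel <- match.arg(channel)
  if (is.matrix(img)) return(img)
  m <- switch(channel,
              red = img[, , 1], green = img[, , 2], blue = img[, , 3],
              max = pmax(img[, , 1], img[, , 2], img[, , 3]))
  attributes(m) <- c(attributes(m)[c("dim")],
                     list(pixel_size = attr(img, "pixel_size"),
                          z_plane = attr(img, "z_plane")))
  m
}

#' Render an ordered defocus stack
#'
#' Images are captured along the optical axis at a fixed step interval,
#' emulating successive displacement of the imaging plane.
#'
#' @param sc A [scene()].
#' @param start_z First focal position, micrometres.
#' @param step Step interval `d` in micrometres (may be negative; nonzero).
#' @param count Number of planes (>= 2).
#' @param optics An [optics_config()].
#' @param ... Passed to [render_scene()] (e.g. `origin`, `size_um`, `noise`).
#' @return A `defocus_stack`: list with `images`, `z_offsets` and
#'   `step_interval`.
#' @export
render_defocus_stack <- function(sc, start_z, step, count, optics, ...) {
  if (!is.numeric(count) || count < 2) stop("'count' must be >= 2")
  if (step == 0) stop("'step' must be nonzero")
  z <- start_z + (seq_len(count) - 1) * step
  imgs <- lapply(z, function(zz) render_scene(sc, zz, optics, ...))
  structure(list(images = imgs, z_offsets = z, step_interval = step),
            class = "defocus_stack")
}

#' Generate a touching cluster of target cells
#'
#' Builds a scene with `k` red cells in mutual contact: each new cell is
#' chained to a previously placed one at a center separation between
#' `sep_range[1]` and `sep_range[2]` of the sum of the two radii, while
#' respecting excluded volume against all other cells (cells are solid,
#' so centers cannot approach closer than `sep_range[1]` of the radius
#' sum). This is the overlapping-cell fixture for the watershed
#' separation path.
#'
#' @param k Number of cells in the cluster.
#' @param seed RNG seed.
#' @param fov_um Scene side, micrometres.
#' @param sep_range Center separation as a fraction of the radius sum.
#' @param z_jitter Axial spread of the cluster, micrometres.
#' @param diameter_mean,diameter_sd Cell diameter distribution, µm.
#' @return A [scene()].
#' @export
make_cluster_scene <- function(k, seed = 1L, fov_um = 64,
                               sep_range = c(0.75, 0.95), z_jitter = 1,
                               diameter_mean = 12, diameter_sd = 0.8) {
  stopifnot(k >= 1)
  .with_seed(seed, {
    rd <- function() max(9, stats::rnorm(1, diameter_mean, diameter_sd))
    cells <- list(cell_spec(1, fov_um / 2, fov_um / 2,
                            stats::runif(1, -z_jitter, z_jitter), rd(),
                            "red"))
    for (i in seq_len(k - 1) + 1) {
      d2 <- rd()
      placed <- FALSE
      for (try in 1:400) {
        base <- cells[[sample(length(cells), 1)]]
        ang <- stats::runif(1, 0, 2 * pi)
        sep <- stats::runif(1, sep_range[1], sep_range[2]) *
          (base$focused_diameter + d2) / 2
        x <- base$x + sep * cos(ang); y <- base$y + sep * sin(ang)
        margin <- diameter_mean
        if (x < margin || x > fov_um - margin ||
            y < margin || y > fov_um - margin) next
        ok <- all(vapply(cells, function(cl)
          sqrt((cl$x - x)^2 + (cl$y - y)^2) >=
            sep_range[1] * (cl$focused_diameter + d2) / 2, TRUE))
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place cluster cell ", i)
      cells[[i]] <- cell_spec(i, x, y, stats::runif(1, -z_jitter, z_jitter),
                              d2, "red")
    }
    scene(cells, fov_width = fov_um, fov_height = fov_um, rng_seed = seed)
  })
}

#' Generate a two-color rare-cell mixture scene
#'
#' Emulates the study's suspension: red-stained target cells mixed with a
#' `ratio`-fold excess of green-stained background cells, uniformly spread
#' through the field of view and a thin axial layer. A chosen fraction of
#' targets is placed in overlapping contact with a neighbour, which is what
#' triggers the watershed separation path downstream.
#'
#' @param n_target Number of red target cells.
#' @param ratio Background-to-target count ratio (the study mixes 1:100).
#' @param fov_width,fov_height Field size, micrometres.
#' @param overlap_fraction Fraction of targets placed so their footprint
#'   intersects another cell's.
#' @param seed RNG seed; scenes are reproducible bit-for-bit.
#' @param z_range Axial interval (micrometres) cells are drawn from.
#' @param diameter_mean,diameter_sd Cell focused-diameter distribution, µm.
#' @return A [scene()] whose first `n_target` cells are the red targets.
#' @export
make_mixture_scene <- function(n_target, ratio = 100, fov_width = 400,
                               fov_height = 400, overlap_fraction = 0,
                               seed = 1L, z_range = c(-20, 20),
                               diameter_mean = 12, diameter_sd = 0.8) {
  stopifnot(n_target >= 0, ratio > 0, overlap_fraction >= 0,
            overlap_fraction <= 1)
  n_green <- round(n_target * ratio)
  mean_area <- pi * (diameter_mean / 2)^2
  if ((n_target + n_green) * mean_area > 0.35 * fov_width * fov_height)
    stop("infeasible density: cells cannot fit in the field of view")
  .with_seed(seed, {
    rd <- function(n) pmax(6, stats::rnorm(n, diameter_mean, diameter_sd))
    margin <- diameter_mean
    rx <- function(n) stats::runif(n, margin, fov_width - margin)
    ry <- function(n) stats::runif(n, margin, fov_height - margin)
    rz <- function(n) stats::runif(n, z_range[1], z_range[2])
    cells <- list(); idn <- 0L
    add <- function(x, y, z, d, color) {
      idn <<- idn + 1L
      cells[[idn]] <<- cell_spec(idn, x, y, z, d, color,
                                 peak_intensity = min(250, max(120,
                                   stats::rnorm(1, 200, 10))))
    }
    # excluded volume: solid cells cannot interpenetrate in the plane
    clear_of_all <- function(x, y, d) {
      all(vapply(cells, function(cl)
        sqrt((cl$x - x)^2 + (cl$y - y)^2) >=
          0.8 * (cl$focused_diameter + d) / 2, TRUE))
    }
    n_over <- round(overlap_fraction * n_target)
    n_pairs <- n_over %/% 2L
    odd <- n_over %% 2L == 1L
    # overlapping target pairs
    for (i in seq_len(n_pairs)) {
      d1 <- rd(1); d2 <- rd(1)
      x1 <- rx(1); y1 <- ry(1); z1 <- rz(1)
      ang <- stats::runif(1, 0, 2 * pi)
      sep <- stats::runif(1, 0.7, 0.95) * (d1 + d2) / 2
      add(x1, y1, z1, d1, "red")
      add(x1 + sep * cos(ang), y1 + sep * sin(ang), z1 + stats::runif(1, -1, 1),
          d2, "red")
    }
    # remaining targets, isolated from other targets
    n_rest <- n_target - 2L * n_pairs
    pending_green <- NULL
    for (i in seq_len(n_rest)) {
      d1 <- rd(1)
      for (try in 1:200) {
        x1 <- rx(1); y1 <- ry(1)
        ok <- all(vapply(cells, function(cl)
          sqrt((cl$x - x1)^2 + (cl$y - y1)^2) >
            0.75 * (cl$focused_diameter + d1), TRUE))
        if (ok) break
      }
      z1 <- rz(1)
      add(x1, y1, z1, d1, "red")
      if (odd && i == 1L) {
        # odd overlap count: pair this target with an adjacent green cell
        d2 <- rd(1); ang <- stats::runif(1, 0, 2 * pi)
        sep <- stats::runif(1, 0.7, 0.95) * (d1 + d2) / 2
        pending_green <- list(x = x1 + sep * cos(ang), y = y1 + sep * sin(ang),
                              z = z1 + stats::runif(1, -1, 1), d = d2)
      }
    }
    if (!is.null(pending_green))
      add(pending_green$x, pending_green$y, pending_green$z, pending_green$d,
          "green")
    n_green_left <- n_green - if (odd) 1L else 0L
    for (i in seq_len(max(0L, n_green_left))) {
      d1 <- rd(1)
      for (try in 1:60) {
        x1 <- rx(1); y1 <- ry(1)
        if (clear_of_all(x1, y1, d1)) break
      }
      add(x1, y1, rz(1), d1, "green")
    }
    scene(cells, fov_width = fov_width, fov_height = fov_height,
          rng_seed = seed)
  })
}
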