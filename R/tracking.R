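# Neighborhood-search tracking of the micropipette tip. A template is
# cropped around the focused tip; in each new frame only a neighborhood
# search area (three times the template's area, centered on the last
# position) is matched with the correlation coefficient, and the template
# is refreshed from recent matches so slow appearance drift (fluorescence
# quenching, impurity adsorption) does not break the track.

#' Initialize a pipette-tip track
#'
#' @param image Grayscale matrix (first frame, tip in focus).
#' @param tip_xy Tip position `(x, y)`, 0-based px.
#' @param template_size Side of the square template, px (odd preferred).
#' @param search_area_factor Search-area to template *area* ratio; the
#'   side length scales by its square root.
#' @return A `track_state`.
#' @export
init_track <- function(image, tip_xy, template_size = 41,
                       search_area_factor = 3) {
  image <- image_channel(image, "red")
  half <- (template_size - 1) %/% 2
  cx <- round(tip_xy[1]); cy <- round(tip_xy[2])
  if (cx - half < 0 || cy - half < 0 ||
      cx + half > ncol(image) - 1 || cy + half > nrow(image) - 1)
    stop("tip too close to the image border for this template size")
  patch <- image[(cy - half):(cy + half) + 1L, (cx - half):(cx + half) + 1L]
  tmpl <- template(patch)
  search_side <- 2L * floor(template_size * sqrt(search_area_factor) / 2) + 1L
  structure(list(template = tmpl, original_template = tmpl,
                 last_center = c(x = cx, y = cy),
                 last_bbox = c(x = cx - half, y = cy - half,
                               w = template_size, h = template_size),
                 last_score = 1, frames_tracked = 0L,
                 template_size = as.integer(template_size),
                 search_side = search_side, lost = FALSE),
            class = "track_state")
}

# clip a centered square window to the image; returns 0-based x0, y0 and
# the submatrix
.window_at <- function(image, cx, cy, side) {
  half <- (side - 1L) %/% 2L
  x0 <- max(0L, as.integer(round(cx)) - half)
  y0 <- max(0L, as.integer(round(cy)) - half)
  x1 <- min(ncol(image) - 1L, x0 + side - 1L)
  y1 <- min(nrow(image) - 1L, y0 + side - 1L)
  x0 <- max(0L, x1 - side + 1L); y0 <- max(0L, y1 - side + 1L)
  list(x0 = x0, y0 = y0,
       win = image[(y0:y1) + 1L, (x0:x1) + 1L, drop = FALSE])
}

#' Advance a track by one frame
#'
#' Matches the current template inside the neighborhood search area; the
#' best correlation updates position and bounding box, the search area is
#' re-centered, and the template is refreshed from the new location when
#' the match is strong (score at or above `update_threshold`) at the
#' configured cadence. A best score below `lost_threshold` flags the
#' track as lost and leaves the state's position unchanged.
#'
#' @param image Next frame (grayscale matrix).
#' @param state A `track_state` from [init_track()].
#' @param update_threshold Minimum score for template refresh.
#' @param update_every Refresh cadence, frames.
#' @param lost_threshold Score below which the track is declared lost.
#' @return Updated `track_state` (fields `last_center`, `last_bbox`,
#'   `last_score`, `lost`).
#' @export
track_step <- function(image, state, update_threshold = 0.8,
                       update_every = 5L, lost_threshold = 0.45) {
  stopifnot(inherits(state, "track_state"))
  image <- image_channel(image, "red")
  w <- .window_at(image, state$last_center["x"], state$last_center["y"],
                  state$search_side)
  R <- correlation_map(w$win, state$template)
  best <- which(R == max(R), arr.ind = TRUE)
  best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
  score <- R[best[1], best[2]]
  state$frames_tracked <- state$frames_tracked + 1L
  if (score < lost_threshold) {
    state$lost <- TRUE
    state$last_score <- score
    return(state)
  }
  half <- (state$template_size - 1L) %/% 2L
  cx <- unname(w$x0 + (best[2] - 1L) + half)
  cy <- unname(w$y0 + (best[1] - 1L) + half)
  state$lost <- FALSE
  state$last_score <- score
  state$last_center <- c(x = cx, y = cy)
  state$last_bbox <- c(x = cx - half, y = cy - half,
                       w = state$template_size, h = state$template_size)
  if (score >= update_threshold &&
      state$frames_tracked %% update_every == 0L) {
    # drift correction: re-register against the original template before
    # refreshing, so update errors do not accumulate over long sequences
    pad <- 8L
    wref <- .window_at(image, cx, cy, state$template_size + 2L * pad)
    Rref <- correlation_map(wref$win, state$original_template)
    bref <- which(Rref == max(Rref), arr.ind = TRUE)[1, ]
    if (max(Rref) >= lost_threshold) {
      cx <- unname(wref$x0 + (bref[2] - 1L) + half)
      cy <- unname(wref$y0 + (bref[1] - 1L) + half)
      state$last_center <- c(x = cx, y = cy)
      state$last_bbox <- c(x = cx - half, y = cy - half,
                           w = state$template_size, h = state$template_size)
    }
    if (cx - half >= 0 && cy - half >= 0 &&
        cx + half <= ncol(image) - 1 && cy + half <= nrow(image) - 1) {
      patch <- image[(cy - half):(cy + half) + 1L,
                     (cx - half):(cx + half) + 1L]
      state$template <- template(patch)
    }
  }
  state
}

#' Overlapping rate of two bounding boxes
#'
#' Intersection over union of two axis-aligned boxes `(x, y, w, h)`.
#'
#' @param bbox_a,bbox_b Numeric vectors `(x, y, w, h)`.
#' @return Ratio in `[0, 1]`.
#' @export
overlapping_rate <- function(bbox_a, bbox_b) {
  ix <- min(bbox_a[1] + bbox_a[3], bbox_b[1] + bbox_b[3]) -
    max(bbox_a[1], bbox_b[1])
  iy <- min(bbox_a[2] + bbox_a[4], bbox_b[2] + bbox_b[4]) -
    max(bbox_a[2], bbox_b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  union <- bbox_a[3] * bbox_a[4] + bbox_b[3] * bbox_b[4] - inter
  unname(inter / union)
}

#' Evaluate tracking accuracy over a frame sequence
#'
#' Initializes a track on the first frame at the true tip position, then
#' tracks through the sequence; a frame counts as accurately tracked when
#' the overlap (IoU) between the tracked box and the ground-truth box
#' exceeds `accurate_threshold`.
#'
#' @param frames List of grayscale matrices.
#' @param truth_xy Two-column matrix of true tip positions (x, y), px, one
#'   row per frame.
#' @param template_size Template side, px.
#' @param accurate_threshold Overlap criterion (the protocol uses 0.7).
#' @param ... Passed to [track_step()].
#' @return List `accuracy` (fraction of accurately tracked frames),
#'   `overlap` (per-frame IoU), `track` (data frame of tracked centers).
#' @export
evaluate_tracking <- function(frames, truth_xy, template_size = 41,
                              accurate_threshold = 0.7, ...) {
  stopifnot(length(frames) >= 2, nrow(truth_xy) == length(frames))
  st <- init_track(frames[[1]], truth_xy[1, ], template_size)
  half <- (template_size - 1) %/% 2
  n <- length(frames)
  ov <- numeric(n - 1)
  cx <- numeric(n - 1); cy <- numeric(n - 1)
  for (f in 2:n) {
    st <- track_step(frames[[f]], st, ...)
    tb <- c(truth_xy[f, 1] - half, truth_xy[f, 2] - half,
            template_size, template_size)
    ov[f - 1] <- overlapping_rate(st$last_bbox, tb)
    cx[f - 1] <- st$last_center["x"]; cy[f - 1] <- st$last_center["y"]
  }
  list(accuracy = mean(ov > accurate_threshold), overlap = ov,
       track = data.frame(frame = 2:n, x = cx, y = cy))
}

#' Simulate a moving fluorescent pipette tip
#'
#' Renders a frame sequence of a dyed pipette translating at constant
#' speed with a slowly wandering heading, optional per-frame intensity
#' fade (emulating fluorescence quenching) and additive noise.
#'
#' @param n_frames Number of frames.
#' @param speed_um_per_frame Tip displacement per frame, micrometres
#'   (300 µm/s at 60 fps is 5 µm/frame).
#' @param optics An [optics_config()].
#' @param fov_um Frame extent, micrometres.
#' @param seed RNG seed.
#' @param fade Multiplicative intensity decay per frame (1 = none).
#' @param heading_jitter SD of the per-frame heading change, radians.
#' @return List `frames` (grayscale matrices, red channel) and `truth_xy`
#'   (true tip positions, px).
#' @export
simulate_tip_sequence <- function(n_frames, speed_um_per_frame = 5,
                                  optics = optics_config(), fov_um = 120,
                                  seed = 1L, fade = 0.9995,
                                  heading_jitter = 0.15) {
  ps <- optics$pixel_size
  .with_seed(seed, {
    margin <- 0.25 * fov_um
    x <- stats::runif(1, margin, fov_um - margin)
    y <- stats::runif(1, margin, fov_um - margin)
    th <- stats::runif(1, 0, 2 * pi)
    frames <- vector("list", n_frames)
    truth <- matrix(0, n_frames, 2)
    peak <- 190
    for (f in seq_len(n_frames)) {
      pip <- pipette_spec(x, y, 0, shaft_angle = 200, width = 9.5,
                          peak_intensity = peak)
      sc <- scene(list(), pipette = pip, fov_width = fov_um,
                  fov_height = fov_um, rng_seed = seed + f)
      img <- render_scene(sc, 0, optics)
      frames[[f]] <- image_channel(img, "red")
      truth[f, ] <- c(x / ps, y / ps)
      # advance; bounce off the margins
      th <- th + stats::rnorm(1, 0, heading_jitter)
      nx <- x + speed_um_per_frame * cos(th)
      ny <- y + speed_um_per_frame * sin(th)
      while (nx < margin || nx > fov_um - margin ||
             ny < margin || ny > fov_um - margin) {
        th <- stats::runif(1, 0, 2 * pi)
        nx <- x + speed_um_per_frame * cos(th)
        ny <- y + speed_um_per_frame * sin(th)
      }
      x <- nx; y <- ny
      peak <- peak * fade
    }
    list(frames = frames, truth_xy = truth)
  })
}
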