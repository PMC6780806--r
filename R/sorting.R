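# Closed-loop virtual sorting: the rig holds a scene and a pipette pose;
# every field of view is processed with rough locating, MDFD autofocus,
# precise locating, watershed separation of overlapped targets, and a
# tracked pipette approach; aspirated cells leave the scene. Purity and
# recovery are computed against the ground truth.

#' Create a virtual rig around a scene
#'
#' @param sc A [scene()] (typically from [make_mixture_scene()]).
#' @param optics An [optics_config()].
#' @param fov_um Side of the square field of view, micrometres.
#' @return A `virtual_rig` list.
#' @export
virtual_rig <- function(sc, optics = optics_config(), fov_um = 112) {
  structure(list(scene = sc, optics = optics, fov_um = fov_um,
                 focal_z = 0, fov_origin = c(0, 0),
                 pipette = pipette_spec(fov_um / 2, fov_um / 2, 0),
                 aspirated_ids = integer(), steps = 0L),
            class = "virtual_rig")
}

# cells whose center falls inside the rig's current FOV
.cells_in_fov <- function(rig) {
  o <- rig$fov_origin; s <- rig$fov_um
  keep <- vapply(rig$scene$cells, function(cl)
    cl$x >= o[1] && cl$x < o[1] + s && cl$y >= o[2] && cl$y < o[2] + s,
    TRUE)
  rig$scene$cells[keep]
}

# render the current FOV (cells plus pipette)
.render_fov <- function(rig, focal_z, with_pipette = TRUE) {
  sc <- rig$scene
  sc$pipette <- if (with_pipette) rig$pipette else NULL
  render_scene(sc, focal_z, rig$optics, origin = rig$fov_origin,
               size_um = c(rig$fov_um, rig$fov_um))
}

# remove a cell id from the scene
.remove_cell <- function(rig, id) {
  keep <- vapply(rig$scene$cells, function(cl) cl$id != id, TRUE)
  rig$scene$cells <- rig$scene$cells[keep]
  rig
}

#' Sort all target cells in the current field of view
#'
#' Runs the full visual-feedback loop on one field: rough locating of
#' blurred targets with the scalable templates, MDFD depth estimation per
#' region of interest, refocus to each target's plane, precise locating,
#' watershed separation of overlapping detections, then a tracked
#' pipette approach and aspiration of every red target found. Cells whose
#' depth is out of the valid fluorescence range are skipped.
#'
#' @param rig A `virtual_rig`.
#' @param config List of loop parameters: `accept_threshold`,
#'   `capture_radius_um` (default 9.5, the pipette inner radius),
#'   `max_pipette_step_um`, `mdfd_step_um`, `mis_capture_prob`,
#'   `template_size`.
#' @param templates Optional prebuilt `template_set`.
#' @return List `rig` (updated), `report` (data frame of aspirations:
#'   id, x, y, z_est, color) and `detections`.
#' @export
sort_fov <- function(rig, config = list(), templates = NULL) {
  cfg <- utils::modifyList(list(accept_threshold = 0.6,
                                capture_radius_um = 9.5,
                                max_pipette_step_um = 5,
                                mdfd_step_um = 6,
                                mis_capture_prob = 0,
                                template_size = 41), config)
  optics <- rig$optics
  ps <- optics$pixel_size
  if (is.null(templates))
    templates <- build_scalable_templates(reference_template(optics))
  aspirated <- NULL
  detections <- NULL
  failed_centers <- NULL    # ROI centers whose depth could not be found
  for (round_i in 1:20) {     # safety bound on passes over one FOV
    img <- .render_fov(rig, rig$focal_z, with_pipette = FALSE)
    gray <- image_channel(img, "red")
    rl <- rough_locate(gray, templates, cfg$accept_threshold)
    if (nrow(rl$detections) == 0) break
    # skip detections already found unprocessable (e.g. out of range)
    if (!is.null(failed_centers) && nrow(rl$detections)) {
      keep <- vapply(seq_len(nrow(rl$detections)), function(i)
        all(sqrt((failed_centers$x - rl$detections$center_x[i])^2 +
                   (failed_centers$y - rl$detections$center_y[i])^2) > 8),
        TRUE)
      rl$detections <- rl$detections[keep, , drop = FALSE]
      rl$rois <- rl$rois[keep, , drop = FALSE]
    }
    if (nrow(rl$detections) == 0) break
    detections <- rbind(detections, rl$detections)
    # depth per ROI, then refocus on the first unfinished target group
    roi <- rl$rois[1, ]
    provider <- function(z) {
      im <- .render_fov(rig, z, with_pipette = FALSE)
      im[(roi$y:(roi$y + roi$h - 1)) + 1L,
         (roi$x:(roi$x + roi$w - 1)) + 1L, , drop = FALSE]
    }
    est <- mdfd_estimate(provider, d = cfg$mdfd_step_um, optics = optics,
                         start_z = rig$focal_z)
    if (est$status == "out_of_range" || is.na(est$d_n)) {
      # unrecognizable or out of range: remember and skip this ROI
      failed_centers <- rbind(failed_centers,
                              data.frame(x = rl$detections$center_x[1],
                                         y = rl$detections$center_y[1]))
      next
    }
    focal <- rig$focal_z + est$d_n
    rig$focal_z <- focal
    fimg <- .render_fov(rig, focal, with_pipette = FALSE)
    fgray <- image_channel(fimg, "red")
    det <- precise_locate(fgray, templates$original, cfg$accept_threshold)
    if (nrow(det) == 0) det <- rough_locate(fgray, templates,
                                            cfg$accept_threshold)$detections
    if (nrow(det) == 0) break
    groups <- overlap_judgement(det)
    centers <- NULL
    for (g in groups) {
      if (length(g) >= 2) {
        segc <- segment_overlapped(fimg, det, g)
        centers <- rbind(centers, segc[, c("x", "y")])
      } else {
        centers <- rbind(centers, data.frame(x = det$center_x[g],
                                             y = det$center_y[g]))
      }
    }
    # approach and aspirate each located target
    for (ci in seq_len(nrow(centers))) {
      tx_um <- centers$x[ci] * ps + rig$fov_origin[1]
      ty_um <- centers$y[ci] * ps + rig$fov_origin[2]
      res <- .approach_and_aspirate(rig, tx_um, ty_um, focal, cfg)
      rig <- res$rig
      if (!is.null(res$aspirated))
        aspirated <- rbind(aspirated, res$aspirated)
    }
  }
  list(rig = rig, report = aspirated, detections = detections)
}

# drive the pipette tip to the target with per-frame tracking; aspirate
# the nearest cell within the capture radius
.approach_and_aspirate <- function(rig, tx_um, ty_um, focal, cfg) {
  optics <- rig$optics; ps <- optics$pixel_size
  # ensure the pipette starts inside the FOV
  o <- rig$fov_origin; s <- rig$fov_um
  rig$pipette$tip_x <- min(max(rig$pipette$tip_x, o[1] + 0.2 * s),
                           o[1] + 0.8 * s)
  rig$pipette$tip_y <- min(max(rig$pipette$tip_y, o[2] + 0.2 * s),
                           o[2] + 0.8 * s)
  rig$pipette$tip_z <- focal
  img <- .render_fov(rig, focal)
  tip_px <- c((rig$pipette$tip_x - o[1]) / ps, (rig$pipette$tip_y - o[2]) / ps)
  st <- tryCatch(init_track(image_channel(img, "red"), tip_px,
                            cfg$template_size),
                 error = function(e) NULL)
  # approach the target closely before aspirating: stopping at the edge
  # of the capture radius risks slurping an adjacent non-target cell
  approach_tol <- min(2, 0.25 * cfg$capture_radius_um)
  for (k in 1:200) {
    dx <- tx_um - rig$pipette$tip_x; dy <- ty_um - rig$pipette$tip_y
    dist <- sqrt(dx^2 + dy^2)
    if (dist <= approach_tol) break
    step <- min(cfg$max_pipette_step_um, dist)
    rig$pipette$tip_x <- rig$pipette$tip_x + step * dx / dist
    rig$pipette$tip_y <- rig$pipette$tip_y + step * dy / dist
    rig$steps <- rig$steps + 1L
    img <- .render_fov(rig, focal)
    if (!is.null(st)) {
      st <- track_step(image_channel(img, "red"), st)
      if (st$lost) {
        # re-initialize from the known pose (precise locate fallback)
        tip_px <- c((rig$pipette$tip_x - o[1]) / ps,
                    (rig$pipette$tip_y - o[2]) / ps)
        st <- tryCatch(init_track(image_channel(img, "red"), tip_px,
                                  cfg$template_size),
                       error = function(e) NULL)
      }
    }
  }
  # aspirate the nearest remaining cell within the capture radius
  cand <- rig$scene$cells
  if (!length(cand)) return(list(rig = rig, aspirated = NULL))
  dd <- vapply(cand, function(cl)
    sqrt((cl$x - rig$pipette$tip_x)^2 + (cl$y - rig$pipette$tip_y)^2), 0)
  i <- which.min(dd)
  if (dd[i] > cfg$capture_radius_um)
    return(list(rig = rig, aspirated = NULL))
  cl <- cand[[i]]
  if (cfg$mis_capture_prob > 0 && stats::runif(1) < cfg$mis_capture_prob) {
    # tube-deformation mis-capture: grab a neighbour instead if present
    j <- order(dd)[min(2, length(dd))]
    cl <- cand[[j]]
  }
  rig$aspirated_ids <- c(rig$aspirated_ids, cl$id)
  rig <- .remove_cell(rig, cl$id)
  list(rig = rig,
       aspirated = data.frame(id = cl$id, x = cl$x, y = cl$y, z = cl$z,
                              color = cl$color, fov_x = rig$fov_origin[1],
                              fov_y = rig$fov_origin[2]))
}

#' Serpentine scan of a dish
#'
#' Rasters the field of view over the dish area with 10% overlap between
#' neighbouring fields, sorting each field in turn, and stops once the
#' requested number of cells has been collected or the dish is exhausted.
#'
#' @param rig A `virtual_rig`.
#' @param dish_width_um,dish_height_um Extent of the scanned region,
#'   micrometres (defaults to the scene's field).
#' @param stop_count Stop after this many aspirations.
#' @param config Passed to [sort_fov()].
#' @return A `sort_report`: list with `aspirated` (data frame), `rig`,
#'   `n_fov`, and the metrics of [compute_metrics()].
#' @export
scan_dish <- function(rig, dish_width_um = NULL, dish_height_um = NULL,
                      stop_count = 1L, config = list()) {
  stopifnot(stop_count >= 1)
  if (is.null(dish_width_um)) dish_width_um <- rig$scene$fov_width
  if (is.null(dish_height_um)) dish_height_um <- rig$scene$fov_height
  # 25% overlap between neighbouring fields: a cell near one field's
  # border is comfortably interior (with template margin) in the next
  step <- rig$fov_um * 0.75
  xs <- unique(c(seq(0, max(0, dish_width_um - rig$fov_um), by = step),
                 max(0, dish_width_um - rig$fov_um)))
  ys <- unique(c(seq(0, max(0, dish_height_um - rig$fov_um), by = step),
                 max(0, dish_height_um - rig$fov_um)))
  templates <- build_scalable_templates(reference_template(rig$optics))
  aspirated <- NULL
  n_fov <- 0L
  for (iy in seq_along(ys)) {
    xs_row <- if (iy %% 2 == 1) xs else rev(xs)    # serpentine
    for (x in xs_row) {
      rig$fov_origin <- c(x, ys[iy])
      rig$focal_z <- 0
      n_fov <- n_fov + 1L
      out <- sort_fov(rig, config, templates)
      rig <- out$rig
      aspirated <- rbind(aspirated, out$report)
      if (!is.null(aspirated) && nrow(aspirated) >= stop_count) {
        res <- compute_metrics(aspirated, rig)
        return(structure(c(list(aspirated = aspirated, rig = rig,
                                n_fov = n_fov), res),
                         class = "sort_report"))
      }
    }
  }
  res <- compute_metrics(aspirated, rig)
  structure(c(list(aspirated = aspirated, rig = rig, n_fov = n_fov), res),
            class = "sort_report")
}

#' Purity, recovery and speed metrics of a sorting run
#'
#' Purity is the fraction of aspirated cells that are true (red) targets;
#' recovery is the fraction of true targets originally present that were
#' aspirated. Speed is reported as cells per simulation step, never
#' wall-clock.
#'
#' @param aspirated Data frame of aspirated cells (`id`, `color`).
#' @param rig The rig after sorting (for the step count).
#' @param n_targets_truth Number of true targets originally present; when
#'   `NULL`, recovered from aspirated reds plus reds left in the scene.
#' @return List `purity`, `recovery`, `cells_per_step`, `n_aspirated`.
#' @export
compute_metrics <- function(aspirated, rig, n_targets_truth = NULL) {
  n_asp <- if (is.null(aspirated)) 0L else nrow(aspirated)
  n_red_asp <- if (n_asp) sum(aspirated$color == "red") else 0L
  if (is.null(n_targets_truth)) {
    reds_left <- sum(vapply(rig$scene$cells,
                            function(cl) cl$color == "red", TRUE))
    n_targets_truth <- n_red_asp + reds_left
  }
  purity <- if (n_asp) n_red_asp / n_asp else NA_real_
  recovery <- if (n_targets_truth > 0) n_red_asp / n_targets_truth
              else NA_real_
  list(purity = purity, recovery = recovery,
       cells_per_step = if (rig$steps > 0) n_asp / rig$steps else NA_real_,
       n_aspirated = n_asp)
}
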