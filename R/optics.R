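#' Optical configuration of the virtual fluorescence microscope
#'
#' Bundles the parameters of the defocus imaging model: defocused cells are
#' rendered as focused discs convolved with a Gaussian point spread function
#' whose spread grows linearly with the distance between the cell and the
#' focal plane, conserving total fluorescence energy.
#'
#' @param pixel_size Lateral sampling, micrometres per pixel.
#' @param blur_slope Growth of the blur diameter in pixels per micrometre of
#'   defocus (the slope of the linear blur law).
#' @param psf_sigma_per_blur Dimensionless factor linking the blur-diameter
#'   excess \eqn{D_n - D} (in px) to the Gaussian spread,
#'   \eqn{\sigma = psf\_sigma\_per\_blur \cdot (D_n - D)/2}.
#' @param valid_depth_range Maximum defocus (micrometres) at which a cell is
#'   still detectable; beyond it fluorescence is rendered below the noise
#'   floor and depth estimates are reported out of range.
#' @param noise_sigma Standard deviation of additive Gaussian read noise,
#'   8-bit grey levels.
#' @param background_level Constant background, 8-bit grey levels.
#' @param max_gray Maximum representable grey level.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(pixel_size = 0.25,
                          blur_slope = 1.0,
                          psf_sigma_per_blur = 1.0,
                          valid_depth_range = 40,
                          noise_sigma = 2,
                          background_level = 8,
                          max_gray = 255) {
  stopifnot(pixel_size > 0, blur_slope > 0, valid_depth_range > 0,
            psf_sigma_per_blur > 0, noise_sigma >= 0,
            background_level >= 0, max_gray > 0)
  structure(list(pixel_size = pixel_size,
                 blur_slope = blur_slope,
                 psf_sigma_per_blur = psf_sigma_per_blur,
                 valid_depth_range = valid_depth_range,
                 noise_sigma = noise_sigma,
                 background_level = background_level,
                 max_gray = max_gray),
            class = "optics_config")
}

#' Specification of a single fluorescent cell
#'
#' @param id Integer identifier.
#' @param x,y Planar position in micrometres (x right, y down, origin at the
#'   top-left corner of the field of view).
#' @param z Axial position in micrometres; depth is measured relative to the
#'   current focal plane at render time.
#' @param focused_diameter Actual focused diameter of the cell, micrometres.
#' @param color `"red"` (target) or `"green"` (background population).
#' @param peak_intensity Peak grey level of the focused cell.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(id, x, y, z, focused_diameter = 12,
                      color = c("red", "green"), peak_intensity = 200) {
  color <- match.arg(color)
  stopifnot(focused_diameter > 0, peak_intensity > 0, peak_intensity <= 255)
  structure(list(id = as.integer(id), x = x, y = y, z = z,
                 focused_diameter = focused_diameter,
                 color = color, peak_intensity = peak_intensity),
            class = "cell_spec")
}

#' Specification of the micropipette
#'
#' The tip is dyed with a red membrane probe, so the pipette appears in the
#' red channel; the shaft extends from the tip at `shaft_angle`.
#'
#' @param tip_x,tip_y Tip position, micrometres.
#' @param tip_z Tip axial position, micrometres.
#' @param shaft_angle Direction of the shaft leaving the tip, degrees
#'   (0 = towards +x, measured clockwise with y pointing down).
#' @param width Shaft width, micrometres.
#' @param peak_intensity Peak grey level of the focused shaft.
#' @return An object of class `pipette_spec`.
#' @export
pipette_spec <- function(tip_x, tip_y, tip_z = 0, shaft_angle = 30,
                         width = 9.5, peak_intensity = 190) {
  stopifnot(width > 0)
  structure(list(tip_x = tip_x, tip_y = tip_y, tip_z = tip_z,
                 shaft_angle = shaft_angle, width = width,
                 color = "red", peak_intensity = peak_intensity),
            class = "pipette_spec")
}

#' Assemble a scene for the virtual microscope
#'
#' @param cells List of [cell_spec()] objects.
#' @param pipette Optional [pipette_spec()].
#' @param fov_width,fov_height Extent of the world, micrometres.
#' @param rng_seed Seed controlling the scene's rendering noise.
#' @param margin Fraction of cell diameter allowed to protrude beyond the
#'   field of view before validation fails.
#' @return An object of class `favf_scene`.
#' @export
scene <- function(cells, pipette = NULL, fov_width = 96, fov_height = 96,
                  rng_seed = 1L, margin = 1) {
  stopifnot(is.list(cells))
  for (cl in cells) {
    stopifnot(inherits(cl, "cell_spec"))
    slack <- margin * cl$focused_diameter
    if (cl$x < -slack || cl$x > fov_width + slack ||
        cl$y < -slack || cl$y > fov_height + slack)
      stop("cell ", cl$id, " lies outside the field of view")
  }
  if (!is.null(pipette)) stopifnot(inherits(pipette, "pipette_spec"))
  structure(list(cells = cells, pipette = pipette,
                 fov_width = fov_width, fov_height = fov_height,
                 rng_seed = as.integer(rng_seed)),
            class = "favf_scene")
}

#' Write / read scene ground truth as JSON
#'
#' @param sc A [scene()] object.
#' @param path File path.
#' @return `scene_to_json` returns `path` invisibly; `scene_from_json`
#'   returns the reconstructed scene.
#' @export
scene_to_json <- function(sc, path) {
  stopifnot(inherits(sc, "favf_scene"))
  cells <- lapply(sc$cells, function(cl)
    list(id = cl$id, x = cl$x, y = cl$y, z = cl$z, d = cl$focused_diameter,
         color = cl$color, peak = cl$peak_intensity))
  obj <- list(cells = cells,
              fov = c(sc$fov_width, sc$fov_height),
              seed = sc$rng_seed)
  if (!is.null(sc$pipette)) {
    p <- sc$pipette
    obj$pipette <- list(tip_x = p$tip_x, tip_y = p$tip_y, tip_z = p$tip_z,
                        angle = p$shaft_angle, width = p$width,
                        peak = p$peak_intensity)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scene_to_json
#' @export
scene_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cells <- lapply(obj$cells, function(cl)
    cell_spec(cl$id, cl$x, cl$y, cl$z, cl$d, cl$color, cl$peak))
  pip <- NULL
  if (!is.null(obj$pipette)) {
    p <- obj$pipette
    pip <- pipette_spec(p$tip_x, p$tip_y, p$tip_z, p$angle, p$width, p$peak)
  }
  scene(cells, pip, fov_width = obj$fov[[1]], fov_height = obj$fov[[2]],
        rng_seed = obj$seed)
}

#' Write / read optics configuration as YAML
#' @param optics An [optics_config()].
#' @param path File path.
#' @export
optics_to_yaml <- function(optics, path) {
  stopifnot(inherits(optics, "optics_config"))
  yaml::write_yaml(unclass(optics), path)
  invisible(path)
}

#' @rdname optics_to_yaml
#' @export
optics_from_yaml <- function(path) {
  do.call(optics_config, yaml::read_yaml(path))
}
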