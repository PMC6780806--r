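# Watershed-based separation of overlapped target cells. Overlapping
# detections trigger the chain: keep the red channel, Otsu binarization,
# morphological opening, distance-transform markers (plus a background
# "water hole" in the top-left corner) and marker-controlled watershed.

# helpers to move between row/col matrices and EBImage's x/y images
.eb <- function(m) EBImage::Image(t(m))
.uneb <- function(im) t(EBImage::imageData(im))

#' Group detections whose bounding boxes overlap
#'
#' Boxes with positive intersection area are joined, transitively, into
#' groups; any group of two or more triggers instance segmentation, while
#' singletons bypass it.
#'
#' @param detections Data frame with columns `x`, `y`, `w`, `h`
#'   (0-based top-left corner plus size, as produced by [rough_locate()]).
#' @return List of integer vectors of row indices into `detections`.
#' @export
overlap_judgement <- function(detections) {
  n <- nrow(detections)
  if (is.null(n) || n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ix <- min(detections$x[i] + detections$w[i],
              detections$x[j] + detections$w[j]) -
      max(detections$x[i], detections$x[j])
    iy <- min(detections$y[i] + detections$h[i],
              detections$y[j] + detections$h[j]) -
      max(detections$y[i], detections$y[j])
    if (ix > 0 && iy > 0) parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(seq_len(n), roots))
}

#' Retain one color channel above a threshold
#'
#' @param image RGB `favf_image` (H x W x 3 array).
#' @param channel `"red"` or `"green"`.
#' @param threshold Grey level; pixels at or below it are zeroed.
#' @return Grayscale matrix.
#' @export
channel_threshold <- function(image, channel = c("red", "green"),
                              threshold = 0) {
  channel <- match.arg(channel)
  if (is.matrix(image) || length(dim(image)) != 3)
    stop("channel_threshold() needs a 3-channel image")
  m <- image_channel(image, channel)
  m[m <= threshold] <- 0
  m
}

#' Otsu binarization
#'
#' Applies Otsu's global threshold. A constant input cannot be thresholded
#' and returns an all-background mask flagged `degenerate`.
#'
#' @param mask Grayscale matrix.
#' @return Binary 0/1 matrix with attribute `degenerate` and the chosen
#'   `threshold` (grey levels).
#' @export
binarize <- function(mask) {
  if (!is.matrix(mask)) stop("binarize() needs a single-channel matrix")
  rng <- range(mask)
  if (diff(rng) < 1e-12) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    attr(out, "degenerate") <- TRUE
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  th <- EBImage::otsu(.eb(mask / 255), range = c(0, 1)) * 255
  out <- (mask > th) * 1L
  attr(out, "degenerate") <- FALSE
  attr(out, "threshold") <- th
  out
}

#' Morphological opening with a disc element
#'
#' Erosion followed by dilation; removes speckle smaller than the disc and
#' severs thin bridges between touching cells.
#'
#' @param binary Binary 0/1 matrix.
#' @param radius Disc radius in pixels (>= 1).
#' @return Binary matrix.
#' @export
morphology_clean <- function(binary, radius = 2) {
  stopifnot(radius >= 1)
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  out <- .uneb(EBImage::opening(.eb(binary), brush))
  (out > 0.5) * 1L
}

#' Distance-transform markers for watershed
#'
#' Computes the Euclidean distance transform of the foreground and labels
#' the regions above `marker_threshold` of its maximum as cell markers
#' (one per connected component). An additional background marker ("water
#' hole") is placed as a small block in the top-left corner — or, if the
#' foreground touches that corner, in the corner with the least
#' foreground.
#'
#' @param binary Binary 0/1 matrix.
#' @param marker_threshold Fraction of the maximum distance (0, 1). The
#'   default 0.8 sits above the distance-transform saddle of touching
#'   cells with center separation down to about 0.7 of the sum of their
#'   radii, so such pairs yield separate markers.
#' @return Integer marker matrix: 0 unassigned, 1 background marker,
#'   2, 3, ... cell markers. Attribute `n_cells` gives the cell-marker
#'   count.
#' @export
distance_markers <- function(binary, marker_threshold = 0.8) {
  stopifnot(marker_threshold > 0, marker_threshold < 1)
  H <- nrow(binary); W <- ncol(binary)
  markers <- matrix(0L, H, W)
  n_cells <- 0L
  if (any(binary > 0)) {
    dt <- .uneb(EBImage::distmap(.eb(binary)))
    # split the distance map at its saddles first, then threshold each
    # basin against its own maximum: a globally scaled threshold would
    # starve the smaller cells of a cluster of their markers
    basins <- .uneb(EBImage::watershed(.eb(dt), tolerance = 1.5, ext = 1))
    basins <- matrix(as.integer(round(basins)), H, W)
    nlab <- 0L
    for (b in sort(setdiff(unique(as.integer(basins)), 0L))) {
      inb <- basins == b
      mx <- max(dt[inb])
      seed <- inb & dt > marker_threshold * mx
      if (any(seed)) {
        nlab <- nlab + 1L
        markers[seed] <- nlab + 1L
      }
    }
    n_cells <- nlab
  }
  # background water hole
  blk <- 1:min(5L, H); blc <- 1:min(5L, W)
  corners <- list(list(r = blk, c = blc),
                  list(r = blk, c = (W - length(blc) + 1):W),
                  list(r = (H - length(blk) + 1):H, c = blc),
                  list(r = (H - length(blk) + 1):H,
                       c = (W - length(blc) + 1):W))
  fg_load <- vapply(corners, function(co) sum(binary[co$r, co$c]), 0)
  co <- corners[[which.min(fg_load)]]
  markers[co$r, co$c] <- 1L
  attr(markers, "n_cells") <- as.integer(n_cells)
  markers
}

#' Marker-controlled watershed separation
#'
#' Grows the markers over an inverted, lightly smoothed intensity surface
#' (fluorescent cells are bright-centered, so bright centers act as
#' basins), restricted to the union of bright foreground and marker
#' support. Boundary lines form between touching cells; each cell's
#' location is the centroid of its region.
#'
#' @param image Grayscale matrix (the channel the cells fluoresce in).
#' @param markers Marker matrix from [distance_markers()].
#' @param mask Optional binary foreground restriction; defaults to the
#'   Otsu foreground of `image`.
#' @return List `labels` (integer matrix, cell regions labelled 2, 3, ...),
#'   `centers` (data frame `x`, `y`, `label`, 0-based px) and `count`.
#' @export
watershed_separate <- function(image, markers, mask = NULL) {
  image <- image_channel(image, "red")
  stopifnot(identical(dim(image), dim(markers)))
  n_cells <- sum(unique(as.integer(markers)) >= 2L)
  if (n_cells == 0)
    return(list(labels = matrix(0L, nrow(image), ncol(image)),
                centers = data.frame(x = numeric(), y = numeric(),
                                     label = integer()),
                count = 0L))
  surf <- .conv2_same(image, gaussian_psf(1))
  surf <- max(surf) - surf               # bright centers become basins
  if (is.null(mask)) mask <- binarize(image)
  grow <- (mask > 0) | (markers > 0)
  lab <- .uneb(EBImage::propagate(.eb(surf / max(surf, 1)),
                                  seeds = .eb(markers),
                                  mask = .eb(grow * 1)))
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  lab[lab == 1L] <- 0L                   # drop the background region
  labs <- sort(setdiff(unique(as.integer(lab)), 0L))
  centers <- do.call(rbind, lapply(labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    data.frame(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1, label = l)
  }))
  if (is.null(centers))
    centers <- data.frame(x = numeric(), y = numeric(), label = integer())
  list(labels = lab, centers = centers, count = length(labs))
}

#' Separate an overlapped detection group into individual cells
#'
#' Runs the full segmentation chain — red-channel retention, Otsu
#' binarization, morphological opening, distance-transform markers and
#' marker-controlled watershed — inside the group's union bounding box
#' (with margin), and returns per-cell centers in whole-image coordinates.
#'
#' @param image RGB `favf_image`.
#' @param detections Detections data frame.
#' @param group Integer vector of rows of `detections` forming one
#'   overlapping group (>= 2 members, from [overlap_judgement()]).
#' @param margin Bounding-box enlargement factor.
#' @param channel Fluorescence channel of the targets.
#' @param open_radius Disc radius for [morphology_clean()].
#' @param marker_threshold Passed to [distance_markers()].
#' @return Data frame of centers (`x`, `y`, 0-based px in image
#'   coordinates) with attribute `under_segmented` set when the watershed
#'   recovered fewer regions than detections.
#' @export
segment_overlapped <- function(image, detections, group, margin = 1.5,
                               channel = "red", open_radius = 2,
                               marker_threshold = 0.8) {
  stopifnot(length(group) >= 1)
  H <- dim(image)[1]; W <- dim(image)[2]
  gx0 <- min(detections$x[group]); gy0 <- min(detections$y[group])
  gx1 <- max(detections$x[group] + detections$w[group])
  gy1 <- max(detections$y[group] + detections$h[group])
  cx <- (gx0 + gx1) / 2; cy <- (gy0 + gy1) / 2
  hw <- (gx1 - gx0) / 2 * margin; hh <- (gy1 - gy0) / 2 * margin
  x0 <- max(0, floor(cx - hw)); x1 <- min(W - 1, ceiling(cx + hw))
  y0 <- max(0, floor(cy - hh)); y1 <- min(H - 1, ceiling(cy + hh))
  sub <- image[(y0:y1) + 1L, (x0:x1) + 1L, , drop = FALSE]
  m <- channel_threshold(sub, channel, 0)
  bin <- binarize(m)
  bin <- morphology_clean(bin, open_radius)
  markers <- distance_markers(bin, marker_threshold)
  res <- watershed_separate(m, markers, mask = bin)
  centers <- res$centers
  if (nrow(centers)) {
    centers$x <- centers$x + x0
    centers$y <- centers$y + y0
  }
  attr(centers, "under_segmented") <- res$count < length(group)
  centers
}
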