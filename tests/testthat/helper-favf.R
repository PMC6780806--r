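# Shared fixtures. Everything is generated in code; the template pyramid
# and the depth calibration are cached per test session because they are
# deterministic and moderately expensive.

.test_cache <- new.env(parent = emptyenv())

test_optics <- function(noise = TRUE) {
  optics_config(noise_sigma = if (noise) 2 else 0)
}

test_templates <- function(optics = test_optics()) {
  key <- paste0("tset_", optics$noise_sigma)
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- build_scalable_templates(reference_template(optics))
  .test_cache[[key]]
}

# single-cell scene whose renderer serves as an MDFD stack provider
cell_provider <- function(diameter = 12, seed = 1L, optics = test_optics(),
                          roi_um = 50, z = 0) {
  sc <- scene(list(cell_spec(1, roi_um / 2, roi_um / 2, z, diameter, "red")),
              fov_width = roi_um, fov_height = roi_um, rng_seed = seed)
  function(zz) render_scene(sc, zz, optics)
}

# brute-force evaluation of the mean-subtracted, norm-normalized
# correlation coefficient -- the independent oracle for correlation_map
brute_correlation <- function(img, tpl) {
  h <- nrow(tpl); w <- ncol(tpl)
  Hr <- nrow(img) - h + 1; Wr <- ncol(img) - w + 1
  Tm <- tpl - mean(tpl)
  tn <- sqrt(sum(Tm^2))
  out <- matrix(0, Hr, Wr)
  for (y in seq_len(Hr)) for (x in seq_len(Wr)) {
    win <- img[y:(y + h - 1), x:(x + w - 1)]
    Wm <- win - mean(win)
    wn <- sqrt(sum(Wm^2))
    out[y, x] <- if (tn < 1e-12 || wn < 1e-9) 0 else
      sum(Tm * Wm) / (tn * wn)
  }
  out
}

# 1D convolution with a unit-sum kernel (for analytic profile fixtures)
conv1 <- function(x, k) {
  n <- length(x); m <- length(k); half <- (m - 1) %/% 2
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  vapply(seq_len(n), function(i) sum(xp[i:(i + m - 1)] * k), 0)
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# count recovered instances over all detection groups of an image
count_instances <- function(img, detections) {
  groups <- overlap_judgement(detections)
  total <- 0
  for (g in groups)
    total <- total + if (length(g) >= 2)
      nrow(segment_overlapped(img, detections, g)) else 1
  total
}
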