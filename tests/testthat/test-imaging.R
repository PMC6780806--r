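test_that("gaussian_psf is a normalized, symmetric kernel with a delta limit", {
  expect_identical(gaussian_psf(0), matrix(1, 1, 1))
  for (s in c(0.5, 2, 7)) {
    k <- gaussian_psf(s)
    expect_equal(sum(k), 1, tolerance = 1e-9)
    expect_equal(k, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))])
    expect_equal(k, t(k))
  }
  expect_error(gaussian_psf(-1), "non-negative")
})

test_that("model_blur_diameter follows the linear law and is symmetric in z", {
  opt <- test_optics()
  cl <- cell_spec(1, 0, 0, 8, focused_diameter = 10)
  # growth = blur_slope * pixel_size per um of defocus
  expect_equal(model_blur_diameter(cl, opt),
               10 + opt$blur_slope * opt$pixel_size * 8)
  cl0 <- cell_spec(1, 0, 0, 0)
  expect_equal(model_blur_diameter(cl0, opt), cl0$focused_diameter)
  cp <- cell_spec(1, 0, 0, 13); cm <- cell_spec(1, 0, 0, -13)
  expect_equal(model_blur_diameter(cp, opt), model_blur_diameter(cm, opt))
})

test_that("rendering conserves per-cell energy and lowers the peak under defocus", {
  opt <- test_optics(noise = FALSE)
  sc <- scene(list(cell_spec(1, 25, 25, 0, 12, "red")),
              fov_width = 50, fov_height = 50, rng_seed = 1)
  i0 <- render_scene(sc, 0, opt, noise = FALSE)
  i10 <- render_scene(sc, 10, opt, noise = FALSE)
  bg <- opt$background_level * prod(dim(i0)[1:2])
  e0 <- sum(i0[, , 1]) - bg; e10 <- sum(i10[, , 1]) - bg
  expect_lt(abs(e0 - e10) / e0, 0.005)
  expect_gt(max(i0[, , 1]), max(i10[, , 1]))
})

test_that("images at +z and -z around focus are identical for a centered cell", {
  opt <- test_optics(noise = FALSE)
  mk <- function(z) {
    sc <- scene(list(cell_spec(1, 25, 25, z, 12, "red")),
                fov_width = 50, fov_height = 50, rng_seed = 1)
    render_scene(sc, 0, opt, noise = FALSE)
  }
  expect_identical(unclass(mk(9))[, , 1], unclass(mk(-9))[, , 1])
})

test_that("measured blur diameter grows linearly with defocus (noise-free)", {
  opt <- test_optics(noise = FALSE)
  prov <- cell_provider(12, seed = 2, optics = opt)
  zs <- c(8, 14, 20, 26, 32, 38)
  W <- vapply(zs, function(z) {
    g <- preprocess_roi(prov(z))
    labs <- kmeans_segment(g, 3)
    measure_blur(extract_cell_region(labs), g)$D_n
  }, 0)
  fit <- fit_blur_linearity(zs, W)
  expect_gt(fit$r_squared, 0.99)
})

test_that("rendering is bit-deterministic for a fixed seed", {
  opt <- test_optics()
  sc <- scene(list(cell_spec(1, 20, 30, 5, 12, "red")),
              fov_width = 50, fov_height = 50, rng_seed = 42)
  a <- render_scene(sc, 3, opt)
  b <- render_scene(sc, 3, opt)
  expect_identical(unclass(a), unclass(b))
})

test_that("cells beyond the valid depth range fall below the noise floor", {
  opt <- test_optics()
  sc <- scene(list(cell_spec(1, 25, 25, 50, 12, "red")),
              fov_width = 50, fov_height = 50, rng_seed = 1)
  img <- render_scene(sc, 0, opt, noise = FALSE)
  peak <- max(img[, , 1]) - opt$background_level
  expect_lt(peak, 2 * opt$noise_sigma)
})

test_that("defocus stacks carry the requested plane geometry", {
  opt <- test_optics(noise = FALSE)
  sc <- scene(list(cell_spec(1, 25, 25, 0, 12, "red")),
              fov_width = 50, fov_height = 50, rng_seed = 1)
  st <- render_defocus_stack(sc, -6, 6, 3, opt, noise = FALSE)
  expect_equal(diff(st$z_offsets), c(6, 6))
  stn <- render_defocus_stack(sc, 6, -6, 3, opt, noise = FALSE)
  expect_equal(stn$z_offsets, c(6, 0, -6))
  expect_error(render_defocus_stack(sc, 0, 6, 1, opt), "count")
  expect_error(render_defocus_stack(sc, 0, 0, 3, opt), "step")
  # contrast of the in-focus scene peaks at the central plane
  cc <- vapply(st$images, function(im) {
    g <- preprocess_roi(im)
    contrast(extract_pgdc(g, c(100, 100)))
  }, 0)
  expect_equal(which.max(cc), 2L)
})

test_that("mixture scenes honor counts, ratio, determinism and overlap", {
  sc <- make_mixture_scene(1, ratio = 100, fov_width = 600, fov_height = 600,
                           seed = 3)
  cols <- vapply(sc$cells, `[[`, "", "color")
  expect_equal(sum(cols == "red"), 1)
  expect_equal(sum(cols == "green"), 100)
  sc2 <- make_mixture_scene(1, ratio = 100, fov_width = 600,
                            fov_height = 600, seed = 3)
  expect_identical(sc, sc2)
  # overlap fraction: at least half the targets have intersecting footprints
  sc3 <- make_mixture_scene(20, ratio = 1, fov_width = 700, fov_height = 700,
                            overlap_fraction = 0.5, seed = 4)
  reds <- Filter(function(cl) cl$color == "red", sc3$cells)
  n_touch <- sum(vapply(seq_along(reds), function(i) {
    any(vapply(seq_along(sc3$cells), function(j) {
      cl <- sc3$cells[[j]]
      if (cl$id == reds[[i]]$id) return(FALSE)
      sqrt((cl$x - reds[[i]]$x)^2 + (cl$y - reds[[i]]$y)^2) <
        (cl$focused_diameter + reds[[i]]$focused_diameter) / 2
    }, TRUE))
  }, TRUE))
  expect_gte(n_touch, 10)
  expect_error(make_mixture_scene(500, ratio = 100, fov_width = 100,
                                  fov_height = 100, seed = 1),
               "infeasible")
})

test_that("cluster scenes keep cells touching but not interpenetrating", {
  for (s in 1:5) {
    sc <- make_cluster_scene(3, seed = s)
    for (i in 1:2) for (j in (i + 1):3) {
      a <- sc$cells[[i]]; b <- sc$cells[[j]]
      dd <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
      expect_gte(dd, 0.75 * (a$focused_diameter + b$focused_diameter) / 2)
    }
    # chained contact: at least one pair overlaps
    overl <- any(vapply(1:2, function(i) any(vapply((i + 1):3, function(j) {
      a <- sc$cells[[i]]; b <- sc$cells[[j]]
      sqrt((a$x - b$x)^2 + (a$y - b$y)^2) <
        (a$focused_diameter + b$focused_diameter) / 2
    }, TRUE)), TRUE))
    expect_true(overl)
  }
})

test_that("scene/optics serialization round-trips", {
  sc <- make_mixture_scene(2, ratio = 3, fov_width = 100, fov_height = 100,
                           seed = 11)
  f <- tempfile(fileext = ".json")
  scene_to_json(sc, f)
  sc2 <- scene_from_json(f)
  expect_equal(length(sc2$cells), length(sc$cells))
  expect_equal(sc2$cells[[1]]$x, sc$cells[[1]]$x)
  fo <- tempfile(fileext = ".yaml")
  optics_to_yaml(test_optics(), fo)
  expect_equal(optics_from_yaml(fo), test_optics())
  # image TIFF round trip
  img <- render_scene(sc, 0, test_optics(),
                      size_um = c(25, 25))
  ft <- tempfile(fileext = ".tif")
  write_image_tiff(img, ft)
  back <- read_image_tiff(ft, pixel_size = attr(img, "pixel_size"))
  expect_equal(max(abs(unclass(back) - unclass(img))), 0)
})
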