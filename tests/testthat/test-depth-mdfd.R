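test_that("ROI preprocessing returns a smoothed single channel", {
  img <- array(runif(32 * 32 * 3, 0, 255), dim = c(32, 32, 3))
  g <- preprocess_roi(img, sigma = 1)
  expect_true(is.matrix(g))
  expect_equal(dim(g), c(32, 32))
  flat <- matrix(77, 20, 20)
  expect_equal(preprocess_roi(flat, 1), flat, tolerance = 1e-9)
  spiky <- matrix(0, 21, 21); spiky[11, 11] <- 255
  expect_lt(max(preprocess_roi(spiky, 2)), 255)
})

test_that("k-means on grayscale recovers discrete level sets exactly", {
  m <- matrix(c(10, 120, 240)[sample.int(3, 400, replace = TRUE)], 20, 20)
  labs <- kmeans_segment(m, 3)
  expect_equal(attr(labs, "k_effective"), 3L)
  expect_true(all(labs[m == 10] == 0))
  expect_true(all(labs[m == 120] == 1))
  expect_true(all(labs[m == 240] == 2))
  # binary image with k = 2
  b <- matrix(c(0, 200)[sample.int(2, 100, replace = TRUE)], 10, 10)
  labs2 <- kmeans_segment(b, 2)
  expect_true(all(labs2[b == 0] == 0) && all(labs2[b == 200] == 1))
  # fewer distinct values than k: reduced and flagged
  labs3 <- kmeans_segment(matrix(c(5, 9), 4, 4), 3)
  expect_true(attr(labs3, "reduced"))
  expect_lte(attr(labs3, "k_effective"), 2L)
})

test_that("extract_cell_region keeps the main component as a convex mask", {
  labs <- matrix(0L, 40, 40)
  labs[10:30, 10:30][outer(1:21, 1:21, function(y, x)
    (x - 11)^2 + (y - 11)^2 <= 81)] <- 2L
  labs[35, 35] <- 1L                           # 1-px speck
  mask <- extract_cell_region(labs)
  expect_equal(mask[35, 35], 0L)               # speck removed
  idx <- which(mask > 0, arr.ind = TRUE)
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  # convexity: the hull of the mask has (almost) the same area as the mask
  expect_lt(length(hull) / nrow(idx), 0.25)
  expect_error(extract_cell_region(matrix(0L, 10, 10)), "no cell")
})

test_that("measure_blur reports moment centers and row widths of a disc", {
  disc <- outer(1:60, 1:60, function(y, x)
    ((x - 31)^2 + (y - 29)^2 <= 400) * 1L)
  gray <- disc * 200 + 8
  mb <- measure_blur(disc, gray)
  expect_lt(abs(mb$center["x"] - 30), 0.6)
  expect_lt(abs(mb$center["y"] - 28), 0.6)
  expect_lt(abs(mb$D_n - 40), 1.6)
  # equivariance under translation
  disc2 <- disc[, c(11:60, 1:10)]              # shift left by 10
  mb2 <- measure_blur(disc2, disc2 * 200 + 8)
  expect_equal(unname(mb2$center["x"] - mb$center["x"]), -10, tolerance = 0.7)
  expect_error(measure_blur(matrix(0L, 5, 5), matrix(8, 5, 5)), "no cell")
})

test_that("PGDC extraction and contrast behave as defined", {
  g <- matrix(rep(8, 900), 30, 30)
  g[15, ] <- c(rep(8, 10), rep(200, 10), rep(8, 10))
  p <- extract_pgdc(g, c(15, 14))
  expect_equal(length(p$profile), 30)
  expect_equal(contrast(p), 192)
  expect_equal(contrast(rep(5, 10)), 0)
  expect_equal(contrast(c(12, 100, 200)), 188)
  expect_error(extract_pgdc(g, c(40, 14)), "outside")
  # symmetric cell gives a symmetric profile
  opt <- test_optics(noise = FALSE)
  prov <- cell_provider(12, optics = opt)
  gg <- preprocess_roi(prov(6))
  pp <- extract_pgdc(gg, c(100, 100))$profile
  pp <- pp[-1]                       # center the reversal on the cell
  expect_lt(max(abs(pp - rev(pp))), 1.5)
})

test_that("sharpness judgement classifies contrast trends", {
  up <- sharpness_judgement(c(50, 80, 120))
  expect_equal(up$direction, "toward"); expect_false(up$screened)
  peak <- sharpness_judgement(c(80, 120, 85))
  expect_true(peak$screened)
  expect_equal(peak$bracket, c(1L, 3L))
  down <- sharpness_judgement(c(120, 80, 50))
  expect_equal(down$direction, "away"); expect_false(down$screened)
  expect_error(sharpness_judgement(c(1, 2)), "at least 3")
  thr <- sharpness_judgement(c(50, 80, 120), focus_threshold = 100)
  expect_equal(thr$focused_at, 3L)
})

test_that("focused diameter comes from profile intersections", {
  # analytic box profiles of width 30 spread by two unit-area kernels
  box <- c(rep(5, 35), rep(105, 30), rep(5, 35))
  p1 <- conv1(box, gauss_kernel_1d(1.5))
  p2 <- conv1(box, gauss_kernel_1d(5))
  D <- focused_diameter(list(p1, p2))
  expect_lt(abs(D - 30), 1)
  expect_error(focused_diameter(list(p1, p1)), "intersections")
  # simulated cell across three planes, noise-free
  opt <- test_optics(noise = FALSE)
  prov <- cell_provider(12, optics = opt)
  pg <- lapply(c(4, 10, 16), function(z) {
    g <- preprocess_roi(prov(z))
    extract_pgdc(g, c(100, 100))
  })
  D2 <- focused_diameter(pg)
  expect_lt(abs(D2 - 12 / opt$pixel_size) / (12 / opt$pixel_size), 0.1)
  # profiles of one cell at two planes intersect at exactly two points
  d12 <- pg[[1]]$profile - pg[[3]]$profile
  signs <- sign(d12[abs(d12) > 1])
  expect_equal(sum(diff(signs) != 0), 2)
})

test_that("the depth relation inverts the analytic blur law exactly", {
  expect_equal(depth_from_defocus(10, 16, 20, 6), 9)
  expect_equal(depth_from_defocus(10, 10, 14, 6), 0)
  expect_error(depth_from_defocus(10, 16, 16, 6), "degenerate")
  expect_error(depth_from_defocus(10, 8, 12, 6), "negative blur")
  # closed-form loop: diameters from the linear law recover depth exactly
  opt <- test_optics()
  for (z0 in c(2, 7.5, 13, 20)) for (d in c(2, 6, 12)) {
    Dn <- model_blur_diameter(cell_spec(1, 0, 0, z0), opt)
    Dn1 <- model_blur_diameter(cell_spec(1, 0, 0, z0 + d), opt)
    expect_equal(depth_from_defocus(12, Dn, Dn1, d), z0, tolerance = 1e-12)
  }
})

test_that("relative error implements the corrected formula", {
  expect_equal(relative_error(20, 20, 12), 0)
  expect_equal(relative_error(20, 18, 12), 6.25)
  expect_equal(relative_error(12, 10, 10), 100 * 2 / 22)
  expect_error(relative_error(0, 0, 0), "denominator")
})

test_that("a single MDFD pass recovers depth on noise-free input", {
  opt <- test_optics(noise = FALSE)
  prov <- cell_provider(12, optics = opt)
  for (di in c(4, 10, 16)) {
    sp <- mdfd_single_pass(prov, d = 6, optics = opt, start_z = di)
    expect_lt(relative_error(sp$d_n, di, sp$D_um), 5)
  }
})

test_that("iterative MDFD converges in a few cycles and flags out-of-range", {
  opt <- test_optics()
  prov <- cell_provider(12, seed = 17, optics = opt)
  est <- mdfd_estimate(prov, d = 6, optics = opt, start_z = 10)
  expect_equal(est$status, "focused")
  expect_lte(est$iterations, 4)
  expect_lt(relative_error(abs(est$d_n), 10, est$D_um), 5)
  # starting in focus: immediate convergence
  est0 <- mdfd_estimate(prov, d = 6, optics = opt, start_z = 0)
  expect_equal(est0$status, "focused")
  expect_equal(est0$iterations, 1L)
  expect_lt(abs(est0$d_n), 1.5)
  # a cell far beyond the fluorescence range is out of range
  sc <- scene(list(cell_spec(1, 25, 25, 50, 12, "red")),
              fov_width = 50, fov_height = 50, rng_seed = 1)
  provoor <- function(z) render_scene(sc, z, opt)
  eoor <- mdfd_estimate(provoor, d = 6, optics = opt, start_z = 0)
  expect_equal(eoor$status, "out_of_range")
})

test_that("each MDFD iteration reduces the distance to focus (noise-free)", {
  opt <- test_optics(noise = FALSE)
  prov <- cell_provider(12, optics = opt)
  est <- mdfd_estimate(prov, d = 6, optics = opt, start_z = 18,
                       max_iter = 4)
  resid <- abs(18 - cumsum(-est$trace))
  expect_true(all(diff(c(18, resid)) <= 0.5))
})

test_that("passes bracketing the focal plane are screened and still accurate", {
  opt <- test_optics(noise = FALSE)
  prov <- cell_provider(12, optics = opt)
  # plane 0 behind focus, travel crosses it: symmetric case
  sp <- mdfd_single_pass(prov, d = 6, optics = opt, start_z = -4)
  expect_true(sp$screened)
  expect_lt(abs(sp$move - 4), 1)
  # mirrored cells produce mirrored estimates
  spm <- mdfd_single_pass(prov, d = -6, optics = opt, start_z = 4)
  expect_lt(abs(spm$move + 4), 1)
})

test_that("the error sweep reproduces the qualitative error structure", {
  opt <- test_optics()
  sw <- run_error_sweep(opt, d_i_list = c(6, 30), d_list = c(6, 12),
                        n_cells = 2, seed = 5)
  expect_true(all(is.finite(sw$table["6um", ])))
  # deep starts with a long travel leave the fluorescence range: OOR
  expect_true(any(sw$long$status == "out_of_range"))
  expect_true(is.na(sw$table["30um", "12um"]) ||
                sw$table["30um", "12um"] > sw$table["6um", "12um"])
})

test_that("blur-linearity fitting behaves on exact, noisy and degenerate input", {
  f <- fit_blur_linearity(1:10, 2 * (1:10) + 3)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 3)
  expect_equal(f$r_squared, 1)
  set.seed(2)
  g <- fit_blur_linearity(1:50, rnorm(50))
  expect_lt(g$r_squared, 0.3)
  expect_error(fit_blur_linearity(rep(3, 5), rnorm(5)), "degenerate")
  expect_error(fit_blur_linearity(1:2, 1:2), "3 points")
})
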