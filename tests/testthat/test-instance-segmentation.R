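test_that("overlap judgement groups boxes by transitive intersection", {
  det <- data.frame(x = c(0, 20, 5, 12), y = c(0, 20, 5, 9),
                    w = c(10, 10, 10, 10), h = c(10, 10, 10, 10))
  groups <- overlap_judgement(det)
  sizes <- sort(vapply(groups, length, 0L))
  expect_equal(sizes, c(1L, 3L))                # chain 1-3-4, singleton 2
  grp <- groups[[which(vapply(groups, length, 0L) == 3L)]]
  expect_setequal(grp, c(1L, 3L, 4L))
  # disjoint boxes stay singletons; touching edges (area 0) do not group
  det2 <- data.frame(x = c(0, 10), y = c(0, 0), w = c(10, 10), h = c(10, 10))
  expect_equal(lengths(overlap_judgement(det2)), c(1L, 1L))
  expect_equal(overlap_judgement(det[0, ]), list())
})

test_that("channel_threshold retains only the requested channel above threshold", {
  img <- array(0, dim = c(8, 8, 3))
  img[3:6, 3:6, 2] <- 120                       # pure green square
  expect_true(all(channel_threshold(img, "red", 10) == 0))
  img[2:4, 2:4, 1] <- 200
  m <- channel_threshold(img, "red", 10)
  expect_equal(sum(m > 0), 9)
  expect_equal(channel_threshold(img, "red", 0), img[, , 1])
  expect_error(channel_threshold(matrix(0, 5, 5), "red"), "3-channel")
})

test_that("Otsu binarization splits a bimodal image and flags constant input", {
  m <- matrix(40, 20, 20); m[8:14, 8:14] <- 220
  b <- binarize(m)
  expect_false(attr(b, "degenerate"))
  expect_gt(attr(b, "threshold"), 40)
  expect_lt(attr(b, "threshold"), 220)
  expect_equal(sum(b), 49)
  flat <- binarize(matrix(13, 10, 10))
  expect_true(attr(flat, "degenerate"))
  expect_true(all(flat == 0))
})

test_that("morphological opening removes speckle and severs thin bridges", {
  m <- matrix(0L, 30, 30); m[15, 15] <- 1L
  expect_true(all(morphology_clean(m, 1) == 0))
  # disc survives opening up to boundary erosion
  disc <- outer(1:40, 1:40, function(y, x) ((x - 20)^2 + (y - 20)^2 <= 100) * 1L)
  op <- morphology_clean(disc, 2)
  expect_gt(sum(op), 0.85 * sum(disc))
  expect_true(all(disc[op > 0] == 1))
  # two discs joined by a 1-px bridge come apart
  two <- outer(1:40, 1:60, function(y, x)
    (((x - 15)^2 + (y - 20)^2 <= 64) | ((x - 45)^2 + (y - 20)^2 <= 64)) * 1L)
  two[20, 23:37] <- 1L
  opened <- morphology_clean(two, 2)
  lab <- EBImage::bwlabel(EBImage::Image(t(opened)))
  expect_equal(max(lab), 2)
})

test_that("distance markers seed one region per cell plus a background hole", {
  disc <- outer(1:40, 1:40, function(y, x) ((x - 20)^2 + (y - 20)^2 <= 121) * 1L)
  mk <- distance_markers(disc, 0.6)
  expect_equal(attr(mk, "n_cells"), 1L)
  expect_true(any(mk == 1))                     # background water hole
  expect_true(all(mk[1:5, 1:5] == 1))           # placed top-left
  # two overlapped discs, centers 1.2 radii apart
  r <- 12
  two <- outer(1:60, 1:60, function(y, x)
    (((x - 24)^2 + (y - 30)^2 <= r^2) |
       ((x - 24 - 1.2 * r)^2 + (y - 30)^2 <= r^2)) * 1L)
  mk2 <- distance_markers(two, 0.6)
  expect_equal(attr(mk2, "n_cells"), 2L)
  # empty mask: background marker only
  mk0 <- distance_markers(matrix(0L, 20, 20), 0.5)
  expect_equal(attr(mk0, "n_cells"), 0L)
  # foreground touching the origin relocates the background hole
  full <- matrix(0L, 30, 30); full[1:20, 1:20] <- 1L
  mk3 <- distance_markers(full, 0.5)
  expect_true(all(full[mk3 == 1] == 0))
})

test_that("marker-controlled watershed separates regions and reports centers", {
  disc <- outer(1:40, 1:40, function(y, x) ((x - 21)^2 + (y - 19)^2 <= 100) * 1)
  img <- disc * 180 + 8
  mk <- distance_markers((disc > 0) * 1L, 0.6)
  res <- watershed_separate(img, mk, mask = (disc > 0) * 1L)
  expect_equal(res$count, 1L)
  expect_lt(abs(res$centers$x - 20), 2)
  expect_lt(abs(res$centers$y - 18), 2)
  # background-only markers yield nothing
  bgonly <- matrix(0L, 40, 40); bgonly[1:5, 1:5] <- 1L
  expect_equal(watershed_separate(img, bgonly)$count, 0L)
})

test_that("watershed labels partition the mask and centers are label-stable", {
  sc <- make_cluster_scene(2, seed = 31)
  img <- render_scene(sc, 0, test_optics())
  m <- channel_threshold(img, "red", 0)
  b <- morphology_clean(binarize(m), 2)
  mk <- distance_markers(b)
  res <- watershed_separate(m, mk, mask = b)
  expect_equal(res$count, attr(mk, "n_cells"))
  # permuting marker labels permutes nothing in the recovered center set
  mk2 <- mk
  mk2[mk == 2] <- 3L; mk2[mk == 3] <- 2L
  attr(mk2, "n_cells") <- attr(mk, "n_cells")
  res2 <- watershed_separate(m, mk2, mask = b)
  ord1 <- order(res$centers$x, res$centers$y)
  ord2 <- order(res2$centers$x, res2$centers$y)
  expect_equal(res$centers[ord1, c("x", "y")],
               res2$centers[ord2, c("x", "y")], ignore_attr = TRUE)
  # labels are disjoint and restricted to the grown region
  expect_true(all(res$labels[b == 0 & mk == 0] == 0))
})

test_that("the full chain separates touching cells into the right count", {
  opt <- test_optics()
  tset <- test_templates(opt)
  ok2 <- 0
  for (s in 1:8) {
    sc <- make_cluster_scene(2, seed = 400 + s)
    img <- render_scene(sc, 0, opt)
    det <- rough_locate(image_channel(img, "red"), tset)$detections
    if (count_instances(img, det) == 2) ok2 <- ok2 + 1
  }
  expect_gte(ok2, 7)
  # a 3-cell cluster resolves into exactly 3 centers
  sc3 <- make_cluster_scene(3, seed = 301)
  img3 <- render_scene(sc3, 0, opt)
  det3 <- rough_locate(image_channel(img3, "red"), tset)$detections
  groups <- overlap_judgement(det3)
  big <- groups[[which.max(lengths(groups))]]
  centers <- segment_overlapped(img3, det3, big)
  expect_equal(nrow(centers), 3)
  truth <- t(vapply(sc3$cells, function(cl) c(cl$x, cl$y) / opt$pixel_size,
                    numeric(2)))
  for (i in seq_len(nrow(centers))) {
    err <- min(sqrt((truth[, 1] - centers$x[i])^2 +
                      (truth[, 2] - centers$y[i])^2))
    expect_lte(err, 5)
  }
})

test_that("cells of the other color are invisible to the red-channel chain", {
  opt <- test_optics()
  sc <- scene(list(cell_spec(1, 24, 30, 0, 12, "red"),
                   cell_spec(2, 33, 30, 0, 12, "red"),
                   cell_spec(3, 28, 39, 0, 12, "green")),
              fov_width = 60, fov_height = 60, rng_seed = 6)
  img <- render_scene(sc, 0, opt)
  det <- data.frame(x = c(80, 115), y = c(100, 100), w = c(55, 55),
                    h = c(55, 55))
  centers <- segment_overlapped(img, det, c(1, 2))
  expect_equal(nrow(centers), 2)
  expect_true(all(centers$y < 140))   # none near the green cell's row
})
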