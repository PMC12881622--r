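test_that("erosion removes strips, keeps block centres, and buffer 0 is identity", {
  lab <- matrix(1L, 9, 9)
  lab[, 5] <- 2L # one-pixel strip of class 2
  lr <- label_raster(lab)
  er <- erode_class_regions(lr, 10)
  expect_false(any(er$labels == 2L, na.rm = TRUE))

  lab2 <- matrix(1L, 9, 9)
  lab2[4:6, 4:6] <- 2L # 3x3 block: only the centre survives
  er2 <- erode_class_regions(label_raster(lab2), 10)
  expect_identical(which(er2$labels == 2L), 5L + 4L * 9L)

  expect_identical(erode_class_regions(lr, 0)$labels, lr$labels)
  expect_error(erode_class_regions(lr, -10), class = "fc_param_error")
  expect_error(erode_class_regions(lr, 15), class = "fc_param_error")
})

test_that("stratified points respect density caps, spacing and determinism", {
  # one class covering exactly 1 km2 (100 x 100 px at 10 m)
  lab <- matrix(1L, 100, 100)
  lab[1:50, ] <- 2L # class 2: 0.5 km2; class 1: 0.5 km2
  full <- matrix(1L, 100, 100) # class 1 alone = 1 km2
  pts_full <- draw_stratified_points(label_raster(full), density = 2,
                                     min_dist_m = 20, seed = 5)
  expect_lte(nrow(pts_full), 2)

  sc <- make_test_scene(rows = 96, cols = 96, seed = 51, n_clearing = 0,
                        n_burn = 0)
  er <- erode_class_regions(sc$truth$mock_reference, 10)
  pts <- suppressWarnings(
    draw_stratified_points(er, density = 60, min_dist_m = 20, seed = 5))
  expect_gt(nrow(pts), 10)
  # pairwise spacing across all classes
  d2 <- as.matrix(dist(cbind(pts$x, pts$y)))^2
  diag(d2) <- Inf
  expect_true(all(d2 >= 20^2))
  # per-class density cap against the eroded class areas
  km2 <- table(er$labels[!is.na(er$labels)]) * 1e-4
  cnt <- table(pts$class_id)
  for (cl in names(cnt)) {
    expect_lte(cnt[[cl]], floor(60 * km2[[cl]]))
  }
  # points only on pixels of their own class, inside the grid
  expect_true(all(er$labels[cbind(pts$row, pts$col)] == pts$class_id))
  # determinism
  pts2 <- suppressWarnings(
    draw_stratified_points(er, density = 60, min_dist_m = 20, seed = 5))
  expect_identical(as.data.frame(pts), as.data.frame(pts2))
  # three attributes are coherent
  expect_true(all(pts$forest == (pts$leaf_type != "none")))
})

test_that("spectral verification keeps clean points and drops planted outliers", {
  sc <- make_test_scene(rows = 64, cols = 64, seed = 52, n_clearing = 0,
                        n_burn = 0, noise_sd = 0, seasonal_amplitude = 0,
                        cloud_fraction = 0, label_noise_rate = 0)
  st <- sc$acquisitions[["2020"]][[1]]
  er <- erode_class_regions(sc$truth$labels[[1]], 10)
  pts <- suppressWarnings(
    draw_stratified_points(er, density = 200, min_dist_m = 20, seed = 6))
  v <- verify_samples_spectral(pts, st)
  expect_identical(nrow(v), nrow(pts)) # no outliers exist on a clean scene

  # plant a mislabelled point: spectra of water, labelled coniferous
  wrong <- pts[pts$class == "water", ][1, ]
  wrong$class_id <- fc_classes()[["coniferous"]]
  wrong$class <- "coniferous"
  planted <- dplyr::bind_rows(pts, wrong)
  v2 <- verify_samples_spectral(planted, st, min_points = 3)
  expect_identical(nrow(v2), nrow(pts)) # exactly the planted point dropped
  expect_true(all(v2$row * 1000 + v2$col != wrong$row * 1000 + wrong$col |
                    v2$class_id != wrong$class_id))
  # verification never adds points
  expect_lte(nrow(v2), nrow(planted))
  # empty input passes through
  expect_identical(nrow(verify_samples_spectral(pts[0, ], st)), 0L)
})

test_that("verification reduces the mislabelled fraction under label noise", {
  sc <- make_test_scene(rows = 96, cols = 96, seed = 53, n_clearing = 0,
                        n_burn = 0, label_noise_rate = 0.25,
                        cloud_fraction = 0)
  st <- sc$acquisitions[["2020"]][[1]]
  truth <- sc$truth$labels[[1]]$labels
  er <- erode_class_regions(sc$truth$mock_reference, 10)
  pts <- suppressWarnings(
    draw_stratified_points(er, density = 120, min_dist_m = 20, seed = 7))
  mislabelled <- function(p) mean(truth[cbind(p$row, p$col)] != p$class_id)
  before <- mislabelled(pts)
  v <- verify_samples_spectral(pts, st)
  expect_gt(before, 0) # noise patches survive erosion by construction
  expect_lt(mislabelled(v), before)
})

test_that("role splitting honours the per-class ratio and the seed", {
  pts <- tibble::tibble(
    row = 1:20, col = 1:20, x = 1:20, y = 1:20,
    class_id = rep(c(1L, 2L), each = 10),
    class = rep(c("coniferous", "broadleaved"), each = 10),
    forest = TRUE,
    leaf_type = rep(c("coniferous", "broadleaved"), each = 10),
    role = NA_character_, source = "reference-raster"
  )
  s60 <- split_samples(pts, 0.6, seed = 8)
  expect_equal(unname(table(s60$role, s60$class_id)["train", ]), c(6, 6))
  expect_equal(unname(table(s60$role, s60$class_id)["validation", ]), c(4, 4))
  s70 <- split_samples(pts, 0.7, seed = 8)
  expect_equal(sum(s70$role == "train"), 14)
  expect_equal(sum(s70$role == "validation"), 6)
  expect_identical(split_samples(pts, 0.6, seed = 8)$role, s60$role)
  expect_error(split_samples(pts, 1.2, seed = 1), class = "fc_param_error")
  one <- pts[c(1, 11:20), ]
  expect_warning(s1 <- split_samples(one, 0.6, seed = 1), "single point")
  expect_identical(s1$role[1], "train")
})
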