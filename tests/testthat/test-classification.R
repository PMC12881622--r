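# Shared fixture: a clean two-year scene plus a drawn, split sample set.
clean_scene_samples <- function(rows = 48, seed = 61, noise_sd = 0,
                                density = 300) {
  sc <- make_test_scene(rows = rows, cols = rows, seed = seed,
                        n_clearing = 0, n_burn = 0, noise_sd = noise_sd,
                        seasonal_amplitude = 0, cloud_fraction = 0,
                        label_noise_rate = 0)
  er <- erode_class_regions(sc$truth$labels[[1]], 10)
  pts <- suppressWarnings(
    draw_stratified_points(er, density = density, min_dist_m = 20,
                           seed = seed + 1))
  pts <- split_samples(pts, 0.6, seed = seed + 2)
  list(scene = sc, samples = pts)
}

test_that("feature extraction has date-times-band arity and drops masked rows", {
  fx <- clean_scene_samples()
  stacks <- fx$scene$acquisitions[["2020"]][1:3]
  ft <- extract_features(stacks, fx$samples)
  expect_length(attr(ft, "feature_names"), 30) # 3 dates x 10 bands
  # all rows of one class identical on a noise-free scene
  one <- ft[ft$class_id == ft$class_id[1], attr(ft, "feature_names")]
  expect_true(all(vapply(one, function(cl) length(unique(cl)) == 1,
                         logical(1))))
  # a sample on a cloud-masked pixel in one date is dropped
  stacks2 <- stacks
  bad <- matrix(TRUE, 48, 48)
  bad[fx$samples$row[1], fx$samples$col[1]] <- FALSE
  stacks2[[2]] <- band_stack(stacks2[[2]]$values,
                             valid = stacks2[[2]]$valid & bad,
                             date = stacks2[[2]]$date, year = 2020)
  ft2 <- extract_features(stacks2, fx$samples)
  expect_equal(nrow(ft2), nrow(ft) - 1)
  expect_equal(attr(ft2, "n_dropped"), 1L)
})

test_that("separable training reaches perfect validation accuracy, deterministically", {
  fx <- clean_scene_samples()
  stacks <- fx$scene$acquisitions[["2020"]]
  ft <- extract_features(stacks, fx$samples)
  m <- train_model(ft, "forest", seed = 3)
  expect_equal(m$validation_accuracy, 1)
  ml <- train_model(ft, "leaf_type", seed = 3)
  expect_equal(ml$validation_accuracy, 1)
  # same seed and data give identical predictions everywhere
  map_a <- classify_scene(stacks, train_model(ft, "forest", seed = 3))
  map_b <- classify_scene(stacks, train_model(ft, "forest", seed = 3))
  expect_identical(map_a$values, map_b$values)
  # single-class table refuses to train
  only_forest <- ft[ft$forest, ]
  attr(only_forest, "feature_names") <- attr(ft, "feature_names")
  expect_error(train_model(only_forest, "forest"),
               class = "fc_training_error")
})

test_that("schema mismatches are refused", {
  fx <- clean_scene_samples()
  stacks <- fx$scene$acquisitions[["2020"]]
  ft <- extract_features(stacks, fx$samples)
  m <- train_model(ft, "forest", seed = 3)
  expect_error(classify_scene(stacks[1:2], m), class = "fc_schema_error")
})

test_that("two-stage maps recover truth and respect the mask hierarchy", {
  fx <- clean_scene_samples()
  stacks <- fx$scene$acquisitions[["2020"]]
  ft <- extract_features(stacks, fx$samples)
  fmap <- classify_scene(stacks, train_model(ft, "forest", seed = 3))
  fmask <- forest_mask(fmap)
  truth_woody <- fx$scene$truth$labels[[1]]$labels %in% fc_woody_classes()
  dim(truth_woody) <- dim(fmask)
  expect_identical(fmask, truth_woody) # zero noise: exact recovery
  lmap <- classify_scene(stacks, train_model(ft, "leaf_type", seed = 3),
                         within_mask = fmask)
  # no tree class outside the forest mask
  expect_true(all(lmap$values[!fmask] %in% c(0L, NA)))
  # leaf labels match truth inside the mask
  truth_lab <- fx$scene$truth$labels[[1]]$labels
  expect_true(all(lmap$values[fmask] == truth_lab[fmask]))
})

test_that("model transfer to a second scene from the same signatures is exact at zero noise", {
  fx <- clean_scene_samples(seed = 61)
  stacks <- fx$scene$acquisitions[["2020"]]
  ft <- extract_features(stacks, fx$samples)
  m <- train_model(ft, "forest", seed = 3)
  other <- make_test_scene(rows = 48, cols = 48, seed = 77, n_clearing = 0,
                           n_burn = 0, noise_sd = 0, seasonal_amplitude = 0,
                           cloud_fraction = 0, label_noise_rate = 0)
  map_t <- classify_scene(other$acquisitions[["2020"]], m)
  truth_woody <- other$truth$labels[[1]]$labels %in% fc_woody_classes()
  dim(truth_woody) <- dim(map_t$values)
  # per-class recall 100%
  expect_true(all(map_t$values[truth_woody] == 1L))
  expect_true(all(map_t$values[!truth_woody] == 0L))
})

test_that("an all-masked scene yields an all-invalid map", {
  fx <- clean_scene_samples()
  stacks <- fx$scene$acquisitions[["2020"]]
  ft <- extract_features(stacks, fx$samples)
  m <- train_model(ft, "forest", seed = 3)
  dead <- lapply(stacks, function(s) {
    band_stack(s$values, valid = matrix(FALSE, 48, 48), date = s$date,
               year = s$year)
  })
  map <- classify_scene(dead, m)
  expect_true(all(is.na(map$values)))
})

test_that("predictions agree with an independent random-forest fit on a separable scene", {
  skip_if_not_installed("randomForest")
  fx <- clean_scene_samples()
  ft <- extract_features(fx$scene$acquisitions[["2020"]], fx$samples)
  fn <- attr(ft, "feature_names")
  m <- train_model(ft, "forest", seed = 3)
  rf <- randomForest::randomForest(
    x = as.data.frame(ft[ft$role == "train", fn]),
    y = factor(ifelse(ft$forest[ft$role == "train"], "forest", "non_forest")))
  val <- as.data.frame(ft[ft$role == "validation", fn])
  ours <- forestchange:::predict_fc(m, as.matrix(ft[ft$role == "validation", fn]))
  theirs <- as.character(predict(rf, val))
  expect_identical(ours, theirs) # both perfect on a separable scene
})
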