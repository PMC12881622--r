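# Clean two-year scene with events, mosaics, differences, stack and truth.
change_fixture <- function(rows = 64, seed = 71, noise_sd = 0,
                           n_clearing = 2, n_burn = 2) {
  sc <- make_test_scene(rows = rows, cols = rows, seed = seed,
                        n_clearing = n_clearing, n_burn = n_burn,
                        noise_sd = noise_sd, seasonal_amplitude = 0,
                        cloud_fraction = 0, label_noise_rate = 0)
  mos <- lapply(sc$acquisitions, seasonal_median_mosaic)
  woody <- sc$truth$labels[[1]]$labels %in% fc_woody_classes()
  dim(woody) <- c(rows, rows)
  dndvi <- index_difference(ndvi(mos[[1]]), ndvi(mos[[2]]), domain = woody)
  dnbr <- index_difference(nbr(mos[[1]]), nbr(mos[[2]]), domain = woody)
  stack <- build_feature_stack(mos[[1]], mos[[2]], dndvi, dnbr, woody)
  list(scene = sc, stack = stack, woody = woody,
       truth = sc$truth$change[[1]])
}

test_that("the change feature stack has 22 features and strict validity", {
  fx <- change_fixture()
  expect_equal(ncol(fx$stack$features), 22)
  expect_identical(colnames(fx$stack$features),
                   c(paste0("t1_", fc_bands()), paste0("t2_", fc_bands()),
                     "dNDVI", "dNBR"))
  expect_true(all(fx$stack$valid == fx$woody))
  # a pixel invalidated in mosaic t2 becomes invalid in the stack
  sc <- fx$scene
  mos <- lapply(sc$acquisitions, seasonal_median_mosaic)
  mos2 <- mos[[2]]
  mos2$valid[5, 5] <- FALSE
  dndvi <- index_difference(ndvi(mos[[1]]), ndvi(mos2), domain = fx$woody)
  dnbr <- index_difference(nbr(mos[[1]]), nbr(mos2), domain = fx$woody)
  st2 <- build_feature_stack(mos[[1]], mos2, dndvi, dnbr, fx$woody)
  expect_false(st2$valid[5, 5])
  # unchanged pixels carry zero difference features
  nc <- fx$truth$values == fc_change_codes()[["no_change"]]
  expect_true(all(fx$stack$features[as.vector(nc), "dNDVI"] == 0))
  expect_true(all(fx$stack$features[as.vector(nc), "dNBR"] == 0))
})

test_that("reference-area sampling is stratified, in-polygon and 7:3 split", {
  fx <- change_fixture(rows = 96, seed = 72, n_clearing = 3, n_burn = 3)
  areas <- reference_areas_from_truth(fx$truth, seed = 4)
  expect_true(all(c("no_change", "woody_to_nonwoody", "burnt") %in%
                    areas$class))
  smp <- sample_reference_areas(areas, fx$stack, per_class_n = 100,
                                ratio = 0.7, seed = 5)
  tab <- table(smp$change_class, smp$role)
  for (cl in rownames(tab)) {
    n_cl <- sum(tab[cl, ])
    expect_equal(tab[cl, "train"], round(0.7 * n_cl))
  }
  full <- smp[smp$change_class == "no_change", ]
  expect_equal(table(full$role)[["train"]], 70)
  expect_equal(table(full$role)[["validation"]], 30)
  # every sample lies inside a reference area of its class
  for (i in seq_len(nrow(smp))) {
    a <- areas[areas$class == smp$change_class[i], ]
    expect_true(any(smp$row[i] >= a$row0 & smp$row[i] <= a$row1 &
                      smp$col[i] >= a$col0 & smp$col[i] <= a$col1))
  }
  # a class without a polygon refuses
  expect_error(
    sample_reference_areas(areas[areas$class != "burnt", ], fx$stack),
    class = "fc_sampling_error")
  # nine areas covering change and no-change classes are accepted
  nine <- suppressWarnings(reference_areas(tibble::tibble(
    class = rep(c("no_change", "woody_to_nonwoody", "burnt"), each = 3),
    row0 = rep(c(1L, 21L, 41L), 3), row1 = rep(c(20L, 40L, 60L), 3),
    col0 = rep(c(1L, 21L, 41L), each = 3), col1 = rep(c(20L, 40L, 60L), each = 3))))
  expect_s3_class(nine, "reference_areas")
  expect_equal(nrow(nine), 9)
})

test_that("a noise-free pair is classified exactly and respects the mask", {
  fx <- change_fixture(rows = 96, seed = 73, n_clearing = 3, n_burn = 3)
  areas <- reference_areas_from_truth(fx$truth, seed = 4,
                                      strata = fx$scene$truth$labels[[1]])
  smp <- sample_reference_areas(areas, fx$stack, per_class_n = 80, seed = 5)
  model <- train_change_model(smp, seed = 6)
  expect_equal(model$n_trees, 100)
  map <- classify_changes(fx$stack, model)
  expect_identical(map$values[fx$woody], fx$truth$values[fx$woody])
  expect_true(all(map$values[!fx$woody] == 0L))
  # containment: change classes only inside the forest mask
  expect_true(all(fx$woody[map$values %in% 2:3]))

  # transfer to a no-change pair: everything in-mask is class 1
  sc2 <- make_test_scene(rows = 64, cols = 64, seed = 74, n_clearing = 0,
                         n_burn = 0, noise_sd = 0, seasonal_amplitude = 0,
                         cloud_fraction = 0, label_noise_rate = 0)
  mos2 <- lapply(sc2$acquisitions, seasonal_median_mosaic)
  woody2 <- sc2$truth$labels[[1]]$labels %in% fc_woody_classes()
  dim(woody2) <- c(64, 64)
  dndvi2 <- index_difference(ndvi(mos2[[1]]), ndvi(mos2[[2]]), domain = woody2)
  dnbr2 <- index_difference(nbr(mos2[[1]]), nbr(mos2[[2]]), domain = woody2)
  st2 <- build_feature_stack(mos2[[1]], mos2[[2]], dndvi2, dnbr2, woody2)
  map2 <- classify_changes(st2, model)
  expect_true(all(map2$values[woody2] == fc_change_codes()[["no_change"]]))
})

test_that("the MMU filter removes <=4-pixel patches, keeps 5, and is idempotent", {
  v <- matrix(1L, 30, 30)
  v[2:3, 2:3] <- 2L            # 4-pixel clearing: removed
  v[10, 10:14] <- 3L           # 5-pixel burn line: kept
  v[20:21, 20:21] <- 3L        # 4-pixel burn: removed
  v[25, 25] <- 2L              # singleton: removed
  cm <- change_map(v, years = c(2020L, 2021L))
  f <- mmu_filter(cm)
  expect_true(all(f$values[2:3, 2:3] == 1L))
  expect_true(all(f$values[10, 10:14] == 3L))
  expect_true(all(f$values[20:21, 20:21] == 1L))
  expect_equal(f$values[25, 25], 1L)
  expect_true(f$mmu_applied)
  expect_identical(mmu_filter(f)$values, f$values)
  # diagonal chains count as one component under 8-connectivity
  v2 <- matrix(1L, 10, 10)
  v2[cbind(1:5, 1:5)] <- 2L
  expect_true(all(mmu_filter(change_map(v2))$values[cbind(1:5, 1:5)] == 2L))
  expect_true(all(mmu_filter(change_map(v2), connectivity = 4)$values ==
                    1L | v2 == 1L))
})

test_that("MMU kept/removed decisions match an independent flood-fill oracle", {
  set.seed(99)
  for (rep in 1:8) {
    v <- matrix(1L, 40, 40)
    v[matrix(runif(1600) < 0.08, 40, 40)] <- 2L
    v[matrix(runif(1600) < 0.05, 40, 40)] <- 3L
    cm <- change_map(v)
    f <- mmu_filter(cm)
    want <- v
    for (cl in c(2L, 3L)) {
      oc <- oracle_components(v == cl, connectivity = 8)
      if (oc$n == 0) next
      sizes <- tabulate(oc$labels[oc$labels > 0], nbins = oc$n)
      for (ci in which(sizes <= 4)) {
        want[oc$labels == ci] <- 1L
      }
    }
    expect_identical(f$values, want)
  }
})
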