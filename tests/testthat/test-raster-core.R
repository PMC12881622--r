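test_that("raster files round-trip values, mask, transform and band names", {
  sc <- make_test_scene(rows = 24, cols = 24, seed = 4, n_clearing = 0,
                        n_burn = 0, cloud_fraction = 0.1)
  st <- sc$acquisitions[["2020"]][[1]]
  path <- withr::local_tempfile(fileext = ".tif")
  write_raster(st, path)
  back <- read_raster(path)
  expect_equal(back$values, st$values, tolerance = 1e-6)
  expect_identical(back$valid, st$valid)
  expect_equal(back$transform, st$transform)
  expect_identical(dimnames(back$values)[[3]], fc_bands())
  # masked pixels come back as nodata
  expect_true(all(is.na(back$values[, , 1][!back$valid])))
})

test_that("malformed raster files are rejected", {
  expect_error(read_raster("/nonexistent/raster.tif"),
               class = "fc_format_error")
  # nine-band file: channel count disagrees with the canonical layout
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:10, function(i) matrix(runif(36), 6, 6)) # 9 bands + mask
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(driver = "forestchange-tiff-v1", bands = fc_bands(), scale = 1,
         offset = 0, pixel_size = 10, transform = c(0, 10, 0, 0, 0, -10),
         date = "NA", year = 2020, mask_channel = 11),
    paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_raster(path), class = "fc_format_error")
})

test_that("bilinear resampling is exact for constants and monotone gradients", {
  const <- matrix(0.3, 5, 5)
  out <- resample_bilinear(const, 2)
  expect_equal(dim(out), c(10, 10))
  expect_equal(out, matrix(0.3, 10, 10))

  grad <- matrix(c(0, 0, 1, 1), 2, 2) # columns 0 then 1
  out2 <- resample_bilinear(grad, 2)
  expect_true(all(diff(t(out2)) >= 0)) # monotone left to right
  expect_equal(out2[1, ], out2[2, ])
})

test_that("bilinear resampling agrees with a brute-force oracle", {
  set.seed(40)
  chk <- matrix(rep(c(0.2, 0.8), length.out = 36), 6, 6) # checkerboard-ish
  chk[2, 3] <- 0.5
  for (factor in c(2L, 4L)) {
    out <- resample_bilinear(chk, factor)
    for (i in seq_len(nrow(out))) {
      for (j in seq_len(ncol(out))) {
        expect_equal(out[i, j],
                     oracle_bilinear_point(chk, (i - 0.5) / factor,
                                           (j - 0.5) / factor),
                     tolerance = 1e-12)
      }
    }
    expect_true(all(out >= min(chk) & out <= max(chk)))
  }
  expect_error(resample_bilinear(chk, 1.5), class = "fc_param_error")
})

test_that("cloud/shadow masking removes exactly the flagged pixels", {
  sc <- make_test_scene(rows = 20, cols = 20, seed = 6, n_clearing = 0,
                        n_burn = 0, cloud_fraction = 0)
  st <- sc$acquisitions[["2020"]][[1]]
  p0 <- matrix(0, 20, 20)
  expect_identical(apply_cloud_mask(st, p0)$valid, st$valid)
  p1 <- matrix(1, 20, 20)
  expect_true(all(!apply_cloud_mask(st, p1)$valid))
  scl <- matrix(4L, 20, 20)
  scl[3:5, 7:9] <- 3L # cloud shadow
  masked <- apply_cloud_mask(st, p0, scl)
  expect_identical(masked$valid, !(scl == 3L))
  # reflectance untouched where still valid
  expect_equal(masked$values[, , 2][masked$valid],
               st$values[, , 2][masked$valid])
  expect_error(apply_cloud_mask(st, matrix(0, 3, 3)),
               class = "fc_param_error")
})

test_that("seasonal median follows the stated median conventions", {
  lab <- matrix(fc_classes()[["coniferous"]], 4, 4)
  mk <- function(vals, doys) {
    lapply(seq_along(vals), function(i) {
      st <- stack_from_labels(lab, doy = doys[i])
      st$values[] <- vals[i]
      st
    })
  }
  stacks <- mk(c(0.2, 0.9, 0.4), c(160, 180, 200))
  mos <- seasonal_median_mosaic(stacks)
  expect_true(all(mos$values == 0.4)) # odd-count median
  # fully masking one date leaves the mean of the remaining two
  stacks[[2]]$valid[] <- FALSE
  stacks[[2]] <- band_stack(stacks[[2]]$values, valid = stacks[[2]]$valid,
                            date = 180, year = 2020)
  mos2 <- seasonal_median_mosaic(stacks)
  expect_true(all(mos2$values == (0.2 + 0.4) / 2))
  expect_true(all(mos2$n_obs == 2))
  # constant series is idempotent
  mos3 <- seasonal_median_mosaic(mk(c(0.5, 0.5), c(170, 210)))
  expect_true(all(mos3$values == 0.5))
  # empty window selection errors
  expect_error(seasonal_median_mosaic(mk(0.5, 20)),
               class = "fc_empty_error")
})

test_that("mosaics are invariant to acquisition order and monotone in masking", {
  sc <- make_test_scene(rows = 32, cols = 32, seed = 8, n_clearing = 0,
                        n_burn = 0, cloud_fraction = 0.15)
  acq <- sc$acquisitions[["2020"]]
  m1 <- seasonal_median_mosaic(acq)
  for (perm_seed in 1:3) {
    set.seed(perm_seed)
    m2 <- seasonal_median_mosaic(sample(acq))
    expect_equal(m2$values, m1$values)
    expect_identical(m2$valid, m1$valid)
  }
  # masking one acquisition harder can only shrink validity, and leaves
  # pixels whose contributing set is unchanged at the same value
  acq2 <- acq
  extra <- matrix(FALSE, 32, 32); extra[1:10, 1:10] <- TRUE
  acq2[[2]] <- band_stack(acq2[[2]]$values,
                          valid = acq2[[2]]$valid & !extra,
                          date = acq2[[2]]$date, year = acq2[[2]]$year)
  m3 <- seasonal_median_mosaic(acq2)
  expect_true(all(m1$valid | !m3$valid))
  unchanged <- m3$n_obs == m1$n_obs
  expect_equal(m3$values[, , 5][unchanged & m3$valid],
               m1$values[, , 5][unchanged & m1$valid])
})
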