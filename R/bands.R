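# Band layout and the land-cover code table used across the package.

#' Sentinel-2 band set used throughout the pipeline
#'
#' The ten surface-reflectance bands retained for analysis: the four native
#' 10 m bands (B2 blue, B3 green, B4 red, B8 NIR) and the six 20 m bands
#' (red-edge B5--B7, B8A narrow NIR, B11/B12 SWIR) after bilinear resampling
#' to 10 m. The 60 m atmospheric bands are excluded.
#'
#' @return Character vector of band names in canonical order.
#' @export
fc_bands <- function() {
  c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A", "B11", "B12")
}

#' Land-cover class code table
#'
#' Integer codes for the eight mapped land-cover classes plus the two
#' disturbance surfaces that appear after a change event (burnt forest and
#' freshly cleared ground). Codes 1--2 are the woody (forest) classes.
#'
#' @return Named integer vector mapping class name to code.
#' @export
fc_classes <- function() {
  c(coniferous = 1L, broadleaved = 2L, sealed = 3L, grassland = 4L,
    cropland = 5L, bare_soil = 6L, wetland = 7L, water = 8L,
    burnt = 9L, cleared = 10L)
}

#' Woody (forest) class codes
#' @return Integer vector of the codes counted as forest.
#' @export
fc_woody_classes <- function() {
  unname(fc_classes()[c("coniferous", "broadleaved")])
}

#' Change-map code table
#'
#' @return Named integer vector: 0 outside the forest mask / invalid,
#'   1 no change, 2 woody converted to non-woody cover, 3 burnt forest.
#' @export
fc_change_codes <- function() {
  c(outside = 0L, no_change = 1L, woody_to_nonwoody = 2L, burnt = 3L)
}

#' Default spectral signature library
#'
#' One signature per land-cover class: per-band mean reflectance, per-band
#' seasonal sinusoid amplitude and a per-class Gaussian noise SD. Means are
#' plausible growing-season surface reflectances chosen so that every pair of
#' classes is separated by at least three noise SDs in at least one band at
#' the default noise level, the burnt surface has lower NIR (B8) and higher
#' SWIR2 (B12) than either woody class (so NBR drops after a burn), and the
#' cleared surface has lower NDVI than the woody classes.
#'
#' @param noise_sd Per-band Gaussian noise standard deviation applied to every
#'   class (reflectance units). Default 0.008.
#' @param seasonal_amplitude Per-band sinusoid amplitude for vegetated
#'   classes; non-seasonal surfaces (sealed, water, burnt) get 0. Default 0.01.
#' @return A tibble with one row per class: `class`, `class_id`, ten band-mean
#'   columns (`B2` ... `B12`), ten amplitude columns (`amp_B2` ...), `noise_sd`.
#' @export
default_signatures <- function(noise_sd = 0.008, seasonal_amplitude = 0.01) {
  bands <- fc_bands()
  means <- rbind(
    coniferous  = c(0.020, 0.040, 0.030, 0.050, 0.120, 0.150, 0.180, 0.190, 0.100, 0.050),
    broadleaved = c(0.030, 0.060, 0.040, 0.080, 0.250, 0.320, 0.380, 0.400, 0.160, 0.080),
    sealed      = c(0.120, 0.140, 0.160, 0.180, 0.200, 0.210, 0.220, 0.230, 0.240, 0.220),
    grassland   = c(0.040, 0.080, 0.070, 0.120, 0.220, 0.260, 0.300, 0.310, 0.200, 0.120),
    cropland    = c(0.050, 0.090, 0.100, 0.140, 0.200, 0.230, 0.260, 0.270, 0.260, 0.180),
    bare_soil   = c(0.100, 0.130, 0.170, 0.200, 0.230, 0.250, 0.270, 0.280, 0.350, 0.300),
    wetland     = c(0.030, 0.070, 0.050, 0.090, 0.170, 0.200, 0.240, 0.250, 0.140, 0.070),
    water       = c(0.030, 0.040, 0.030, 0.020, 0.015, 0.012, 0.010, 0.008, 0.004, 0.003),
    burnt       = c(0.040, 0.050, 0.070, 0.080, 0.090, 0.100, 0.110, 0.110, 0.280, 0.300),
    cleared     = c(0.080, 0.110, 0.140, 0.170, 0.200, 0.220, 0.240, 0.250, 0.320, 0.270)
  )
  colnames(means) <- bands
  seasonal <- c(coniferous = 1, broadleaved = 1, sealed = 0, grassland = 1,
                cropland = 1, bare_soil = 0, wetland = 1, water = 0,
                burnt = 0, cleared = 0)
  amp <- matrix(seasonal_amplitude * seasonal[rownames(means)],
                nrow = nrow(means), ncol = length(bands))
  colnames(amp) <- paste0("amp_", bands)
  codes <- fc_classes()
  out <- tibble::as_tibble(cbind(as.data.frame(means), as.data.frame(amp)))
  out <- dplyr::bind_cols(
    tibble::tibble(class = rownames(means),
                   class_id = unname(codes[rownames(means)])),
    out
  )
  out$noise_sd <- noise_sd
  validate_signatures(out)
  out
}

# Check signature-library invariants; stops on violation.
validate_signatures <- function(sig) {
  bands <- fc_bands()
  stopifnot(all(c("class", "class_id", bands, paste0("amp_", bands),
                  "noise_sd") %in% names(sig)))
  m <- as.matrix(sig[, bands])
  a <- as.matrix(sig[, paste0("amp_", bands)])
  if (any(m + a > 1) || any(m - a < 0)) {
    abort_fc("signature means +/- seasonal amplitude must stay within [0, 1]",
             "fc_config_error")
  }
  if (any(sig$noise_sd < 0)) {
    abort_fc("noise_sd must be >= 0", "fc_config_error")
  }
  woody <- sig$class_id %in% fc_woody_classes()
  if (any(sig$class == "burnt")) {
    b <- sig[sig$class == "burnt", ]
    if (any(b$B8 >= sig$B8[woody]) || any(b$B12 <= sig$B12[woody])) {
      abort_fc("burn signature must have lower B8 and higher B12 than woody classes",
               "fc_config_error")
    }
  }
  invisible(sig)
}

# Row of the signature table for a class id, as a list of numeric vectors.
signature_for <- function(sig, class_id) {
  row <- sig[sig$class_id == class_id, ]
  if (nrow(row) != 1) {
    abort_fc(paste0("no signature for class id ", class_id), "fc_config_error")
  }
  list(mean = as.numeric(row[, fc_bands()]),
       amp = as.numeric(row[, paste0("amp_", fc_bands())]),
       noise_sd = row$noise_sd)
}
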