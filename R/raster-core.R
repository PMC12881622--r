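# Grid data model, raster file I/O, resampling, masking and compositing.

#' Construct a band stack
#'
#' A `band_stack` holds one acquisition: a rows x cols x 10 reflectance array
#' (third dimension named by [fc_bands()]), a logical validity mask, the pixel
#' size, an affine geotransform and the acquisition date. Reflectance is kept
#' as floating point in \[0, 1\]; invalid pixels carry `NA`.
#'
#' The geotransform follows the GDAL convention
#' `c(x_origin, dx, 0, y_origin, 0, -dy)`; pixel centres sit at half-pixel
#' offsets and rows index a half-open `[row, row + 1)` grid from the top edge.
#'
#' @param values rows x cols x 10 numeric array, third dim named by band.
#' @param valid Logical matrix (TRUE = usable); default all valid.
#' @param pixel_size Pixel edge length in metres (default 10).
#' @param transform Length-6 affine geotransform; default anchored at (0, 0).
#' @param date Acquisition date (`Date` or day-of-year integer with `year`).
#' @param year Acquisition year.
#' @return An object of class `band_stack`.
#' @export
band_stack <- function(values, valid = NULL, pixel_size = 10,
                       transform = NULL, date = NA, year = NA_integer_) {
  bands <- fc_bands()
  if (length(dim(values)) != 3 || dim(values)[3] != length(bands)) {
    abort_fc("values must be a rows x cols x 10 array", "fc_format_error")
  }
  if (is.null(dimnames(values)[[3]])) {
    dimnames(values)[[3]] <- bands
  }
  if (!identical(dimnames(values)[[3]], bands)) {
    abort_fc("third dimension must be named B2...B12 in canonical order",
             "fc_format_error")
  }
  if (is.null(valid)) {
    valid <- matrix(TRUE, nrow = dim(values)[1], ncol = dim(values)[2])
  }
  if (!identical(dim(valid), dim(values)[1:2])) {
    abort_fc("valid mask shape must match band shape", "fc_format_error")
  }
  if (is.null(transform)) {
    transform <- c(0, pixel_size, 0, 0, 0, -pixel_size)
  }
  values[!array(valid, dim(values))] <- NA_real_
  structure(
    list(values = values, valid = valid, pixel_size = pixel_size,
         transform = transform, date = date, year = year),
    class = "band_stack"
  )
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<band_stack> %d x %d px, %d bands, %.0f m, year %s, %.1f%% valid\n",
              d[1], d[2], d[3], x$pixel_size, x$year,
              100 * mean(x$valid)))
  invisible(x)
}

#' @export
dim.band_stack <- function(x) dim(x$values)[1:2]

#' Construct a categorical label raster
#'
#' @param labels Integer matrix of class codes; `NA` = nodata.
#' @param codes Named integer code table (default [fc_classes()]).
#' @param pixel_size Pixel size in metres.
#' @param transform Affine geotransform as in [band_stack()].
#' @return An object of class `label_raster`.
#' @export
label_raster <- function(labels, codes = fc_classes(), pixel_size = 10,
                         transform = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (is.null(transform)) {
    transform <- c(0, pixel_size, 0, 0, 0, -pixel_size)
  }
  structure(
    list(labels = labels, codes = codes, pixel_size = pixel_size,
         transform = transform),
    class = "label_raster"
  )
}

#' @export
dim.label_raster <- function(x) dim(x$labels)

#' @export
print.label_raster <- function(x, ...) {
  cat(sprintf("<label_raster> %d x %d px, %d classes present\n",
              nrow(x$labels), ncol(x$labels),
              length(unique(x$labels[!is.na(x$labels)]))))
  invisible(x)
}

# World coordinates of pixel centres for 1-based (row, col) indices.
pixel_centres <- function(transform, row, col) {
  list(x = transform[1] + (col - 0.5) * transform[2] + (row - 0.5) * transform[3],
       y = transform[4] + (col - 0.5) * transform[5] + (row - 0.5) * transform[6])
}

#' Write a band stack to a TIFF + JSON sidecar pair
#'
#' Values are stored as 32-bit float TIFF channels (ten bands plus a validity
#' channel); the sidecar `<path>.json` records band names, scale/offset,
#' pixel size, geotransform and date so a read round-trips the object. This
#' pair plays the role of a georeferenced multi-band raster file using only
#' the baseline TIFF container.
#'
#' @param stack A [band_stack()].
#' @param path Output path (conventionally `.tif`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(stack, path) {
  stopifnot(inherits(stack, "band_stack"))
  d <- dim(stack$values)
  vals <- stack$values
  vals[is.na(vals)] <- 0
  # one grayscale page per band plus a validity page
  pages <- lapply(seq_len(d[3]), function(b) matrix(vals[, , b], d[1], d[2]))
  pages[[d[3] + 1L]] <- matrix(as.numeric(stack$valid), d[1], d[2])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    driver = "forestchange-tiff-v1",
    bands = fc_bands(), scale = 1, offset = 0,
    pixel_size = stack$pixel_size, transform = as.numeric(stack$transform),
    date = as.character(stack$date), year = stack$year,
    mask_channel = d[3] + 1L
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a band stack written by [write_raster()]
#'
#' @param path Path to the TIFF file (sidecar `<path>.json` must exist).
#' @return A [band_stack()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) {
    abort_fc(paste0("no such file: ", path), "fc_format_error")
  }
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    abort_fc("missing JSON sidecar for raster", "fc_format_error")
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$bands) + 1L) {
    abort_fc(sprintf("expected %d pages (bands + mask), found %d",
                     length(meta$bands) + 1L, length(pages)),
             "fc_format_error")
  }
  if (!identical(as.character(meta$bands), fc_bands())) {
    abort_fc("band set in sidecar is not the canonical 10-band layout",
             "fc_format_error")
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1) {
    abort_fc("band pages disagree in shape", "fc_format_error")
  }
  d <- dim(pages[[1]])
  valid <- pages[[length(pages)]] > 0.5
  values <- array(NA_real_, dim = c(d[1], d[2], length(meta$bands)))
  for (b in seq_along(meta$bands)) {
    values[, , b] <- pages[[b]] * meta$scale + meta$offset
  }
  dimnames(values)[[3]] <- meta$bands
  date <- if (identical(meta$date, "NA")) NA else meta$date
  band_stack(values, valid = valid, pixel_size = meta$pixel_size,
             transform = meta$transform, date = date,
             year = as.integer(meta$year))
}

#' Bilinear resampling of a coarser band to a finer grid
#'
#' Resamples a grid whose pixel size is an integer multiple of the target
#' (e.g. 20 m -> 10 m) by bilinear interpolation between source pixel
#' centres, with edge pixels clamped to the nearest source centre. Both grids
#' share the same upper-left corner (pixel-centre alignment on the common
#' origin).
#'
#' @param band 2-D numeric matrix at the source resolution.
#' @param factor Integer refinement factor (source pixel / target pixel),
#'   e.g. 2 for 20 m -> 10 m.
#' @return Matrix with `factor` times the rows and columns of `band`.
#' @export
resample_bilinear <- function(band, factor = 2) {
  if (factor < 1 || factor != round(factor)) {
    abort_fc("refinement factor must be a positive integer", "fc_param_error")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(band)
  nr <- nrow(band); nc <- ncol(band)
  # Target pixel centres in source pixel coordinates (source centres at 0.5,
  # 1.5, ...): target centre j (1-based) sits at (j - 0.5) / factor.
  tr <- (seq_len(nr * factor) - 0.5) / factor
  tc <- (seq_len(nc * factor) - 0.5) / factor
  interp_axis <- function(t, n) {
    # fractional position between source centre floor(t - .5)+.5 and the next
    p <- pmin(pmax(t - 0.5, 0), n - 1)
    i0 <- pmin(floor(p) + 1, n)
    i1 <- pmin(i0 + 1, n)
    w <- p - (i0 - 1)
    list(i0 = i0, i1 = i1, w = w)
  }
  ax_r <- interp_axis(tr, nr)
  ax_c <- interp_axis(tc, nc)
  a <- band[ax_r$i0, ax_c$i0, drop = FALSE]
  b <- band[ax_r$i0, ax_c$i1, drop = FALSE]
  cc <- band[ax_r$i1, ax_c$i0, drop = FALSE]
  d <- band[ax_r$i1, ax_c$i1, drop = FALSE]
  wr <- matrix(ax_r$w, nrow = nr * factor, ncol = nc * factor)
  wc <- matrix(ax_c$w, nrow = nr * factor, ncol = nc * factor, byrow = TRUE)
  (1 - wr) * (1 - wc) * a + (1 - wr) * wc * b + wr * (1 - wc) * cc + wr * wc * d
}

#' Scene-classification codes treated as cloud shadow / cloud
#'
#' Mirrors the Level-2A scene classification values masked in practice:
#' 3 cloud shadow, 8 cloud medium probability, 9 cloud high probability,
#' 10 thin cirrus.
#' @return Integer vector of masked codes.
#' @export
fc_scl_masked_codes <- function() c(3L, 8L, 9L, 10L)

#' Mask clouds and shadows in a band stack
#'
#' Invalidates pixels whose cloud probability meets `threshold` or whose
#' scene-classification code is in the masked set. Reflectance values are
#' never altered, only the validity mask shrinks.
#'
#' @param stack A [band_stack()].
#' @param cloud_probability Numeric matrix in \[0, 1\] (or percent in
#'   \[0, 100\]; values > 1 are interpreted as percent).
#' @param scl Optional integer matrix of scene-classification codes.
#' @param threshold Cloud-probability cutoff; default 0.65.
#' @param masked_codes Codes to remove via `scl`; default
#'   [fc_scl_masked_codes()].
#' @return The stack with an updated validity mask.
#' @export
apply_cloud_mask <- function(stack, cloud_probability = NULL, scl = NULL,
                             threshold = 0.65,
                             masked_codes = fc_scl_masked_codes()) {
  stopifnot(inherits(stack, "band_stack"))
  bad <- matrix(FALSE, nrow = nrow(stack$valid), ncol = ncol(stack$valid))
  if (!is.null(cloud_probability)) {
    if (!identical(dim(cloud_probability), dim(stack$valid))) {
      abort_fc("cloud probability grid shape mismatch", "fc_param_error")
    }
    p <- cloud_probability
    if (max(p, na.rm = TRUE) > 1) p <- p / 100
    bad <- bad | (p >= threshold)
  }
  if (!is.null(scl)) {
    if (!identical(dim(scl), dim(stack$valid))) {
      abort_fc("scene-classification grid shape mismatch", "fc_param_error")
    }
    bad <- bad | (scl %in% masked_codes)
    dim(bad) <- dim(stack$valid)
  }
  band_stack(stack$values, valid = stack$valid & !bad,
             pixel_size = stack$pixel_size, transform = stack$transform,
             date = stack$date, year = stack$year)
}

#' Seasonal median composite of several acquisitions
#'
#' Builds an annual mosaic: per pixel and band, the median over all unmasked
#' observations whose day-of-year falls inside the season window (default
#' June--August, the vegetation-season window used for change mosaics). With
#' an even number of observations the median is the mean of the two middle
#' values. A pixel is valid iff at least one unmasked observation
#' contributed; the per-pixel contributing count is retained.
#'
#' @param acquisitions List of [band_stack()]s from one year; each must carry
#'   a `date` interpretable as day-of-year (integer) or `Date`.
#' @param window Integer vector `c(start_month, end_month)`; default
#'   `c(6, 8)`.
#' @return An `annual_mosaic`: a [band_stack()]-like object with an `n_obs`
#'   count matrix and `season_window` attribute.
#' @export
seasonal_median_mosaic <- function(acquisitions, window = c(6, 8)) {
  stopifnot(length(acquisitions) >= 1)
  doy_window <- month_window_to_doy(window)
  doys <- vapply(acquisitions, function(a) as_doy(a$date), numeric(1))
  keep <- doys >= doy_window[1] & doys <= doy_window[2]
  if (!any(keep)) {
    abort_fc("no acquisitions fall inside the season window", "fc_empty_error")
  }
  acq <- acquisitions[keep]
  d <- dim(acq[[1]]$values)
  vals <- array(NA_real_, dim = c(d[1] * d[2], d[3], length(acq)))
  for (i in seq_along(acq)) {
    v <- acq[[i]]$values
    v[!array(acq[[i]]$valid, dim = d)] <- NA_real_
    vals[, , i] <- v
  }
  n_obs <- matrix(rowSums(!is.na(vals[, 1, , drop = FALSE])), d[1], d[2])
  med <- array(NA_real_, dim = c(d[1] * d[2], d[3]))
  for (b in seq_len(d[3])) {
    med[, b] <- row_medians(vals[, b, , drop = TRUE])
  }
  values <- array(med, dim = d)
  dimnames(values)[[3]] <- fc_bands()
  out <- band_stack(values, valid = n_obs > 0,
                    pixel_size = acq[[1]]$pixel_size,
                    transform = acq[[1]]$transform,
                    year = acq[[1]]$year)
  out$n_obs <- n_obs
  out$season_window <- window
  class(out) <- c("annual_mosaic", class(out))
  out
}

# Fast row-wise median with NA removal for a matrix with few columns.
row_medians <- function(m) {
  if (is.null(dim(m))) return(m)
  k <- ncol(m)
  if (k == 1L) return(m[, 1])
  n_ok <- rowSums(!is.na(m))
  s <- t(apply(m, 1, sort, na.last = TRUE))
  lo <- s[cbind(seq_len(nrow(m)), pmax(ceiling(n_ok / 2), 1))]
  hi <- s[cbind(seq_len(nrow(m)), pmax(floor(n_ok / 2) + 1, 1))]
  out <- (lo + hi) / 2
  out[n_ok == 0] <- NA_real_
  out
}

# Day-of-year from a Date or an already-numeric day-of-year.
as_doy <- function(date) {
  if (inherits(date, "Date")) {
    as.integer(format(date, "%j"))
  } else if (is.numeric(date)) {
    as.numeric(date)
  } else if (is.character(date) && !is.na(suppressWarnings(as.Date(date)))) {
    as.integer(format(as.Date(date), "%j"))
  } else {
    abort_fc("acquisition date must be a Date or day-of-year", "fc_param_error")
  }
}

# First/last day-of-year of a month window (non-leap calendar).
month_window_to_doy <- function(window) {
  starts <- c(1, 32, 60, 91, 121, 152, 182, 213, 244, 274, 305, 335)
  ends <- c(31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334, 365)
  c(starts[window[1]], ends[window[2]])
}
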