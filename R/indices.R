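# Spectral indices, year-to-year differencing and the candidate-change mask.

#' Normalized Difference Vegetation Index
#'
#' Per-pixel `(B8 - B4) / (B8 + B4)` over a band stack or annual mosaic.
#' Pixels that are invalid in either band, or whose denominator is zero, are
#' nodata.
#'
#' @param mosaic A [band_stack()] or annual mosaic.
#' @return An `index_raster`: list with `values` matrix in \[-1, 1\],
#'   `index_name`, `year`, `pixel_size`, `transform`.
#' @export
ndvi <- function(mosaic) {
  normalized_difference(mosaic, "B8", "B4", "NDVI")
}

#' Normalised Burn Ratio
#'
#' Per-pixel `(B8 - B12) / (B8 + B12)`; drops sharply after fire because
#' burnt surfaces lose NIR reflectance and gain SWIR2 reflectance.
#'
#' @inheritParams ndvi
#' @return An `index_raster`.
#' @export
nbr <- function(mosaic) {
  normalized_difference(mosaic, "B8", "B12", "NBR")
}

normalized_difference <- function(mosaic, plus, minus, name) {
  stopifnot(inherits(mosaic, "band_stack"))
  bands <- dimnames(mosaic$values)[[3]]
  if (!all(c(plus, minus) %in% bands)) {
    abort_fc(sprintf("%s requires bands %s and %s", name, plus, minus),
             "fc_format_error")
  }
  d <- dim(mosaic$values)
  a <- matrix(mosaic$values[, , plus], d[1], d[2])
  b <- matrix(mosaic$values[, , minus], d[1], d[2])
  den <- a + b
  v <- (a - b) / den
  v[!mosaic$valid | is.na(den) | den == 0] <- NA_real_
  structure(
    list(values = v, index_name = name, year = mosaic$year,
         pixel_size = mosaic$pixel_size, transform = mosaic$transform),
    class = "index_raster"
  )
}

#' @export
print.index_raster <- function(x, ...) {
  cat(sprintf("<index_raster> %s, year %s, %d x %d px\n", x$index_name,
              x$year, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Year-to-year index difference
#'
#' Computes `index(t1) - index(t2)` so that vegetation loss between the two
#' years is positive. The mean and standard deviation of the difference are
#' recorded over the valid pixels of an optional evaluation domain (in
#' practice, the year-1 forest mask); they feed the candidate-change
#' threshold.
#'
#' @param index_t1,index_t2 Two `index_raster`s of the same index and grid,
#'   with `index_t1` the earlier year.
#' @param domain Optional logical matrix restricting the mean/SD computation.
#' @return A `difference_raster`: `values`, `index_name`, `years`, `mean`,
#'   `sd`, `domain`.
#' @export
index_difference <- function(index_t1, index_t2, domain = NULL) {
  stopifnot(inherits(index_t1, "index_raster"),
            inherits(index_t2, "index_raster"))
  if (!identical(index_t1$index_name, index_t2$index_name)) {
    abort_fc("cannot difference rasters of different indices",
             "fc_param_error")
  }
  if (!identical(dim(index_t1$values), dim(index_t2$values))) {
    abort_fc("index rasters are not co-registered", "fc_param_error")
  }
  v <- index_t1$values - index_t2$values
  if (is.null(domain)) {
    domain <- matrix(TRUE, nrow(v), ncol(v))
  }
  if (!identical(dim(domain), dim(v))) {
    abort_fc("domain mask shape mismatch", "fc_param_error")
  }
  in_dom <- v[domain & !is.na(v)]
  structure(
    list(values = v, index_name = index_t1$index_name,
         years = c(index_t1$year, index_t2$year),
         mean = if (length(in_dom)) mean(in_dom) else NA_real_,
         sd = if (length(in_dom) > 1) stats::sd(in_dom) else 0,
         domain = domain, pixel_size = index_t1$pixel_size,
         transform = index_t1$transform),
    class = "difference_raster"
  )
}

#' @export
print.difference_raster <- function(x, ...) {
  cat(sprintf("<difference_raster> d%s %s-%s, mean %.4f, sd %.4f\n",
              x$index_name, x$years[1], x$years[2], x$mean, x$sd))
  invisible(x)
}

#' Candidate forest-loss mask from index differences
#'
#' Flags pixels whose dNDVI / dNBR exceed `mean + k * SD` of the evaluation
#' domain (one-sided, on the loss side; differences are oriented so loss is
#' positive). With `rule = "union"` a pixel is a candidate if either index
#' exceeds its threshold; with `"intersection"`, both must. A zero-SD domain
#' yields an empty mask.
#'
#' @param dndvi,dnbr `difference_raster`s over the same grid and domain.
#' @param k Threshold multiplier; default 3.
#' @param rule `"union"` (default) or `"intersection"`.
#' @return A `candidate_mask`: logical `values` matrix plus the thresholds
#'   used.
#' @export
candidate_change_mask <- function(dndvi, dnbr, k = 3, rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  if (k <= 0) {
    abort_fc("threshold multiplier k must be positive", "fc_param_error")
  }
  stopifnot(inherits(dndvi, "difference_raster"),
            inherits(dnbr, "difference_raster"))
  if (!identical(dim(dndvi$values), dim(dnbr$values))) {
    abort_fc("difference rasters are not co-registered", "fc_param_error")
  }
  exceed <- function(d) {
    if (is.na(d$sd) || d$sd == 0) {
      matrix(FALSE, nrow(d$values), ncol(d$values))
    } else {
      out <- d$values > d$mean + k * d$sd
      out[is.na(out)] <- FALSE
      out & d$domain
    }
  }
  e1 <- exceed(dndvi)
  e2 <- exceed(dnbr)
  v <- if (rule == "union") e1 | e2 else e1 & e2
  structure(
    list(values = v, k = k, rule = rule,
         thresholds = c(dNDVI = dndvi$mean + k * dndvi$sd,
                        dNBR = dnbr$mean + k * dnbr$sd),
         pixel_size = dndvi$pixel_size, transform = dndvi$transform),
    class = "candidate_mask"
  )
}

#' @export
print.candidate_mask <- function(x, ...) {
  cat(sprintf("<candidate_mask> k=%g, rule=%s, %d flagged px\n",
              x$k, x$rule, sum(x$values)))
  invisible(x)
}
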