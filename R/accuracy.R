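# Error matrices, thematic accuracy metrics and stratified verification
# polygons with edge shrinking.

#' Build an error matrix from a map and reference labels
#'
#' Cross-tabulates map class (rows) against reference class (columns) over a
#' set of reference items. Reference items are points (`row`/`col` plus a
#' `ref_class` column) or 10 m x 10 m verification polygons from
#' [generate_verification_polygons()], which contribute their centre pixel.
#' Items falling off-grid or on NA map pixels are skipped and counted in
#' attribute `"n_skipped"`.
#'
#' @param map Integer matrix of map codes, or a `classified_map` /
#'   `change_map`.
#' @param reference Tibble with columns `row`, `col`, `ref_class`
#'   (codes from the map's class set).
#' @param classes Optional integer vector fixing class order; default the
#'   sorted union of observed codes.
#' @return An `error_matrix`: K x K count matrix with map classes in rows.
#' @export
error_matrix <- function(map, reference, classes = NULL) {
  vals <- if (is.matrix(map)) map else map$values
  on_grid <- reference$row >= 1 & reference$row <= nrow(vals) &
    reference$col >= 1 & reference$col <= ncol(vals)
  ref <- reference[on_grid, , drop = FALSE]
  map_class <- vals[cbind(ref$row, ref$col)]
  usable <- !is.na(map_class) & !is.na(ref$ref_class)
  if (is.null(classes)) {
    classes <- sort(unique(c(map_class[usable], ref$ref_class[usable])))
  }
  m <- table(factor(map_class[usable], levels = classes),
             factor(ref$ref_class[usable], levels = classes))
  m <- unclass(m)
  dimnames(m) <- list(map = as.character(classes),
                      reference = as.character(classes))
  structure(m, class = c("error_matrix", "matrix"),
            n_skipped = sum(!on_grid) + sum(!usable))
}

#' Error matrix directly from counts
#'
#' Convenience constructor for worked examples and published tables: wraps a
#' plain count matrix (map classes in rows, reference in columns) as an
#' `error_matrix`.
#'
#' @param counts Square numeric matrix of counts.
#' @param labels Optional class labels.
#' @return An `error_matrix`.
#' @export
as_error_matrix <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || any(counts < 0)) {
    abort_fc("error matrix must be square with non-negative counts",
             "fc_param_error")
  }
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(counts))) rownames(counts) else
      as.character(seq_len(nrow(counts)))
  }
  dimnames(counts) <- list(map = labels, reference = labels)
  structure(counts, class = c("error_matrix", "matrix"), n_skipped = 0L)
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("<error_matrix> (rows = map, cols = reference)\n")
  print(unclass(x))
  g <- glance.error_matrix(x)
  cat(sprintf("OA %.3f, Kappa %.3f, n = %d\n", g$overall_accuracy, g$kappa,
              g$n))
  invisible(x)
}

#' Thematic accuracy metrics from an error matrix
#'
#' Computes overall accuracy `trace/n`, per-class user's accuracy
#' (`diag/row sum`; 1 - commission error), producer's accuracy
#' (`diag/col sum`; 1 - omission error), per-class F1 as the harmonic mean
#' of UA and PA, and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with `p_e = sum(row_i * col_i) / n^2`.
#' Classes with an empty row or column report `NA` (undefined), never 0.
#'
#' @param matrix An `error_matrix`.
#' @return A list with `overall_accuracy`, `kappa`, `n` and a per-class
#'   tibble `by_class` (`class`, `users_accuracy`, `producers_accuracy`,
#'   `f1`).
#' @export
accuracy_metrics <- function(matrix) {
  m <- unclass(matrix)
  n <- sum(m)
  if (n <= 0) {
    abort_fc("error matrix has no counts", "fc_param_error")
  }
  rs <- rowSums(m); cs <- colSums(m); dg <- diag(m)
  ua <- ifelse(rs > 0, dg / rs, NA_real_)
  pa <- ifelse(cs > 0, dg / cs, NA_real_)
  f1 <- ifelse(!is.na(ua) & !is.na(pa) & (ua + pa) > 0,
               2 * ua * pa / (ua + pa), NA_real_)
  po <- sum(dg) / n
  pe <- sum(rs * cs) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  list(
    overall_accuracy = po, kappa = kappa, n = n,
    by_class = tibble::tibble(
      class = rownames(m), users_accuracy = unname(ua),
      producers_accuracy = unname(pa), f1 = unname(f1))
  )
}

#' Tidy and glance methods for forestchange results
#'
#' `tidy()` on an `error_matrix` returns the per-class accuracy table;
#' `glance()` the one-row summary (OA, kappa, n). `glance()` on an
#' `fc_model` returns its metadata and accuracies.
#'
#' @param x An `error_matrix` or `fc_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_forestchange
NULL

#' @rdname tidy_forestchange
#' @method tidy error_matrix
#' @export
tidy.error_matrix <- function(x, ...) {
  accuracy_metrics(x)$by_class
}

#' @rdname tidy_forestchange
#' @method glance error_matrix
#' @export
glance.error_matrix <- function(x, ...) {
  met <- accuracy_metrics(x)
  tibble::tibble(overall_accuracy = met$overall_accuracy, kappa = met$kappa,
                 n = met$n)
}

#' Stratified verification polygons with inward shrink
#'
#' Draws up to `per_class_n` pixel centres per map class after shrinking
#' each class region inward by `shrink_m` (edge-effect control), and turns
#' each centre into a pixel-sized square polygon. At 10 m resolution each
#' polygon is exactly one pixel, so its reference label is that pixel's
#' label in whatever truth is consulted. Deterministic given `seed`; classes
#' too small after the shrink yield fewer polygons with a warning.
#'
#' @param map Integer matrix of map codes, or a `classified_map` /
#'   `change_map`.
#' @param per_class_n Target polygons per class; default 100.
#' @param shrink_m Inward shrink distance in metres; default 10.
#' @param seed Integer RNG seed.
#' @param pixel_size Pixel size in metres (taken from the map object when
#'   available).
#' @param exclude Codes never sampled (default 0, the outside/invalid code,
#'   when present).
#' @return Tibble with `row`, `col`, `x`, `y`, `map_class` and polygon
#'   corner columns `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
generate_verification_polygons <- function(map, per_class_n = 100,
                                           shrink_m = 10, seed = 1L,
                                           pixel_size = NULL,
                                           exclude = 0L) {
  vals <- if (is.matrix(map)) map else map$values
  if (is.null(pixel_size)) {
    pixel_size <- if (is.matrix(map)) 10 else map$pixel_size
  }
  transform <- if (is.matrix(map)) c(0, pixel_size, 0, 0, 0, -pixel_size) else
    map$transform
  lr <- label_raster(vals, pixel_size = pixel_size, transform = transform)
  lr$labels[lr$labels %in% exclude] <- NA_integer_
  shrunk <- erode_class_regions(lr, buffer_m = shrink_m)
  set.seed(seed)
  out <- list()
  for (cl in sort(unique(shrunk$labels[!is.na(shrunk$labels)]))) {
    idx <- which(shrunk$labels == cl)
    if (length(idx) < per_class_n) {
      warning(sprintf("class %d: only %d candidate pixels after %g m shrink",
                      cl, length(idx), shrink_m))
    }
    take <- if (length(idx) <= per_class_n) idx else
      sample(idx, per_class_n)
    r <- ((take - 1) %% nrow(vals)) + 1L
    cc <- ((take - 1) %/% nrow(vals)) + 1L
    ctr <- pixel_centres(transform, r, cc)
    out[[as.character(cl)]] <- tibble::tibble(
      row = r, col = cc, x = ctr$x, y = ctr$y, map_class = cl,
      xmin = ctr$x - pixel_size / 2, xmax = ctr$x + pixel_size / 2,
      ymin = ctr$y - pixel_size / 2, ymax = ctr$y + pixel_size / 2)
  }
  dplyr::bind_rows(out)
}
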