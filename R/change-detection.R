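# Direct classification of year-pair forest change and the
# minimum-mapping-unit filter.

#' Construct a change map
#'
#' @param values Integer matrix coded per [fc_change_codes()].
#' @param years Length-2 integer vector (t1, t2).
#' @param pixel_size Pixel size in metres.
#' @param transform Affine geotransform.
#' @param mmu_applied Whether the minimum-mapping-unit filter has run.
#' @return A `change_map` object.
#' @export
change_map <- function(values, years = c(NA_integer_, NA_integer_),
                       pixel_size = 10, transform = NULL,
                       mmu_applied = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(transform)) {
    transform <- c(0, pixel_size, 0, 0, 0, -pixel_size)
  }
  structure(
    list(values = values, codes = fc_change_codes(), years = years,
         pixel_size = pixel_size, transform = transform,
         mmu_applied = mmu_applied),
    class = "change_map"
  )
}

#' @export
print.change_map <- function(x, ...) {
  tab <- table(factor(x$values, levels = x$codes, labels = names(x$codes)))
  cat(sprintf("<change_map> %s-%s%s: %s\n", x$years[1], x$years[2],
              if (x$mmu_applied) " (MMU filtered)" else "",
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
dim.change_map <- function(x) dim(x$values)

#' Stack change-classification features for a year pair
#'
#' Assembles the 22 per-pixel features the change classifier uses: the ten
#' bands of each annual mosaic (`t1_B2` ... `t2_B12`) plus `dNDVI` and
#' `dNBR`. A pixel is valid only where both mosaics and both differences are
#' valid and it lies inside the year-1 forest mask.
#'
#' @param mosaic_t1,mosaic_t2 Annual mosaics of consecutive years.
#' @param dndvi,dnbr `difference_raster`s for the same year pair.
#' @param forest_mask Logical matrix: the year-1 forest mask.
#' @return A `change_feature_stack`: `features` (n_pixels x 22 matrix),
#'   `valid` matrix, grid metadata, `years`.
#' @export
build_feature_stack <- function(mosaic_t1, mosaic_t2, dndvi, dnbr,
                                forest_mask) {
  d <- dim(mosaic_t1$values)
  if (!identical(d, dim(mosaic_t2$values))) {
    abort_fc("mosaics are not co-registered", "fc_param_error")
  }
  yrs <- c(mosaic_t1$year, mosaic_t2$year)
  if (!anyNA(yrs) && !anyNA(dndvi$years) &&
      !identical(as.integer(dndvi$years), as.integer(yrs))) {
    abort_fc("difference rasters do not match the mosaic year pair",
             "fc_param_error")
  }
  m1 <- matrix(mosaic_t1$values, nrow = d[1] * d[2])
  m2 <- matrix(mosaic_t2$values, nrow = d[1] * d[2])
  colnames(m1) <- paste0("t1_", fc_bands())
  colnames(m2) <- paste0("t2_", fc_bands())
  fm <- cbind(m1, m2, dNDVI = as.vector(dndvi$values),
              dNBR = as.vector(dnbr$values))
  valid <- mosaic_t1$valid & mosaic_t2$valid & !is.na(dndvi$values) &
    !is.na(dnbr$values) & forest_mask
  structure(
    list(features = fm, valid = valid, years = yrs,
         pixel_size = mosaic_t1$pixel_size, transform = mosaic_t1$transform),
    class = "change_feature_stack"
  )
}

#' Reference areas for change-model training
#'
#' Validates a tibble of reference polygons/rectangles with a change class
#' each. Areas outside the 4--400 ha range observed in practice trigger a
#' warning, not an error.
#'
#' @param areas Tibble with columns `class` (one of `"no_change"`,
#'   `"woody_to_nonwoody"`, `"burnt"`) and either rectangle bounds `row0`,
#'   `row1`, `col0`, `col1` or a `poly` list-column of world-coordinate
#'   vertex matrices.
#' @param pixel_size Pixel size in metres, for the area soft check.
#' @return The validated tibble with an `area_ha` column, class
#'   `reference_areas`.
#' @export
reference_areas <- function(areas, pixel_size = 10) {
  ok_classes <- setdiff(names(fc_change_codes()), "outside")
  if (!all(areas$class %in% ok_classes)) {
    abort_fc("reference-area class must be no_change, woody_to_nonwoody or burnt",
             "fc_param_error")
  }
  if (all(c("row0", "row1", "col0", "col1") %in% names(areas))) {
    npx <- (areas$row1 - areas$row0 + 1) * (areas$col1 - areas$col0 + 1)
    areas$area_ha <- npx * pixel_size^2 / 1e4
  } else if (!"area_ha" %in% names(areas)) {
    areas$area_ha <- NA_real_
  }
  soft <- !is.na(areas$area_ha) & (areas$area_ha < 4 | areas$area_ha > 400)
  if (any(soft)) {
    warning(sprintf("%d reference area(s) outside the typical 4-400 ha range",
                    sum(soft)))
  }
  class(areas) <- unique(c("reference_areas", class(areas)))
  areas
}

#' Sample stratified training points inside reference areas
#'
#' Draws up to `per_class_n` points per change class uniformly from the
#' valid in-stack pixels of that class's reference areas, then splits roles
#' 7:3 per class. All three change classes must be represented.
#'
#' @param areas A [reference_areas()] tibble.
#' @param stack A `change_feature_stack`.
#' @param per_class_n Target points per class; default 100.
#' @param ratio Train fraction; default 0.7.
#' @param seed Integer RNG seed.
#' @return A tibble with `row`, `col`, `change_class`, `role` and the 22
#'   feature columns; feature names in attribute `"feature_names"`.
#' @export
sample_reference_areas <- function(areas, stack, per_class_n = 100,
                                   ratio = 0.7, seed = 1L) {
  stopifnot(inherits(stack, "change_feature_stack"))
  need <- setdiff(names(fc_change_codes()), "outside")
  if (!all(need %in% areas$class)) {
    abort_fc("reference areas must cover all three change classes",
             "fc_sampling_error")
  }
  set.seed(seed)
  d <- dim(stack$valid)
  pts <- list()
  for (cl in need) {
    rows_cl <- areas[areas$class == cl, , drop = FALSE]
    pix <- integer(0)
    for (i in seq_len(nrow(rows_cl))) {
      a <- rows_cl[i, ]
      if ("poly" %in% names(a) && !is.null(a$poly[[1]])) {
        ctr <- pixel_centres(stack$transform,
                             rep(seq_len(d[1]), times = d[2]),
                             rep(seq_len(d[2]), each = d[1]))
        pix <- c(pix, which(points_in_polygon(ctr$x, ctr$y, a$poly[[1]])))
      } else {
        rr <- a$row0:a$row1
        cc <- a$col0:a$col1
        pix <- c(pix, as.vector(outer(rr, (cc - 1) * d[1], "+")))
      }
    }
    pix <- unique(pix[as.vector(stack$valid)[pix]])
    if (length(pix) == 0) {
      abort_fc(sprintf("no valid pixels in reference areas of class %s", cl),
               "fc_sampling_error")
    }
    take <- sample(pix, min(per_class_n, length(pix)))
    pts[[cl]] <- tibble::tibble(
      row = ((take - 1) %% d[1]) + 1L,
      col = ((take - 1) %/% d[1]) + 1L,
      pixel = take,
      change_class = cl
    )
  }
  out <- dplyr::bind_rows(pts)
  out$role <- "validation"
  for (cl in need) {
    idx <- which(out$change_class == cl)
    out$role[sample(idx, round(ratio * length(idx)))] <- "train"
  }
  fm <- stack$features[out$pixel, , drop = FALSE]
  out <- dplyr::bind_cols(out[, c("row", "col", "change_class", "role")],
                          tibble::as_tibble(fm))
  attr(out, "feature_names") <- colnames(stack$features)
  class(out) <- unique(c("sample_set", class(out)))
  out
}

#' Train the change-detection random forest
#'
#' 100-tree random forest over the 22 stacked features, fitted on the
#' training-role points. Thin wrapper over [train_model()] with
#' `task = "change"`.
#'
#' @param samples Output of [sample_reference_areas()].
#' @param n_trees Number of trees; default 100.
#' @param seed Integer RNG seed.
#' @param scene_id Training-scene identifier for the metadata.
#' @return An `fc_model` with task `"change"`.
#' @export
train_change_model <- function(samples, n_trees = 100, seed = 1L,
                               scene_id = NA_character_) {
  train_model(samples, task = "change", n_trees = n_trees, seed = seed,
              scene_id = scene_id)
}

#' Classify year-pair change over a feature stack
#'
#' Labels every valid in-mask pixel with one of the three change classes;
#' pixels outside the forest mask or invalid are code 0. Applying a model
#' fitted on another scene or period is the transfer regime (the model is
#' used unchanged).
#'
#' @param stack A `change_feature_stack`.
#' @param model An `fc_model` with task `"change"`.
#' @return A `change_map` (before MMU filtering).
#' @export
classify_changes <- function(stack, model) {
  stopifnot(inherits(stack, "change_feature_stack"),
            inherits(model, "fc_model"))
  if (model$task != "change") {
    abort_fc("model task must be 'change'", "fc_param_error")
  }
  d <- dim(stack$valid)
  out <- matrix(fc_change_codes()[["outside"]], d[1], d[2])
  target <- which(as.vector(stack$valid))
  if (length(target) > 0) {
    pred <- predict_fc(model, stack$features[target, , drop = FALSE])
    out[target] <- fc_change_codes()[pred]
  }
  change_map(out, years = stack$years, pixel_size = stack$pixel_size,
             transform = stack$transform)
}

#' Minimum-mapping-unit filter
#'
#' Removes unreliable small change patches: every 8-connected component of a
#' change class (woody-to-non-woody or burnt, each class labelled
#' separately) whose area is less than or equal to `min_area_m2` reverts to
#' "no change". At 10 m pixels the default 400 m2 removes components of up
#' to 4 pixels and keeps 5-pixel components. Idempotent.
#'
#' @param map A `change_map`.
#' @param min_area_m2 Area threshold; components with area `<=` this are
#'   removed. Default 400.
#' @param connectivity 8 (default) or 4.
#' @return The filtered `change_map` with `mmu_applied = TRUE`.
#' @export
mmu_filter <- function(map, min_area_m2 = 400, connectivity = 8) {
  stopifnot(inherits(map, "change_map"))
  px_area <- map$pixel_size^2
  max_px <- floor(min_area_m2 / px_area)
  v <- map$values
  for (cl in c(fc_change_codes()[["woody_to_nonwoody"]],
               fc_change_codes()[["burnt"]])) {
    comp <- label_components(v == cl, connectivity = connectivity)
    if (comp$n == 0) next
    sizes <- tabulate(comp$labels[comp$labels > 0], nbins = comp$n)
    small <- which(sizes <= max_px)
    if (length(small) > 0) {
      v[comp$labels %in% small] <- fc_change_codes()[["no_change"]]
    }
  }
  change_map(v, years = map$years, pixel_size = map$pixel_size,
             transform = map$transform, mmu_applied = TRUE)
}

# Connected-component labelling of a logical matrix (iterative BFS; 4- or
# 8-connectivity). Returns list(labels = integer matrix, n = count).
label_components <- function(mask, connectivity = 8) {
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                  dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else if (connectivity == 4) {
    offs <- cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  } else {
    abort_fc("connectivity must be 4 or 8", "fc_param_error")
  }
  n <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    n <- n + 1L
    queue <- integer(256)
    queue[1] <- start
    head_i <- 1L; tail_i <- 1L
    labels[start] <- n
    while (head_i <= tail_i) {
      cur <- queue[head_i]; head_i <- head_i + 1L
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs[k, 1]; c2 <- cc + offs[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        idx <- (c2 - 1L) * nr + r2
        if (mask[idx] && labels[idx] == 0L) {
          labels[idx] <- n
          tail_i <- tail_i + 1L
          if (tail_i > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[tail_i] <- idx
        }
      }
    }
  }
  list(labels = labels, n = n)
}
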