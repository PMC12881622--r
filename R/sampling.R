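# Rule-based stratified reference sampling with automatic spectral
# verification and train/validation splitting. Sample sets are tibbles so
# they chain with dplyr verbs; provenance travels in attributes.

#' Erode class regions away from their boundaries
#'
#' Morphological erosion per class: a pixel survives only if every pixel
#' within the buffer distance (Chebyshev neighbourhood) shares its class.
#' This implements the internal buffer that keeps reference points away from
#' class edges; the default 10 m equals one pixel at 10 m resolution.
#'
#' @param labels A [label_raster()].
#' @param buffer_m Buffer distance in metres; must be a non-negative multiple
#'   of the pixel size. Default 10.
#' @return A [label_raster()] with boundary pixels set to `NA`.
#' @export
erode_class_regions <- function(labels, buffer_m = 10) {
  stopifnot(inherits(labels, "label_raster"))
  if (buffer_m < 0) {
    abort_fc("buffer must be non-negative", "fc_param_error")
  }
  if (buffer_m %% labels$pixel_size != 0) {
    abort_fc("buffer must be a multiple of the pixel size", "fc_param_error")
  }
  px <- buffer_m / labels$pixel_size
  if (px == 0) return(labels)
  lab <- labels$labels
  nr <- nrow(lab); nc <- ncol(lab)
  keep <- !is.na(lab)
  # Neighbour must exist and match for every offset in the (2px+1)^2 window.
  for (dr in -px:px) {
    for (dc in -px:px) {
      if (dr == 0 && dc == 0) next
      shifted <- matrix(NA_integer_, nr, nc)
      r_src <- max(1, 1 + dr):min(nr, nr + dr)
      c_src <- max(1, 1 + dc):min(nc, nc + dc)
      shifted[r_src - dr, c_src - dc] <- lab[r_src, c_src]
      keep <- keep & !is.na(shifted) & (shifted == lab | is.na(lab))
    }
  }
  lab[!keep] <- NA_integer_
  label_raster(lab, codes = labels$codes, pixel_size = labels$pixel_size,
               transform = labels$transform)
}

#' Draw stratified random sample points under spacing and density rules
#'
#' Per class, draws up to `floor(density * class_area_km2)` points uniformly
#' from the (eroded) class pixels, rejecting any point closer than
#' `min_dist_m` to an already accepted point of any class. Deterministic
#' given `seed`. Classes with no eligible pixels are skipped with a warning.
#'
#' Each accepted point carries the three reference attributes: the land-cover
#' class, a forest/non-forest flag, and the dominant leaf type for woody
#' classes.
#'
#' @param eroded A [label_raster()], typically from [erode_class_regions()].
#' @param density Maximum points per square kilometre per class; default 2.
#' @param min_dist_m Minimum pairwise point distance in metres; default 20.
#' @param seed Integer RNG seed.
#' @param max_attempts_factor Rejection-sampling cap: give up on a class
#'   after `max_attempts_factor` times its target count; default 100.
#' @return A `sample_set` tibble with columns `row`, `col`, `x`, `y`,
#'   `class_id`, `class`, `forest`, `leaf_type`, `role`, `source`; rule
#'   provenance in attributes.
#' @export
draw_stratified_points <- function(eroded, density = 2, min_dist_m = 20,
                                   seed = 1L, max_attempts_factor = 100) {
  stopifnot(inherits(eroded, "label_raster"))
  if (density <= 0) {
    abort_fc("density must be positive", "fc_param_error")
  }
  set.seed(seed)
  lab <- eroded$labels
  px_km2 <- (eroded$pixel_size / 1000)^2
  classes <- sort(unique(lab[!is.na(lab)]))
  acc_xy <- matrix(numeric(0), ncol = 2)
  rows <- integer(0); cols <- integer(0); cls <- integer(0)
  for (cl in classes) {
    idx <- which(lab == cl)
    target <- floor(density * length(idx) * px_km2)
    if (target == 0 || length(idx) == 0) {
      warning(sprintf("class %d skipped: no room for points at density %g",
                      cl, density))
      next
    }
    cand <- sample(idx, length(idx))
    n_acc <- 0; attempts <- 0
    for (i in cand) {
      if (n_acc >= target || attempts >= max_attempts_factor * target) break
      attempts <- attempts + 1
      r <- ((i - 1) %% nrow(lab)) + 1
      cc <- ((i - 1) %/% nrow(lab)) + 1
      ctr <- pixel_centres(eroded$transform, r, cc)
      if (nrow(acc_xy) > 0) {
        d2 <- (acc_xy[, 1] - ctr$x)^2 + (acc_xy[, 2] - ctr$y)^2
        if (any(d2 < min_dist_m^2)) next
      }
      acc_xy <- rbind(acc_xy, c(ctr$x, ctr$y))
      rows <- c(rows, r); cols <- c(cols, cc); cls <- c(cls, cl)
      n_acc <- n_acc + 1
    }
  }
  codes <- fc_classes()
  name_of <- setNames(names(codes), codes)
  out <- tibble::tibble(
    row = rows, col = cols,
    x = if (length(rows)) acc_xy[, 1] else numeric(0),
    y = if (length(rows)) acc_xy[, 2] else numeric(0),
    class_id = cls,
    class = unname(name_of[as.character(cls)]),
    forest = cls %in% fc_woody_classes(),
    leaf_type = dplyr::case_when(
      cls == codes[["coniferous"]] ~ "coniferous",
      cls == codes[["broadleaved"]] ~ "broadleaved",
      TRUE ~ "none"
    ),
    role = NA_character_,
    source = "reference-raster"
  )
  attr(out, "rules") <- list(density = density, min_dist_m = min_dist_m,
                             seed = seed)
  class(out) <- c("sample_set", class(out))
  out
}

#' Drop spectrally atypical sample points (automatic verification)
#'
#' Robust per-class outlier screen standing in for manual checking of
#' reference points against imagery: for each class, the per-band median and
#' MAD of the candidate points' spectra are computed; a point is dropped when
#' it falls outside `median +/- 3 * 1.4826 * MAD` in more than
#' `max_flagged_bands` bands. Classes with fewer than `min_points` candidates
#' are passed through unverified (robust statistics would be meaningless).
#'
#' @param samples A `sample_set` tibble.
#' @param stack A [band_stack()] or annual mosaic supplying the spectra.
#' @param n_sigma Robust z cutoff; default 3.
#' @param max_flagged_bands A point is dropped if flagged in strictly more
#'   than this many bands; default 3.
#' @param min_points Minimum class size for verification; default 10.
#' @return The verified `sample_set` (subset of the input); per-class drop
#'   counts in attribute `"drop_report"`.
#' @export
verify_samples_spectral <- function(samples, stack, n_sigma = 3,
                                    max_flagged_bands = 3, min_points = 10) {
  stopifnot(inherits(stack, "band_stack"))
  if (nrow(samples) == 0) return(samples)
  spectra <- spectra_at(stack, samples$row, samples$col)
  keep <- rep(TRUE, nrow(samples))
  report <- list()
  for (cl in unique(samples$class_id)) {
    in_cl <- which(samples$class_id == cl)
    sp <- spectra[in_cl, , drop = FALSE]
    ok_rows <- stats::complete.cases(sp)
    if (sum(ok_rows) < min_points) {
      report[[as.character(cl)]] <- tibble::tibble(
        class_id = cl, n_in = length(in_cl), n_dropped = 0L, verified = FALSE)
      next
    }
    med <- apply(sp[ok_rows, , drop = FALSE], 2, median)
    s <- apply(sp[ok_rows, , drop = FALSE], 2, mad) # mad() includes 1.4826
    s[s == 0] <- 1e-12
    z <- abs(sweep(sweep(sp, 2, med), 2, s, "/"))
    flagged_bands <- rowSums(z > n_sigma, na.rm = TRUE)
    drop <- flagged_bands > max_flagged_bands
    drop[!ok_rows] <- TRUE # off-mask spectra cannot be verified; drop
    keep[in_cl[drop]] <- FALSE
    report[[as.character(cl)]] <- tibble::tibble(
      class_id = cl, n_in = length(in_cl), n_dropped = sum(drop),
      verified = TRUE)
  }
  out <- samples[keep, , drop = FALSE]
  attr(out, "rules") <- attr(samples, "rules")
  attr(out, "drop_report") <- dplyr::bind_rows(report)
  class(out) <- unique(c("sample_set", class(out)))
  out
}

# Band matrix (n x 10) at sample pixels; NA where invalid.
spectra_at <- function(stack, row, col) {
  d <- dim(stack$values)
  out <- matrix(NA_real_, length(row), d[3])
  colnames(out) <- dimnames(stack$values)[[3]]
  lin <- cbind(row, col)
  for (b in seq_len(d[3])) {
    out[, b] <- stack$values[, , b][lin]
  }
  out[!stack$valid[lin], ] <- NA_real_
  out
}

#' Stratified train/validation split
#'
#' Assigns roles per class: `round(ratio * n)` points to `"train"`, the rest
#' to `"validation"`, deterministically given `seed`. A single-point class
#' goes to train with a warning.
#'
#' @param samples A `sample_set` tibble.
#' @param ratio Training fraction in (0, 1); 0.6 mirrors the 60/40 model
#'   split, 0.7 the 7:3 change-detection split.
#' @param seed Integer RNG seed.
#' @return The `sample_set` with the `role` column filled.
#' @export
split_samples <- function(samples, ratio = 0.6, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) {
    abort_fc("train ratio must be in (0, 1)", "fc_param_error")
  }
  set.seed(seed)
  role <- rep("validation", nrow(samples))
  for (cl in unique(samples$class_id)) {
    idx <- which(samples$class_id == cl)
    if (length(idx) == 1) {
      warning(sprintf("class %s has a single point; assigned to train", cl))
      role[idx] <- "train"
      next
    }
    n_train <- round(ratio * length(idx))
    role[sample(idx, n_train)] <- "train"
  }
  samples$role <- role
  samples
}
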