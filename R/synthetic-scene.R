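# Synthetic multi-year scene generator with known truth.
#
# Scenes emulate the inputs of a regional forest-monitoring campaign:
# multi-date 10-band acquisitions with cloud gaps, a noisy global land-cover
# product standing in for the reference dataset, and injected change events
# (clearings and burns) between annual epochs.

#' Scene configuration
#'
#' Bundles every knob of the synthetic-scene generator. Defaults describe a
#' small but realistic study scene: 10 m pixels, five acquisitions per year
#' spread over the April--September vegetation season, 5% cloud cover per
#' acquisition, and a mock reference land-cover product degraded with 25%
#' label noise (the published global products report overall accuracies near
#' 75%).
#'
#' @param rows,cols Grid dimensions in pixels.
#' @param years Integer vector of scene years (>= 2 for change detection).
#' @param doys Acquisition days-of-year within each year. Default
#'   `c(105, 135, 166, 196, 227)` (mid-April to mid-August).
#' @param pixel_size Pixel size in metres; default 10.
#' @param seed Integer RNG seed; the same config + seed reproduces the scene
#'   bit for bit.
#' @param n_blobs Number of Voronoi seed patches in the class layout.
#' @param class_weights Named numeric sampling weights over the eight mapped
#'   classes for patch assignment.
#' @param label_noise_rate Fraction of mock-reference pixels relabelled;
#'   default 0.25.
#' @param cloud_fraction Approximate fraction of pixels cloud-masked per
#'   acquisition; default 0.05.
#' @param events Tibble of change events with columns `kind`
#'   (`"clearing"` or `"burn"`), `year`, and rectangle bounds `row0`, `row1`,
#'   `col0`, `col1` (inclusive, 1-based) or a `poly` list-column of x/y
#'   vertex matrices in world coordinates. Default none.
#' @return A `scene_config` list.
#' @export
scene_config <- function(rows = 128, cols = 128, years = c(2020, 2021),
                         doys = c(105, 135, 166, 196, 227),
                         pixel_size = 10, seed = 1L, n_blobs = 30,
                         class_weights = NULL, label_noise_rate = 0.25,
                         cloud_fraction = 0.05, events = NULL) {
  if (is.null(class_weights)) {
    class_weights <- c(coniferous = 0.25, broadleaved = 0.25, sealed = 0.04,
                       grassland = 0.10, cropland = 0.20, bare_soil = 0.05,
                       wetland = 0.06, water = 0.05)
  }
  if (label_noise_rate < 0 || label_noise_rate >= 1) {
    abort_fc("label_noise_rate must be in [0, 1)", "fc_param_error")
  }
  if (cloud_fraction < 0 || cloud_fraction >= 1) {
    abort_fc("cloud_fraction must be in [0, 1)", "fc_param_error")
  }
  if (is.null(events)) {
    events <- tibble::tibble(kind = character(), year = integer(),
                             row0 = integer(), row1 = integer(),
                             col0 = integer(), col1 = integer())
  }
  if (nrow(events) > 0) {
    if (!all(events$kind %in% c("clearing", "burn"))) {
      abort_fc("event kind must be 'clearing' or 'burn'", "fc_config_error")
    }
    if (all(c("row0", "row1", "col0", "col1") %in% names(events))) {
      inside <- events$row0 >= 1 & events$row1 <= rows &
        events$col0 >= 1 & events$col1 <= cols & events$row0 <= events$row1 &
        events$col0 <= events$col1
      if (!all(inside)) {
        abort_fc("change-event rectangles must lie inside the grid",
                 "fc_config_error")
      }
    }
  }
  structure(
    list(rows = rows, cols = cols, years = sort(unique(years)), doys = doys,
         pixel_size = pixel_size, seed = as.integer(seed), n_blobs = n_blobs,
         class_weights = class_weights, label_noise_rate = label_noise_rate,
         cloud_fraction = cloud_fraction, events = events),
    class = "scene_config"
  )
}

#' Generate a synthetic multi-year scene with truth
#'
#' Builds a Voronoi-patch class layout, then simulates every configured
#' acquisition as signature mean + per-band seasonal sinusoid + Gaussian
#' noise, with rectangular cloud masks. Change events replace the underlying
#' signature (clearing -> cleared surface, burn -> burnt surface) from the
#' event year onward. Returns both the acquisitions and the full truth:
#' per-year labels, per-year-pair change maps, and the mock reference product
#' (year-1 labels degraded by label noise).
#'
#' @param config A [scene_config()].
#' @param signatures Signature library; default [default_signatures()].
#' @return A list with elements `acquisitions` (list per year of
#'   [band_stack()] lists), `truth` (list: `labels` per year as
#'   [label_raster()], `change` per year pair as `change_map`,
#'   `mock_reference` [label_raster()]), and `config`.
#' @export
make_scene <- function(config, signatures = default_signatures()) {
  stopifnot(inherits(config, "scene_config"))
  if (length(config$years) < 2) {
    abort_fc("at least two years must be configured", "fc_config_error")
  }
  validate_signatures(signatures)
  set.seed(config$seed)
  layout <- voronoi_layout(config, signatures)

  # Per-year truth labels: events flip woody pixels to burnt/cleared codes
  # from the event year onward.
  labels_by_year <- list()
  current <- layout
  for (y in config$years) {
    ev <- config$events[config$events$year == y, , drop = FALSE]
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        px <- event_pixels(ev[i, ], config)
        prior <- current[px]
        if (!all(prior %in% fc_woody_classes())) {
          abort_fc("change event overlaps non-woody truth; impossible truth map",
                   "fc_config_error")
        }
        current[px] <- if (ev$kind[i] == "burn") fc_classes()[["burnt"]] else
          fc_classes()[["cleared"]]
      }
    }
    labels_by_year[[as.character(y)]] <-
      label_raster(current, pixel_size = config$pixel_size)
  }

  # Acquisitions: signature mean + seasonal term + noise, per year and date.
  acquisitions <- list()
  sig_means <- as.matrix(signatures[, fc_bands()])
  sig_amp <- as.matrix(signatures[, paste0("amp_", fc_bands())])
  id_index <- match(seq_len(max(signatures$class_id)), signatures$class_id)
  for (y in config$years) {
    lab <- labels_by_year[[as.character(y)]]$labels
    idx <- id_index[lab]
    year_acq <- list()
    for (doy in config$doys) {
      s <- sin(2 * pi * (doy - 81) / 365)
      base <- sig_means[idx, , drop = FALSE] +
        sig_amp[idx, , drop = FALSE] * s
      noise_sd <- signatures$noise_sd[idx]
      noise <- matrix(rnorm(length(base), sd = rep(noise_sd, ncol(base))),
                      nrow = nrow(base))
      vals <- pmin(pmax(base + noise, 0), 1)
      arr <- array(vals, dim = c(config$rows, config$cols, length(fc_bands())))
      dimnames(arr)[[3]] <- fc_bands()
      valid <- !cloud_rectangles(config$rows, config$cols,
                                 config$cloud_fraction)
      year_acq[[length(year_acq) + 1]] <-
        band_stack(arr, valid = valid, pixel_size = config$pixel_size,
                   date = doy, year = y)
    }
    acquisitions[[as.character(y)]] <- year_acq
  }

  # Truth change per consecutive year pair.
  change <- list()
  yrs <- config$years
  for (i in seq_len(length(yrs) - 1)) {
    l1 <- labels_by_year[[as.character(yrs[i])]]$labels
    l2 <- labels_by_year[[as.character(yrs[i + 1])]]$labels
    cm <- matrix(fc_change_codes()[["outside"]], config$rows, config$cols)
    woody1 <- matrix(l1 %in% fc_woody_classes(), config$rows, config$cols)
    cm[woody1] <- fc_change_codes()[["no_change"]]
    cm[woody1 & l2 == fc_classes()[["cleared"]]] <-
      fc_change_codes()[["woody_to_nonwoody"]]
    cm[woody1 & l2 == fc_classes()[["burnt"]]] <- fc_change_codes()[["burnt"]]
    change[[paste(yrs[i], yrs[i + 1], sep = "_")]] <-
      change_map(cm, years = c(yrs[i], yrs[i + 1]),
                 pixel_size = config$pixel_size)
  }

  mock_reference <- apply_label_noise(labels_by_year[[1]],
                                      rate = config$label_noise_rate,
                                      seed = config$seed + 1L)

  list(acquisitions = acquisitions,
       truth = list(labels = labels_by_year, change = change,
                    mock_reference = mock_reference),
       config = config)
}

# Voronoi-patch class layout. Seeds get one patch per weighted class first so
# every configured class is present, then weighted random classes.
voronoi_layout <- function(config, signatures) {
  w <- config$class_weights[config$class_weights > 0]
  ids <- fc_classes()[names(w)]
  if (anyNA(ids)) {
    abort_fc("class layout names a class with no signature", "fc_config_error")
  }
  if (!all(ids %in% signatures$class_id)) {
    abort_fc("class layout names a class with no signature", "fc_config_error")
  }
  n <- max(config$n_blobs, length(ids))
  sr <- runif(n, 0.5, config$rows + 0.5)
  sc <- runif(n, 0.5, config$cols + 0.5)
  cls <- c(ids, sample(ids, n - length(ids), replace = TRUE, prob = w))
  px <- cbind(rep(seq_len(config$rows), times = config$cols),
              rep(seq_len(config$cols), each = config$rows))
  d2 <- cross_dist2(px, cbind(sr, sc))
  nearest <- max.col(-d2, ties.method = "first")
  matrix(as.integer(cls[nearest]), config$rows, config$cols)
}

# Random rectangular cloud mask covering about `fraction` of pixels.
cloud_rectangles <- function(rows, cols, fraction) {
  cloud <- matrix(FALSE, rows, cols)
  if (fraction <= 0) return(cloud)
  target <- fraction * rows * cols
  guard <- 0
  while (sum(cloud) < target && guard < 100) {
    h <- sample.int(max(2, rows %/% 4), 1) + 1
    w <- sample.int(max(2, cols %/% 4), 1) + 1
    r0 <- sample.int(rows - h + 1, 1)
    c0 <- sample.int(cols - w + 1, 1)
    cloud[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
    guard <- guard + 1
  }
  cloud
}

# Linear pixel indices covered by one event row (rectangle or polygon).
event_pixels <- function(ev, config) {
  if ("poly" %in% names(ev) && !is.null(ev$poly[[1]])) {
    ctr <- pixel_centres(c(0, config$pixel_size, 0, 0, 0, -config$pixel_size),
                         row = rep(seq_len(config$rows), times = config$cols),
                         col = rep(seq_len(config$cols), each = config$rows))
    which(points_in_polygon(ctr$x, ctr$y, ev$poly[[1]]))
  } else {
    rr <- ev$row0:ev$row1
    cc <- ev$col0:ev$col1
    as.vector(outer(rr, (cc - 1) * config$rows, "+"))
  }
}

#' Propose change-event rectangles inside woody truth
#'
#' Utility for building valid scene configurations: finds rectangles that lie
#' entirely inside the woody classes of a truth label raster, suitable as
#' clearing/burn events.
#'
#' @param labels A [label_raster()] (typically year-1 truth).
#' @param n_events Number of rectangles wanted.
#' @param size Edge length of each square event in pixels; default 8.
#' @param seed RNG seed.
#' @param max_tries Sampling attempts before giving up; default 2000.
#' @return Tibble with columns `row0`, `row1`, `col0`, `col1`; may hold fewer
#'   than `n_events` rows if woody patches are scarce (with a warning).
#' @export
propose_change_events <- function(labels, n_events, size = 8, seed = 1L,
                                  max_tries = 2000) {
  stopifnot(inherits(labels, "label_raster"))
  set.seed(seed)
  woody <- labels$labels %in% fc_woody_classes()
  dim(woody) <- dim(labels$labels)
  out <- list()
  taken <- matrix(FALSE, nrow(woody), ncol(woody))
  tries <- 0
  while (length(out) < n_events && tries < max_tries) {
    tries <- tries + 1
    r0 <- sample.int(nrow(woody) - size + 1, 1)
    c0 <- sample.int(ncol(woody) - size + 1, 1)
    block_w <- woody[r0:(r0 + size - 1), c0:(c0 + size - 1)]
    block_t <- taken[r0:(r0 + size - 1), c0:(c0 + size - 1)]
    if (all(block_w) && !any(block_t)) {
      taken[r0:(r0 + size - 1), c0:(c0 + size - 1)] <- TRUE
      out[[length(out) + 1]] <- tibble::tibble(
        row0 = r0, row1 = r0 + size - 1L, col0 = c0, col1 = c0 + size - 1L)
    }
  }
  if (length(out) < n_events) {
    warning(sprintf("placed only %d of %d events inside woody truth",
                    length(out), n_events))
  }
  dplyr::bind_rows(out)
}

#' Relabel a fraction of pixels to emulate reference-product error
#'
#' Degrades a label raster the way real global land-cover products err:
#' in small misclassified patches rather than isolated pixels. Exactly
#' `round(rate * n_valid)` valid pixels end up carrying a different valid
#' class; patches are square neighbourhoods of radius `patch_radius` around
#' random seeds (the last patch is truncated to hit the count exactly), each
#' assigned one random other class present in the raster, with per-pixel
#' fix-ups so every noised pixel really differs from the truth.
#' Deterministic given `seed`. `patch_radius = 0` gives independent
#' single-pixel flips.
#'
#' @param labels A [label_raster()].
#' @param rate Fraction in \[0, 1).
#' @param seed Integer RNG seed.
#' @param patch_radius Chebyshev radius of each noise patch in pixels.
#'   The default 4 gives 9 x 9 patches, about the footprint of one pixel of
#'   a 100 m land-cover product on a 10 m grid.
#' @return A new [label_raster()] of the same shape.
#' @export
apply_label_noise <- function(labels, rate, seed = 1L, patch_radius = 4) {
  stopifnot(inherits(labels, "label_raster"))
  if (rate < 0 || rate >= 1) {
    abort_fc("label noise rate must be in [0, 1)", "fc_param_error")
  }
  lab <- labels$labels
  nr <- nrow(lab); nc <- ncol(lab)
  valid_idx <- which(!is.na(lab))
  n_noise <- round(rate * length(valid_idx))
  if (n_noise == 0) return(labels)
  present <- sort(unique(lab[valid_idx]))
  if (length(present) < 2) {
    abort_fc("cannot apply label noise with a single class present",
             "fc_param_error")
  }
  set.seed(seed)
  flipped <- logical(length(lab))
  n_done <- 0
  seeds <- sample(valid_idx, length(valid_idx))
  si <- 0
  while (n_done < n_noise && si < length(seeds)) {
    si <- si + 1
    s <- seeds[si]
    r0 <- ((s - 1) %% nr) + 1
    c0 <- ((s - 1) %/% nr) + 1
    rr <- max(1, r0 - patch_radius):min(nr, r0 + patch_radius)
    cc <- max(1, c0 - patch_radius):min(nc, c0 + patch_radius)
    patch <- as.vector(outer(rr, (cc - 1) * nr, "+"))
    patch <- patch[!flipped[patch] & !is.na(lab[patch])]
    if (length(patch) == 0) next
    if (n_done + length(patch) > n_noise) {
      patch <- patch[seq_len(n_noise - n_done)]
    }
    wrong <- sample(present, 1)
    new_lab <- rep(wrong, length(patch))
    same <- lab[patch] == wrong
    if (any(same)) {
      # per-pixel fix-up: pick the next other class so the pixel differs
      alt <- vapply(lab[patch][same],
                    function(o) present[present != o][1], present[1])
      new_lab[same] <- alt
    }
    lab[patch] <- new_lab
    flipped[patch] <- TRUE
    n_done <- n_done + length(patch)
  }
  label_raster(lab, codes = labels$codes, pixel_size = labels$pixel_size,
               transform = labels$transform)
}
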