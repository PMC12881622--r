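# Shared fixtures and independent oracles. Oracles deliberately use different
# algorithms from the package code paths they check.

# Small synthetic scene with optional injected events in the second year.
make_test_scene <- function(rows = 64, cols = 64, seed = 101,
                            n_clearing = 1, n_burn = 1, event_size = 6,
                            noise_sd = 0.008, seasonal_amplitude = 0.01,
                            cloud_fraction = 0.05, label_noise_rate = 0.25,
                            doys = c(105, 135, 166, 196, 227)) {
  sig <- default_signatures(noise_sd = noise_sd,
                            seasonal_amplitude = seasonal_amplitude)
  base <- scene_config(rows = rows, cols = cols, seed = seed, doys = doys,
                       cloud_fraction = cloud_fraction,
                       label_noise_rate = label_noise_rate)
  sc0 <- make_scene(base, sig)
  n_events <- n_clearing + n_burn
  if (n_events == 0) return(sc0)
  ev <- propose_change_events(sc0$truth$labels[[1]], n_events = n_events,
                              size = event_size, seed = seed + 1)
  ev$kind <- rep(c("clearing", "burn"), c(n_clearing, n_burn))[seq_len(nrow(ev))]
  ev$year <- sc0$config$years[2]
  cfg <- scene_config(rows = rows, cols = cols, seed = seed, doys = doys,
                      cloud_fraction = cloud_fraction,
                      label_noise_rate = label_noise_rate, events = ev)
  make_scene(cfg, sig)
}

# A single noise-free, cloud-free band stack where every pixel carries the
# signature mean of the class in `labels`.
stack_from_labels <- function(labels, sig = default_signatures(0, 0),
                              doy = 196, year = 2020) {
  bands <- fc_bands()
  idx <- match(as.vector(labels), sig$class_id)
  vals <- as.matrix(sig[, bands])[idx, , drop = FALSE]
  arr <- array(vals, dim = c(nrow(labels), ncol(labels), length(bands)))
  dimnames(arr)[[3]] <- bands
  band_stack(arr, date = doy, year = year)
}

# Independent connected-component labelling: recursive-style DFS with an
# explicit stack, structured differently from the package's BFS.
oracle_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  comp <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!isTRUE(mask[r, cc]) || lab[r, cc] != 0L) next
      comp <- comp + 1L
      stack <- list(c(r, cc))
      lab[r, cc] <- comp
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(nb))) {
          r2 <- p[1] + nb$dr[k]; c2 <- p[2] + nb$dc[k]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              isTRUE(mask[r2, c2]) && lab[r2, c2] == 0L) {
            lab[r2, c2] <- comp
            stack[[length(stack) + 1]] <- c(r2, c2)
          }
        }
      }
    }
  }
  list(labels = lab, n = comp)
}

# Brute-force bilinear interpolation at one target centre (source pixel
# centres at 0.5, 1.5, ... in source pixel coordinates), clamped at edges.
oracle_bilinear_point <- function(band, tr, tc) {
  n <- nrow(band); m <- ncol(band)
  pr <- min(max(tr - 0.5, 0), n - 1)
  pc <- min(max(tc - 0.5, 0), m - 1)
  r0 <- min(floor(pr) + 1, n); r1 <- min(r0 + 1, n)
  c0 <- min(floor(pc) + 1, m); c1 <- min(c0 + 1, m)
  wr <- pr - (r0 - 1); wc <- pc - (c0 - 1)
  (1 - wr) * (1 - wc) * band[r0, c0] + (1 - wr) * wc * band[r0, c1] +
    wr * (1 - wc) * band[r1, c0] + wr * wc * band[r1, c1]
}

# Accuracy metrics recomputed from raw (map, reference) label pairs, not
# from the matrix: brute-force pair counting.
oracle_metrics_from_pairs <- function(map_lab, ref_lab) {
  stopifnot(length(map_lab) == length(ref_lab))
  n <- length(map_lab)
  classes <- sort(unique(c(map_lab, ref_lab)))
  oa <- mean(map_lab == ref_lab)
  pe <- 0
  ua <- pa <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    p_map <- mean(map_lab == cl)
    p_ref <- mean(ref_lab == cl)
    pe <- pe + p_map * p_ref
    ua[as.character(cl)] <- if (sum(map_lab == cl) > 0)
      sum(map_lab == cl & ref_lab == cl) / sum(map_lab == cl) else NA
    pa[as.character(cl)] <- if (sum(ref_lab == cl) > 0)
      sum(map_lab == cl & ref_lab == cl) / sum(ref_lab == cl) else NA
  }
  list(oa = oa, kappa = (oa - pe) / (1 - pe), ua = ua, pa = pa)
}

# Fraction of truth change pixels mapped as the *other* change class.
burn_clear_confusion <- function(map, truth) {
  codes <- fc_change_codes()
  ch <- truth$values %in% c(codes[["woody_to_nonwoody"]], codes[["burnt"]])
  m <- map$values[ch]; t <- truth$values[ch]
  swapped <- (m == codes[["woody_to_nonwoody"]] & t == codes[["burnt"]]) |
    (m == codes[["burnt"]] & t == codes[["woody_to_nonwoody"]])
  mean(swapped)
}
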