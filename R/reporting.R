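# Pixel-count-to-area conversion and the regional loss report.

#' Convert a pixel count to hectares
#'
#' @param pixel_count Non-negative pixel count (vectorised).
#' @param pixel_size_m Pixel edge length in metres; default 10 (so 100
#'   pixels = 1 ha and 4 pixels = 0.04 ha = 400 m2).
#' @return Area in hectares.
#' @export
area_ha <- function(pixel_count, pixel_size_m = 10) {
  if (any(pixel_count < 0)) {
    abort_fc("pixel count must be non-negative", "fc_param_error")
  }
  pixel_count * pixel_size_m^2 / 1e4
}

#' Read the bundled regional loss table
#'
#' Loads the per-region forest-cover and loss table shipped with the package
#' (region area, forest cover, leaf-type areas, and woody-conversion / burnt
#' areas for the 2020--2021 and 2021--2022 periods, all in hectares) as a
#' tibble. It is the worked-example input for [aggregate_report()].
#'
#' @return A tibble with one row per region.
#' @export
regional_loss_table <- function() {
  path <- system.file("extdata", "regional_loss_table.csv",
                      package = "forestchange", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

#' Regional and pooled forest-loss report
#'
#' Takes a per-region table of forest areas and per-period loss areas (the
#' shape of [regional_loss_table()], or one assembled from change maps via
#' [report_from_maps()]) and derives the report statistics: per-region and
#' pooled totals per period, per-class shares of total loss, loss as a
#' percentage of forest area, forest cover and leaf-type percentages, and
#' the period-over-period ratio. Percentages are rounded half-up at the
#' printed precision (whole percent for shares, 0.1 for cover fractions);
#' unrounded values are kept in `*_raw` columns. Shares of a zero total are
#' reported as `NA`.
#'
#' @param losses Tibble with columns `region`, `region_area_ha`,
#'   `forest_ha`, `coniferous_ha`, `broadleaved_ha`, and per period `p`
#'   (`"2020_2021"`, `"2021_2022"`, ...) `woody_<p>` and `burnt_<p>`.
#' @return A list of tibbles: `regions` (per region x period),
#'   `pooled` (per period), `cover` (per region), each carrying rounded and
#'   raw columns.
#' @export
aggregate_report <- function(losses) {
  woody_cols <- grep("^woody_", names(losses), value = TRUE)
  periods <- sub("^woody_", "", woody_cols)
  if (length(periods) == 0) {
    abort_fc("no woody_<period> columns found", "fc_param_error")
  }
  per_region <- list()
  for (p in periods) {
    w <- losses[[paste0("woody_", p)]]
    b <- losses[[paste0("burnt_", p)]]
    tot <- w + b
    per_region[[p]] <- tibble::tibble(
      region = losses$region, period = p,
      woody_ha = w, burnt_ha = b, total_ha = tot,
      woody_share_raw = ifelse(tot > 0, 100 * w / tot, NA_real_),
      burnt_share_raw = ifelse(tot > 0, 100 * b / tot, NA_real_),
      loss_pct_of_forest_raw = ifelse(losses$forest_ha > 0,
                                      100 * tot / losses$forest_ha, NA_real_)
    )
  }
  regions <- dplyr::bind_rows(per_region) %>%
    dplyr::mutate(
      woody_share = round_half_up(.data$woody_share_raw, 0),
      burnt_share = round_half_up(.data$burnt_share_raw, 0),
      loss_pct_of_forest = round_half_up(.data$loss_pct_of_forest_raw, 1)
    )
  pooled <- regions %>%
    dplyr::group_by(.data$period) %>%
    dplyr::summarise(
      woody_ha = sum(.data$woody_ha), burnt_ha = sum(.data$burnt_ha),
      total_ha = sum(.data$total_ha), .groups = "drop"
    ) %>%
    dplyr::mutate(
      woody_share_raw = ifelse(.data$total_ha > 0,
                               100 * .data$woody_ha / .data$total_ha,
                               NA_real_),
      burnt_share_raw = ifelse(.data$total_ha > 0,
                               100 * .data$burnt_ha / .data$total_ha,
                               NA_real_),
      woody_share = round_half_up(.data$woody_share_raw, 0),
      burnt_share = round_half_up(.data$burnt_share_raw, 0),
      ratio_to_previous = .data$total_ha / dplyr::lag(.data$total_ha)
    )
  cover <- tibble::tibble(
    region = losses$region,
    forest_ha = losses$forest_ha,
    forest_cover_pct_raw = 100 * losses$forest_ha / losses$region_area_ha,
    coniferous_pct_raw = ifelse(!is.na(losses$coniferous_ha),
                                100 * losses$coniferous_ha / losses$forest_ha,
                                NA_real_),
    broadleaved_pct_raw = ifelse(!is.na(losses$broadleaved_ha),
                                 100 * losses$broadleaved_ha / losses$forest_ha,
                                 NA_real_)
  ) %>%
    dplyr::mutate(
      forest_cover_pct = round_half_up(.data$forest_cover_pct_raw, 1),
      coniferous_pct = round_half_up(.data$coniferous_pct_raw, 1),
      broadleaved_pct = round_half_up(.data$broadleaved_pct_raw, 1)
    )
  list(regions = regions, pooled = pooled, cover = cover)
}

#' Assemble a loss table from classified and change maps
#'
#' Counts pixels per class in a forest mask, leaf-type map and per-period
#' change maps (after MMU filtering) and converts them to hectares, yielding
#' a table in the shape [aggregate_report()] consumes.
#'
#' @param region Region identifier.
#' @param fmask Logical forest-mask matrix ([forest_mask()]).
#' @param leaf_map Optional `classified_map` from the leaf-type task.
#' @param change_maps Named list of `change_map`s; names become periods
#'   (e.g. `"2020_2021"`).
#' @param pixel_size_m Pixel size in metres; default 10.
#' @return One-row tibble matching the [aggregate_report()] input contract.
#' @export
report_from_maps <- function(region, fmask, leaf_map = NULL,
                             change_maps = list(), pixel_size_m = 10) {
  row <- tibble::tibble(
    region = region,
    region_area_ha = area_ha(length(fmask), pixel_size_m),
    forest_ha = area_ha(sum(fmask), pixel_size_m),
    coniferous_ha = NA_real_, broadleaved_ha = NA_real_
  )
  if (!is.null(leaf_map)) {
    row$coniferous_ha <- area_ha(
      sum(leaf_map$values == leaf_map$codes[["coniferous"]], na.rm = TRUE),
      pixel_size_m)
    row$broadleaved_ha <- area_ha(
      sum(leaf_map$values == leaf_map$codes[["broadleaved"]], na.rm = TRUE),
      pixel_size_m)
  }
  for (p in names(change_maps)) {
    cm <- change_maps[[p]]
    row[[paste0("woody_", p)]] <- area_ha(
      sum(cm$values == fc_change_codes()[["woody_to_nonwoody"]]),
      pixel_size_m)
    row[[paste0("burnt_", p)]] <- area_ha(
      sum(cm$values == fc_change_codes()[["burnt"]]), pixel_size_m)
  }
  row
}

#' Write a human-readable loss summary
#'
#' @param report Output of [aggregate_report()].
#' @param path Optional file path; when `NULL` the text is returned
#'   invisibly only.
#' @return Character vector of summary lines, invisibly.
#' @export
write_report_summary <- function(report, path = NULL) {
  lines <- c("Forest loss report", "==================")
  for (i in seq_len(nrow(report$pooled))) {
    p <- report$pooled[i, ]
    lines <- c(lines, sprintf(
      "%s: total %.0f ha (woody-to-non-woody %.0f ha [%.0f%%], burnt %.0f ha [%.0f%%])",
      p$period, p$total_ha, p$woody_ha, p$woody_share, p$burnt_ha,
      p$burnt_share))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
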