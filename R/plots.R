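# ggplot2 display methods for the main result types.

map_df <- function(values) {
  tibble::tibble(
    row = rep(seq_len(nrow(values)), times = ncol(values)),
    col = rep(seq_len(ncol(values)), each = nrow(values)),
    value = as.vector(values)
  )
}

#' Plot a change map
#'
#' @param object A `change_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot change_map
#' @export
autoplot.change_map <- function(object, ...) {
  df <- map_df(object$values)
  df$class <- factor(df$value, levels = fc_change_codes(),
                     labels = names(fc_change_codes()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(
      outside = "grey85", no_change = "darkgreen",
      woody_to_nonwoody = "steelblue", burnt = "firebrick"),
      drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Forest change %s-%s", object$years[1],
                                  object$years[2]),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a classified map
#'
#' @param object A `classified_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot classified_map
#' @export
autoplot.classified_map <- function(object, ...) {
  df <- map_df(object$values)
  df$class <- factor(df$value, levels = object$codes,
                     labels = names(object$codes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Classification:", object$task),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an error matrix as a heat map with counts
#'
#' @param object An `error_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot error_matrix
#' @export
autoplot.error_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::tibble(
    map = rep(rownames(m), times = ncol(m)),
    reference = rep(colnames(m), each = nrow(m)),
    count = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$map,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = "Error matrix", x = "Reference", y = "Map") +
    ggplot2::theme_minimal()
}

#' Plot an index or difference raster
#'
#' @param object An `index_raster` or `difference_raster`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot index_raster
#' @export
autoplot.index_raster <- function(object, ...) {
  df <- map_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "sienna", mid = "khaki",
                                  high = "darkgreen", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$index_name, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.index_raster
#' @method autoplot difference_raster
#' @export
autoplot.difference_raster <- function(object, ...) {
  df <- map_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "khaki",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("d%s %s-%s", object$index_name,
                                  object$years[1], object$years[2]),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
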