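# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding: exact halves go up (2.5 -> 3), unlike [base::round()]
#' which rounds half to even. Regional report percentages use this convention
#' so printed shares such as 73.51% -> 74% behave as readers expect.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Test whether grid points fall inside a polygon (even-odd ray casting).
# `px`, `py`: coordinates of the points; `poly`: matrix/data.frame with
# columns x, y (vertices in order, not necessarily closed).
points_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  nv <- nrow(poly)
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Stop with a classed condition so callers/tests can match on error class.
abort_fc <- function(message, class) {
  rlang::abort(message, class = c(class, "forestchange_error"))
}

# Squared pairwise distances between an n x 2 and an m x 2 coordinate matrix.
cross_dist2 <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}
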