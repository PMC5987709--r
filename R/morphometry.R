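# Cell-shape morphometrics from closed contour polygons.

# segment intersection test for polygon simplicity (proper crossings only;
# shared endpoints of adjacent edges are allowed)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

validate_contour <- function(vertices, check_simple = TRUE) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop_bad("contour vertices must be an n x 2 matrix")
  assert_finite_num(v, "contour vertices")
  # drop a repeated closing vertex if present
  n <- nrow(v)
  if (n >= 2L && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3L) stop_bad("contour needs at least 3 distinct vertices")
  if (check_simple && nrow(v) <= 2000L) {
    n <- nrow(v)
    for (i in seq_len(n)) {
      a1 <- v[i, ]; a2 <- v[if (i == n) 1L else i + 1L, ]
      for (j in seq_len(n)) {
        if (abs(i - j) <= 1L || (i == 1L && j == n) || (i == n && j == 1L)) next
        b1 <- v[j, ]; b2 <- v[if (j == n) 1L else j + 1L, ]
        if (segments_cross(a1, a2, b1, b2)) {
          stop_bad("contour is self-intersecting (edges %d and %d)", i, j)
        }
      }
    }
  }
  v
}

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_perimeter <- function(v) {
  d <- rbind(diff(v), v[1, ] - v[nrow(v), ])
  sum(sqrt(rowSums(d^2)))
}

#' Circularity of a closed contour
#'
#' Circularity = 4·pi·Area / Perimeter², with the area from the shoelace
#' formula and the perimeter as polygonal arc length. Equals 1 for a disk
#' (in the polygon limit) and decreases with protrusiveness; the
#' isoperimetric inequality bounds it by 1 for simple polygons.
#'
#' @param vertices n x 2 matrix (or data.frame with 2 columns) of contour
#'   vertices in µm, ordered along the boundary; an explicit closing vertex
#'   is optional. Degenerate (collinear / zero-area / self-intersecting)
#'   polygons are rejected.
#' @param check_simple verify non-self-intersection (O(n²); skipped above
#'   2000 vertices).
#' @return circularity, a dimensionless scalar in (0, 1].
#' @examples
#' circularity(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # pi/4
#' @export
circularity <- function(vertices, check_simple = TRUE) {
  v <- validate_contour(vertices, check_simple = check_simple)
  a <- shoelace_area(v)
  p <- polygon_perimeter(v)
  if (a <= 0 || p <= 0) stop_bad("degenerate contour: zero area or perimeter")
  4 * pi * a / p^2
}

#' Circularity series with group comparison
#'
#' Computes circularity for every contour in a long-format contour table
#' and, if a `group` column is present, summarizes per group via
#' [group_compare()].
#'
#' @param contours data.frame with columns `contour_id`, `vertex_index`,
#'   `x_um`, `y_um` and optionally `frame` and `group`.
#' @param reference reference group passed to [group_compare()].
#' @return list with `per_contour` (data.table of `contour_id`,
#'   `circularity`, plus `group` if given) and `summary` (group_compare
#'   output or NULL when no groups).
#' @export
circularity_series <- function(contours, reference = NULL) {
  need <- c("contour_id", "vertex_index", "x_um", "y_um")
  miss <- setdiff(need, names(contours))
  if (length(miss)) {
    stop_bad("contour table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  dt <- data.table::as.data.table(contours)
  data.table::setorder(dt, contour_id, vertex_index)
  per <- dt[, .(circularity = circularity(cbind(x_um, y_um))), by = contour_id]
  if ("group" %in% names(dt)) {
    gmap <- unique(dt[, .(contour_id, group)])
    per <- gmap[per, on = "contour_id"]
    summary <- group_compare(per[, .(group, circularity)], reference = reference)
  } else {
    summary <- NULL
  }
  list(per_contour = per, summary = summary)
}
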