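#' Closed lesion contour
#'
#' An ordered, closed polyline of sub-pixel boundary points in image
#' coordinates: \code{x} is the column index, \code{y} the row index,
#' with \code{y} increasing downward.  Vertices are stored without
#' duplicating the closing point; traversal is counter-clockwise in the
#' y-down convention (signed shoelace area negative in raw coordinates).
#'
#' @param x,y numeric vertex coordinates (equal length, >= 8 points).
#' @return An object of class \code{bus_contour}: a list with a
#'   \code{vertices} data frame and \code{closed = TRUE}.
#' @export
bus_contour <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n > 1 && isTRUE(all.equal(c(x[1], y[1]), c(x[n], y[n])))) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  if (n < 8) stop("contour needs at least 8 vertices")
  if (shoelace_area(x, y) > 0) { x <- rev(x); y <- rev(y) }
  structure(list(vertices = data.frame(x = x, y = y), closed = TRUE),
            class = "bus_contour")
}

# signed area; negative = counter-clockwise when y points downward
shoelace_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @export
print.bus_contour <- function(x, ...) {
  v <- x$vertices
  cat(sprintf("bus_contour: %d vertices, bbox x [%.1f, %.1f], y [%.1f, %.1f]\n",
              nrow(v), min(v$x), max(v$x), min(v$y), max(v$y)))
  invisible(x)
}

contour_length <- function(contour) {
  v <- contour$vertices
  xn <- c(v$x[-1], v$x[1]); yn <- c(v$y[-1], v$y[1])
  sum(sqrt((xn - v$x)^2 + (yn - v$y)^2))
}

# resample the closed polyline to (approximately) uniform arc-length spacing
resample_contour <- function(contour, spacing) {
  v <- contour$vertices
  x <- c(v$x, v$x[1]); y <- c(v$y, v$y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  n <- max(16L, ceiling(L / spacing))
  si <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  list(x = stats::approx(s, x, xout = si, ties = "ordered")$y,
       y = stats::approx(s, y, xout = si, ties = "ordered")$y,
       arc = si, total = L)
}
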