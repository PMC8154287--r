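# shared fixtures built in code

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# dense circle contour (radius r, center (cx, cy)), param reversed so the
# stored orientation is the package's y-down counter-clockwise convention
circle_contour <- function(r = 50, cx = 100, cy = 100, n = 2000) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  bus_contour(cx + r * cos(th), cy + r * sin(th))
}

ellipse_contour <- function(a = 40, b = 20, cx = 100, cy = 100, n = 2000) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  bus_contour(cx + a * cos(th), cy + b * sin(th))
}

# signed distance to a disc, as a rows x cols field
disc_sdf <- function(rows, cols, cy, cx, r) {
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  sqrt((rr - cy)^2 + (cc - cx)^2) - r
}

# mask height/width ratio measured by row/column extents
mask_hw_ratio <- function(mask) {
  rows_in <- which(apply(mask, 1, any))
  cols_in <- which(apply(mask, 2, any))
  (max(rows_in) - min(rows_in) + 1) / (max(cols_in) - min(cols_in) + 1)
}

# mean |grad I| sampled along a contour (bilinear interpolation)
boundary_gradient <- function(image, contour) {
  gx <- t(apply(image, 1, function(v) c(diff(v), 0)))
  gy <- apply(image, 2, function(v) c(diff(v), 0))
  gm <- sqrt(gx^2 + gy^2)
  v <- contour$vertices
  bilin <- function(m, x, y) {
    x0 <- pmax(1, pmin(floor(x), ncol(m) - 1)); y0 <- pmax(1, pmin(floor(y), nrow(m) - 1))
    fx <- x - x0; fy <- y - y0
    m[cbind(y0, x0)] * (1 - fx) * (1 - fy) + m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
      m[cbind(y0 + 1, x0)] * (1 - fx) * fy + m[cbind(y0 + 1, x0 + 1)] * fx * fy
  }
  mean(bilin(gm, v$x, v$y))
}

# polygon area oracle (quadrature over the densely sampled true boundary)
shoelace_area_oracle <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# closed-form simple-regression slope/intercept oracle
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}
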