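#' Extreme points of a lesion contour
#'
#' Finds the top (minimal y), bottom (maximal y), leftmost (minimal x) and
#' rightmost (maximal x) points of a closed contour — the four vertices where
#' the horizontal and vertical tangent lines touch the lesion.  When several
#' consecutive vertices share the extreme coordinate (a flat run, e.g. the
#' side of a square), the midpoint of the run is returned, which still lies
#' on the polyline.
#'
#' @param contour a [bus_contour()].
#' @return List of class \code{bus_extremes} with points \code{top},
#'   \code{bottom}, \code{leftmost}, \code{rightmost}, each \code{c(x, y)}.
#' @export
contour_extremes <- function(contour) {
  v <- contour$vertices
  if (nrow(v) < 8) stop("contour needs at least 8 vertices")
  if (diff(range(v$x)) < 1e-9 || diff(range(v$y)) < 1e-9)
    stop("degenerate contour: zero width or zero height")
  structure(list(
    top = extreme_point(v, v$y, min),
    bottom = extreme_point(v, v$y, max),
    leftmost = extreme_point(v, v$x, min),
    rightmost = extreme_point(v, v$x, max)), class = "bus_extremes")
}

# midpoint of the (circularly) contiguous run of vertices attaining the
# extreme of `coord`; for an isolated extremum this is that vertex itself
extreme_point <- function(v, coord, which_fun) {
  tol <- 1e-7 * max(1, diff(range(coord)))
  target <- which_fun(coord)
  hit <- abs(coord - target) <= tol
  n <- length(hit)
  idx <- which(hit)
  if (length(idx) == 1) return(c(x = v$x[idx], y = v$y[idx]))
  # split into circular runs of consecutive indices
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  if (length(runs) > 1 && hit[1] && hit[n]) {
    # merge wrap-around run
    first <- runs[[1]]; last <- runs[[length(runs)]]
    runs[[1]] <- c(last - n, first)
    runs[[length(runs)]] <- NULL
  }
  run <- runs[[which.max(lengths(runs))]]
  ends <- ((c(run[1], run[length(run)]) - 1) %% n) + 1
  c(x = mean(v$x[ends]), y = mean(v$y[ends]))
}

#' Lesion orientation (height/width ratio)
#'
#' Ratio of lesion height to width, \eqn{|y_u - y_d| / (x_r - x_l)}, from
#' the four contour extreme points.  Values near or above 1 (taller than
#' wide) are associated with malignancy.
#'
#' @param extremes a [contour_extremes()] result.
#' @return Positive scalar.
#' @export
orientation_score <- function(extremes) {
  width <- extremes$rightmost["x"] - extremes$leftmost["x"]
  if (width <= 0) stop("zero-width contour: cannot compute orientation")
  unname(abs(extremes$top["y"] - extremes$bottom["y"]) / width)
}

#' Extract an edge patch around a contour vertex
#'
#' Cuts an exact \code{m} x \code{n} (rows x columns) intensity patch
#' centered on the (rounded) vertex.  Patches that would extend beyond the
#' image are rejected.
#'
#' @param image numeric matrix.
#' @param vertex point \code{c(x, y)} (x = column, y = row).
#' @param m,n patch rows and columns (defaults 21 and 15).
#' @return List of class \code{bus_ei_patch} with \code{values} (m x n
#'   matrix) and \code{vertex}.
#' @export
ei_patch <- function(image, vertex, m = 21L, n = 15L) {
  cx <- round(vertex[["x"]]); cy <- round(vertex[["y"]])
  hr <- (m - 1) %/% 2; hc <- (n - 1) %/% 2
  r0 <- cy - hr; r1 <- r0 + m - 1
  c0 <- cx - hc; c1 <- c0 + n - 1
  if (r0 < 1) stop("edge patch exceeds image bounds at the top")
  if (r1 > nrow(image)) stop("edge patch exceeds image bounds at the bottom")
  if (c0 < 1) stop("edge patch exceeds image bounds on the left")
  if (c1 > ncol(image)) stop("edge patch exceeds image bounds on the right")
  structure(list(values = image[r0:r1, c0:c1, drop = FALSE],
                 vertex = c(x = cx, y = cy)),
            class = "bus_ei_patch")
}

# population standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Edge-indistinctness score of one patch
#'
#' \eqn{x_{std}} is the mean over columns of each column's (population)
#' standard deviation, \eqn{y_{std}} the mean over rows of each row's; the
#' patch score is \eqn{\max(x_{std}, y_{std})}.  Sharp, distinct margins
#' give high scores; blurred margins low ones.
#'
#' @param patch a [ei_patch()].
#' @return Non-negative scalar.
#' @export
ei_score_patch <- function(patch) {
  v <- patch$values
  x_std <- mean(apply(v, 2, pop_sd))
  y_std <- mean(apply(v, 1, pop_sd))
  max(x_std, y_std)
}

#' Edge-indistinctness score of a lesion
#'
#' Mean of the patch scores at the top and bottom contour vertices, where
#' the lesion margin crosses the patch horizontally.
#'
#' @param image numeric matrix.
#' @param extremes a [contour_extremes()] result.
#' @param m,n patch geometry (see [ei_patch()]).
#' @return Non-negative scalar.
#' @export
ei_score <- function(image, extremes, m = 21L, n = 15L) {
  up <- ei_score_patch(ei_patch(image, extremes$top, m, n))
  down <- ei_score_patch(ei_patch(image, extremes$bottom, m, n))
  (up + down) / 2
}

#' Posterior-shadow region below a lesion
#'
#' Rectangle spanning the lesion's horizontal extent \eqn{[x_l, x_r]} from
#' the bottom vertex \eqn{y_d} down to \code{depth} pixels (or the image
#' bottom, whichever comes first).  \code{depth = "auto"} uses the lesion
#' height \eqn{y_d - y_u}.
#'
#' @param image numeric matrix.
#' @param extremes a [contour_extremes()] result.
#' @param depth positive pixel count or \code{"auto"}.
#' @return Numeric matrix (the cropped region).
#' @export
ps_region <- function(image, extremes, depth = "auto") {
  y_d <- round(extremes$bottom[["y"]]); y_u <- round(extremes$top[["y"]])
  x_l <- round(extremes$leftmost[["x"]]); x_r <- round(extremes$rightmost[["x"]])
  if (identical(depth, "auto")) depth <- y_d - y_u
  if (depth <= 0) stop("PS depth must be positive")
  r0 <- y_d + 1
  r1 <- min(y_d + depth, nrow(image))
  if (r0 > nrow(image))
    stop("no posterior region: lesion bottom touches the image bottom")
  x_l <- max(1, x_l); x_r <- min(ncol(image), x_r)
  image[r0:r1, x_l:x_r, drop = FALSE]
}

#' Geometric, central and normalized central moments of a region
#'
#' Moments of the intensity function \eqn{f(x, y)} with 1-based pixel
#' coordinates (x = column, y = row):
#' \eqn{m_{pq} = \sum_y \sum_x x^p y^q f(x,y)}, central moments
#' \eqn{\mu_{pq}} about the intensity centroid, and normalized central
#' moments \eqn{\eta_{pq} = \mu_{pq} / \mu_{00}^{\rho}} with
#' \eqn{\rho = (p+q)/2 + 1}.
#'
#' @param region numeric matrix with non-negative mass (\eqn{m_{00} > 0}).
#' @param max_order maximal p+q (default 3).
#' @return List of class \code{bus_moments} with matrices \code{m},
#'   \code{mu}, \code{eta} (indexed \code{[p+1, q+1]}) and \code{centroid}.
#' @export
hu_moments <- function(region, max_order = 3L) {
  f <- as.matrix(region)
  M <- ncol(f); N <- nrow(f)
  xs <- matrix(seq_len(M), N, M, byrow = TRUE)
  ys <- matrix(seq_len(N), N, M)
  m00 <- sum(f)
  if (m00 <= 0) stop("region has zero intensity mass (m00 = 0)")
  ord <- max_order
  m <- mu <- eta <- matrix(NA_real_, ord + 1, ord + 1,
                           dimnames = list(p = 0:ord, q = 0:ord))
  for (p in 0:ord) for (q in 0:ord) if (p + q <= ord)
    m[p + 1, q + 1] <- sum(xs^p * ys^q * f)
  xbar <- m[2, 1] / m00; ybar <- m[1, 2] / m00
  for (p in 0:ord) for (q in 0:ord) if (p + q <= ord) {
    mu[p + 1, q + 1] <- sum((xs - xbar)^p * (ys - ybar)^q * f)
    rho <- (p + q) / 2 + 1
    eta[p + 1, q + 1] <- mu[p + 1, q + 1] / m00^rho
  }
  structure(list(m = m, mu = mu, eta = eta, centroid = c(x = xbar, y = ybar)),
            class = "bus_moments")
}

#' Posterior-shadow score from Hu moments
#'
#' The second-order normalized central moment sum \eqn{\eta_{20} +
#' \eta_{02}} of the posterior region, log-transformed as
#' \eqn{-\mathrm{sign}(\cdot)\log_{10}|\cdot|} so that darker, more
#' attenuated shadows separate from echogenic posteriors on a convenient
#' scale.
#'
#' The score is computed on the region values exactly as given.  Published
#' clinical scores correspond to 8-bit grey levels; the pipeline therefore
#' converts [0, 1] intensities to grey levels (see the \code{grey_levels}
#' argument of [characteristic_features()]) before calling this function,
#' since \eqn{\eta_{pq}} scales as \eqn{1/c} when intensities are scaled
#' by \eqn{c}.
#'
#' @param region numeric matrix (posterior-shadow crop).
#' @return Scalar score.
#' @export
hu_ps_score <- function(region) {
  mom <- hu_moments(region, max_order = 2L)
  raw <- mom$eta[3, 1] + mom$eta[1, 3]  # eta20 + eta02
  if (raw == 0) stop("eta20 + eta02 is zero: log-transformed score undefined")
  -sign(raw) * log10(abs(raw))
}

#' Divider trace (radius/count pairs)
#'
#' @param R strictly increasing radii (pixels).
#' @param N_R positive integer circle counts.
#' @param start optional start point used for the walk.
#' @return Object of class \code{bus_divider_trace}: data frame with
#'   columns \code{R}, \code{N_R}.
#' @export
bus_divider_trace <- function(R, N_R, start = NULL) {
  stopifnot(length(R) == length(N_R))
  if (any(diff(R) <= 0)) stop("radii must be strictly increasing")
  if (any(N_R <= 0) || any(N_R != round(N_R)))
    stop("counts must be positive integers")
  structure(data.frame(R = R, N_R = as.integer(N_R)),
            start = start, class = c("bus_divider_trace", "data.frame"))
}

#' Divider (Richardson) walk along a contour
#'
#' Steps a divider of radius R along the closed contour, starting from the
#' top extreme point: each step advances to the first forward intersection
#' of the circle of radius R centered at the current point with the
#' contour polyline, and N(R) counts the steps needed to get back to (or
#' past) the start; the final partial step counts as one circle.  The
#' contour is first resampled to a uniform arc-length spacing of at most
#' \code{min(radii)/4} (an eighth of the smallest radius is used) so
#' segment-circle intersections are well conditioned.
#'
#' @param contour a [bus_contour()].
#' @param radii circle radii in pixels (default 4..11).
#' @param start only \code{"top"} is supported: the walk starts at the
#'   contour point nearest the top extreme.
#' @return A [bus_divider_trace()].
#' @export
divider_counts <- function(contour, radii = 4:11, start = "top") {
  stopifnot(identical(start, "top"))
  v <- contour$vertices
  extent <- max(diff(range(v$x)), diff(range(v$y)))
  if (any(radii >= extent))
    stop(sprintf("radius %g is not smaller than the contour extent %.1f",
                 max(radii), extent))
  rs <- resample_contour(contour, spacing = min(radii) / 8)
  top <- contour_extremes(contour)$top
  i0 <- which.min((rs$x - top["x"])^2 + (rs$y - top["y"])^2)
  # rotate so the walk starts at index 1
  ord <- c(i0:length(rs$x), seq_len(i0 - 1))
  px <- rs$x[ord]; py <- rs$y[ord]
  counts <- vapply(radii, function(R) divider_walk(px, py, R, rs$total),
                   integer(1))
  bus_divider_trace(R = radii, N_R = counts,
                    start = c(x = px[1], y = py[1]))
}

# one divider walk on a closed polyline given as points (px, py), returning
# the number of radius-R steps needed to traverse total arc length L
divider_walk <- function(px, py, R, L) {
  n <- length(px)
  # extend past the start so the final step can pass it
  ex <- c(px, px); ey <- c(py, py)
  seg <- sqrt(diff(ex)^2 + diff(ey)^2)
  arc <- c(0, cumsum(seg))
  cx <- px[1]; cy <- py[1]
  pos_arc <- 0
  idx <- 1L
  count <- 0L
  repeat {
    # first vertex beyond idx at distance >= R from the current center
    j <- idx
    found <- FALSE
    while (j < length(ex)) {
      j <- j + 1L
      if (sqrt((ex[j] - cx)^2 + (ey[j] - cy)^2) >= R) { found <- TRUE; break }
    }
    if (!found) { count <- count + 1L; break }  # ran off: partial step closes
    # refine crossing on segment (j-1, j): |p(t) - c| = R
    ax <- ex[j - 1]; ay <- ey[j - 1]
    bx <- ex[j] - ax; by <- ey[j] - ay
    fa <- ax - cx; fb <- ay - cy
    A <- bx^2 + by^2
    B <- 2 * (fa * bx + fb * by)
    C <- fa^2 + fb^2 - R^2
    disc <- B^2 - 4 * A * C
    t <- if (disc >= 0 && A > 0) {
      roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
      cand <- roots[roots >= 0 & roots <= 1]
      if (length(cand)) max(cand) else 1
    } else 1
    cx <- ax + t * bx; cy <- ay + t * by
    pos_arc <- arc[j - 1] + t * seg[j - 1]
    idx <- j - 1L
    count <- count + 1L
    if (pos_arc >= L) break  # passed the start; this partial step counted
    if (count > 100000L) stop("divider walk failed to terminate")
  }
  count
}

#' Shape-complexity fit (fractal slope)
#'
#' Ordinary least squares of \eqn{\log_{10} N(R)} on \eqn{\log_{10} R}
#' over a divider trace; the slope is the shape-complexity (SC) score and
#' its magnitude estimates the fractal dimension of the boundary.  More
#' negative slopes indicate more complex contours.
#'
#' @param trace a [bus_divider_trace()] with at least 3 pairs.
#' @return List of class \code{bus_scfit} with \code{intercept},
#'   \code{slope} (the SC score) and \code{rss}.
#' @export
sc_score <- function(trace) {
  if (nrow(trace) < 3) stop("need at least 3 (R, N(R)) pairs for the fit")
  lx <- log10(trace$R); ly <- log10(trace$N_R)
  fit <- stats::lm(ly ~ lx)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 rss = sum(stats::residuals(fit)^2)),
            class = "bus_scfit")
}

#' The four characteristic features of a lesion
#'
#' Assembles the handcrafted characteristic-feature (CF) vector in fixed
#' order: orientation (height/width), edge-indistinctness (EI) score,
#' posterior-shadow (PS) Hu-moment score, and shape-complexity (SC) slope.
#'
#' @param image numeric matrix in [0, 1].
#' @param contour lesion boundary as a [bus_contour()].
#' @param m,n EI patch geometry.
#' @param radii divider radii for the SC fit.
#' @param ps_depth posterior-region depth ("auto" = lesion height).
#' @param grey_levels grey-level scale applied to the posterior region
#'   before the Hu-moment score (default 255): normalized central moments
#'   scale as 1/c under intensity scaling, and published PS scores are on
#'   the 8-bit grey-level scale, so this keeps scores comparable across
#'   bit depths once images are loaded as [0, 1].
#' @return Named numeric vector
#'   \code{c(orientation, ei_score, ps_score, sc_score)}.
#' @export
characteristic_features <- function(image, contour, m = 21L, n = 15L,
                                    radii = 4:11, ps_depth = "auto",
                                    grey_levels = 255) {
  ex <- contour_extremes(contour)
  c(orientation = orientation_score(ex),
    ei_score = ei_score(image, ex, m, n),
    ps_score = hu_ps_score(ps_region(image, ex, ps_depth) * grey_levels),
    sc_score = sc_score(divider_counts(contour, radii))$slope)
}
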