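#' Parameters of distance-regularized level-set evolution
#'
#' Collects the coefficients of the DRLSE energy
#' \deqn{E(\phi) = \mu \int_\Omega p(|\nabla\phi|)\,dx
#'   + \lambda \int_\Omega g\,\delta(\phi)|\nabla\phi|\,dx
#'   + \alpha \int_\Omega g\,H(-\phi)\,dx}
#' together with the numerical settings of its explicit gradient-descent
#' discretization.  The distance-regularization term uses the double-well
#' potential (minima at gradient magnitudes 0 and 1), so the level-set field
#' relaxes toward a signed distance function near the contour and stays flat
#' far away, with no reinitialization.
#'
#' @param mu regularization coefficient (> 0); stability requires
#'   \code{mu * tau < 0.25}.
#' @param lambda weight of the edge-length (geodesic) term (> 0).
#' @param alpha area/balloon coefficient; negative expands an interior seed,
#'   positive shrinks.
#' @param epsilon half-width (pixels) of the smoothed Heaviside/Dirac pair.
#' @param tau explicit time step.
#' @param c0 magnitude of the binary-step initialization.
#' @param sigma_g Gaussian smoothing width used to build the edge
#'   indicator g.
#' @param grad_scale grey-level scale on which image gradients are measured
#'   in g (default 255, i.e. gradients in 8-bit grey levels per pixel;
#'   on [0,1]-normalized images the raw gradient would be far below 1 and g
#'   would hardly deviate from 1).
#' @param max_iters iteration budget.
#' @param zc_window number of consecutive zero-crossing-stability checks
#'   required to stop.
#' @param zc_interval iterations between stability checks.
#' @return An object of class \code{bus_drlse_params}.
#' @export
drlse_params <- function(mu = 0.2, lambda = 5, alpha = -3, epsilon = 1.5,
                         tau = 1, c0 = 2, sigma_g = 1.5, grad_scale = 255,
                         max_iters = 1000L, zc_window = 10L,
                         zc_interval = 10L) {
  p <- structure(list(mu = mu, lambda = lambda, alpha = alpha,
                      epsilon = epsilon, tau = tau, c0 = c0,
                      sigma_g = sigma_g, grad_scale = grad_scale,
                      max_iters = as.integer(max_iters),
                      zc_window = as.integer(zc_window),
                      zc_interval = as.integer(zc_interval)),
                 class = "bus_drlse_params")
  if (p$mu <= 0 || p$lambda <= 0) stop("mu and lambda must be > 0")
  if (p$epsilon <= 0) stop("epsilon must be > 0")
  if (p$tau <= 0) stop("tau must be > 0")
  if (p$mu * p$tau >= 0.25)
    stop("stability requires mu * tau < 0.25")
  p
}

# Neumann (mirror) boundary condition on a matrix
neumann_bc <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[1, ] <- m[2, ]; m[nr, ] <- m[nr - 1, ]
  m[, 1] <- m[, 2]; m[, nc] <- m[, nc - 1]
  m
}

# central-difference gradients; x = column direction, y = row direction
grad_x <- function(m) {
  nc <- ncol(m)
  (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
}
grad_y <- function(m) {
  nr <- nrow(m)
  (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
}
divergence <- function(fx, fy) grad_x(fx) + grad_y(fy)
laplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(2:nr, nr), ] + m[c(1, 1:(nr - 1)), ] +
    m[, c(2:nc, nc)] + m[, c(1, 1:(nc - 1))] - 4 * m
}

# smoothed Dirac delta with compact support [-epsilon, epsilon]
dirac_eps <- function(phi, epsilon) {
  d <- (1 / (2 * epsilon)) * (1 + cos(pi * phi / epsilon))
  d * (abs(phi) <= epsilon)
}

# smoothed Heaviside matching dirac_eps
heaviside_eps <- function(phi, epsilon) {
  h <- 0.5 * (1 + phi / epsilon + sin(pi * phi / epsilon) / pi)
  ifelse(phi > epsilon, 1, ifelse(phi < -epsilon, 0, h))
}

#' Edge indicator function
#'
#' Computes \eqn{g = 1 / (1 + |\nabla (G_\sigma * I)|^2)} with the gradient
#' magnitude expressed in grey levels per pixel (\code{grad_scale} grey
#' levels correspond to the [0,1] intensity range).  g is close to 1 in flat
#' regions and drops toward 0 at strong edges, slowing and stopping the
#' evolving contour there.
#'
#' @param image numeric matrix with finite values (intensities in [0, 1]).
#' @param sigma_g Gaussian pre-smoothing width in pixels (> 0).
#' @param grad_scale grey-level scale for the gradient (default 255).
#' @return Matrix of the same shape with values in (0, 1].
#' @export
edge_indicator <- function(image, sigma_g = 1.5, grad_scale = 255) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("image must be a finite numeric matrix")
  if (sigma_g <= 0) stop("sigma_g must be > 0")
  sm <- EBImage::gblur(image, sigma = sigma_g)
  gx <- grad_x(sm); gy <- grad_y(sm)
  1 / (1 + grad_scale^2 * (gx^2 + gy^2))
}

#' Initialize a level-set field as a binary step
#'
#' @param shape image size \code{c(rows, cols)}.
#' @param seed_region rectangle \code{c(x0, y0, x1, y1)} (1-based, inclusive,
#'   x = column, y = row) strictly inside the image.
#' @param c0 step magnitude; the field is \code{-c0} inside the rectangle
#'   and \code{+c0} outside.
#' @return Numeric matrix (the initial level-set field).
#' @export
initialize_lsf <- function(shape, seed_region, c0 = 2) {
  rows <- shape[1]; cols <- shape[2]
  r <- round(seed_region)
  x0 <- r[1]; y0 <- r[2]; x1 <- r[3]; y1 <- r[4]
  if (x1 < x0 || y1 < y0) stop("empty seed region")
  if (x0 < 1 || y0 < 1 || x1 > cols || y1 > rows)
    stop("seed region out of image bounds")
  if (x0 == 1 && y0 == 1 && x1 == cols && y1 == rows)
    stop("seed region must leave an exterior (cannot cover the whole image)")
  phi <- matrix(c0, rows, cols)
  phi[y0:y1, x0:x1] <- -c0
  phi
}

#' One explicit DRLSE update step
#'
#' Advances the level-set field by one explicit Euler step of the DRLSE
#' gradient flow: the double-well distance-regularization term (weight
#' \code{mu}), the edge-weighted curvature/length term (weight
#' \code{lambda}), and the balloon/area term (weight \code{alpha}), the last
#' two localized by the smoothed Dirac delta.
#'
#' @param phi level-set field (matrix).
#' @param g edge indicator from [edge_indicator()], same shape.
#' @param params a [drlse_params()].
#' @return Updated level-set field.
#' @export
evolve_step <- function(phi, g, params) {
  stopifnot(identical(dim(phi), dim(g)))
  if (params$tau == 0) return(phi)
  phi <- neumann_bc(phi)
  px <- grad_x(phi); py <- grad_y(phi)
  s <- sqrt(px^2 + py^2)
  tiny <- 1e-10

  # double-well potential: d p(s)/ds / s
  in01 <- (s >= 0) & (s <= 1)
  ps <- in01 * sin(2 * pi * s) / (2 * pi) + (!in01) * (s - 1)
  dps <- ifelse(s > tiny, ps / s, 1)
  dist_reg <- divergence((dps - 1) * px, (dps - 1) * py) + laplacian(phi)

  nx <- px / (s + tiny); ny <- py / (s + tiny)
  curv <- divergence(nx, ny)
  dirac <- dirac_eps(phi, params$epsilon)
  vx <- grad_x(g); vy <- grad_y(g)
  edge_term <- dirac * (vx * nx + vy * ny) + dirac * g * curv
  area_term <- dirac * g

  out <- phi + params$tau * (params$mu * dist_reg +
                             params$lambda * edge_term +
                             params$alpha * area_term)
  if (!all(is.finite(out)))
    stop("non-finite values in level-set update (evolution diverged)")
  out
}

#' Discrete DRLSE energy
#'
#' Evaluates the discretized energy functional (regularization + smoothed
#' edge-length + smoothed area terms) for monitoring convergence; on a
#' well-posed run it is non-increasing up to small discretization
#' fluctuations.
#'
#' @inheritParams evolve_step
#' @return Scalar energy value.
#' @export
drlse_energy <- function(phi, g, params) {
  px <- grad_x(phi); py <- grad_y(phi)
  s <- sqrt(px^2 + py^2)
  in01 <- (s >= 0) & (s <= 1)
  pval <- in01 * (1 - cos(2 * pi * s)) / (2 * pi)^2 + (!in01) * (s - 1)^2 / 2
  params$mu * sum(pval) +
    params$lambda * sum(g * dirac_eps(phi, params$epsilon) * s) +
    params$alpha * sum(g * heaviside_eps(-phi, params$epsilon))
}

#' Extract the zero-level contour of a level-set field
#'
#' Takes the largest connected negative region of \code{phi} and traces its
#' zero level as a sub-pixel closed polyline (marching through
#' \code{grDevices::contourLines}), oriented counter-clockwise in the y-down
#' image convention.
#'
#' @param phi level-set field with at least one negative pixel.
#' @return A [bus_contour()].
#' @export
extract_contour <- function(phi) {
  neg <- phi < 0
  if (!any(neg)) stop("no zero crossing: level-set field is nonnegative everywhere")
  lab <- EBImage::bwlabel(neg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  phi2 <- phi
  drop <- neg & (lab != keep)
  phi2[drop] <- abs(phi2[drop])
  cl <- grDevices::contourLines(x = seq_len(nrow(phi2)), y = seq_len(ncol(phi2)),
                                z = phi2, levels = 0)
  if (!length(cl)) stop("no zero crossing found by contour tracing")
  lens <- vapply(cl, function(p) length(p$x), numeric(1))
  best <- cl[[which.max(lens)]]
  # contourLines: its x follows the first matrix index (rows), y the second
  bus_contour(x = best$y, y = best$x)
}

#' Segment a lesion with DRLSE
#'
#' Full segmentation driver: builds the edge indicator, initializes the
#' level-set field as a binary step on \code{seed_region}, iterates
#' [evolve_step()] until the zero-crossing pixel set is stable for
#' \code{zc_window} consecutive checks (spaced \code{zc_interval} iterations
#' apart) or the iteration budget is exhausted, then extracts the final mask
#' (largest connected component of \eqn{\phi < 0}) and its sub-pixel
#' contour.
#'
#' @param image numeric matrix with intensities in [0, 1].
#' @param seed_region rectangle \code{c(x0, y0, x1, y1)} inside the lesion.
#' @param params a [drlse_params()].
#' @return List with \code{contour} ([bus_contour()]), \code{mask} (logical
#'   matrix), \code{iterations}, and the final field \code{phi}.
#' @export
segment_lesion <- function(image, seed_region, params = drlse_params()) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("image must be a finite numeric matrix")
  if (min(image) < 0 || max(image) > 1)
    stop("image intensities must be normalized to [0, 1]")
  g <- edge_indicator(image, params$sigma_g, params$grad_scale)
  phi <- initialize_lsf(dim(image), seed_region, params$c0)
  prev_mask <- phi < 0
  stable <- 0L
  iters <- 0L
  for (k in seq_len(params$max_iters)) {
    phi <- tryCatch(evolve_step(phi, g, params),
                    error = function(e) stop(sprintf("iteration %d: %s", k,
                                                     conditionMessage(e))))
    iters <- k
    if (k %% params$zc_interval == 0L) {
      mask <- phi < 0
      if (!any(mask))
        stop("zero-level set collapsed; try a smaller |alpha| or a larger seed")
      if (identical(mask, prev_mask)) stable <- stable + 1L else stable <- 0L
      prev_mask <- mask
      if (stable >= params$zc_window) break
    }
  }
  if (!any(phi < 0))
    stop("zero-level set collapsed; try a smaller |alpha| or a larger seed")
  contour <- extract_contour(phi)
  lab <- EBImage::bwlabel(phi < 0)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  list(contour = contour, mask = mask, iterations = iters, phi = phi)
}
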