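#' Specification of a synthetic breast-ultrasound phantom
#'
#' Describes a single hypoechoic lesion embedded in a speckled background,
#' with controllable geometry (height/width aspect, boundary irregularity),
#' edge blur, and an optional posterior acoustic shadow.  The phantom is the
#' package's fully controllable stand-in for a clinical B-mode image: every
#' downstream stage (segmentation, feature scoring, classification) can be
#' exercised against known ground truth.
#'
#' The lesion boundary is defined in polar form around \code{center}:
#' \deqn{r(\theta) = r_0\, s(\theta)\, \Big(1 + \frac{A}{K}\sum_{k=1}^{K}
#'   \sin((k+1)\theta + \varphi_k)\Big)}
#' where \eqn{s(\theta)} is the polar radius of an ellipse with horizontal
#' semi-axis 1 and vertical semi-axis \code{aspect}, \eqn{A} is
#' \code{irregularity_amp}, \eqn{K} is \code{irregularity_harmonics}, and the
#' phases \eqn{\varphi_k} are drawn from the seeded generator.  Dividing the
#' harmonic sum by \eqn{K} keeps the maximal relative perturbation equal to
#' \eqn{A}, so the radius stays positive over the whole admissible range
#' \eqn{A \le 0.5}; harmonics start at \eqn{k+1=2} because the first harmonic
#' merely translates the boundary.
#'
#' @param rows,cols image size in pixels.
#' @param center lesion center as \code{c(row, col)}; default image center.
#' @param base_radius horizontal lesion semi-axis in pixels.
#' @param aspect height/width ratio of the lesion (1 = circular).
#' @param irregularity_amp boundary perturbation amplitude in [0, 0.5];
#'   benign-like lesions use small values, malignant-like ones large.
#' @param irregularity_harmonics number of sinusoidal boundary harmonics.
#' @param edge_blur_sigma Gaussian blur width (pixels) applied to the lesion
#'   edge, emulating the blurred mixed zone at infiltrative margins.
#' @param lesion_intensity,background_intensity mean intensities in [0, 1];
#'   the lesion must be darker (hypoechoic).
#' @param speckle_looks shape of the mean-1 Gamma multiplicative speckle
#'   factor (number of looks); variance is \code{1/speckle_looks}.  Use
#'   \code{Inf} to disable speckle.
#' @param shadow_strength posterior shadow attenuation in [0, 1].
#' @param shadow_enabled logical; add the posterior shadow band?
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#'
#' @return An object of class \code{bus_phantom_spec}.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(rows = 128L, cols = 128L, center = NULL,
                         base_radius = 30, aspect = 1,
                         irregularity_amp = 0, irregularity_harmonics = 14L,
                         edge_blur_sigma = 1.5,
                         lesion_intensity = 0.25, background_intensity = 0.55,
                         speckle_looks = Inf,
                         shadow_strength = 0, shadow_enabled = FALSE,
                         seed = 1L) {
  if (is.null(center)) center <- c((rows + 1) / 2, (cols + 1) / 2)
  spec <- structure(list(
    rows = as.integer(rows), cols = as.integer(cols), center = as.numeric(center),
    base_radius = base_radius, aspect = aspect,
    irregularity_amp = irregularity_amp,
    irregularity_harmonics = as.integer(irregularity_harmonics),
    edge_blur_sigma = edge_blur_sigma,
    lesion_intensity = lesion_intensity,
    background_intensity = background_intensity,
    speckle_looks = speckle_looks,
    shadow_strength = shadow_strength, shadow_enabled = isTRUE(shadow_enabled),
    seed = as.integer(seed)), class = "bus_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$rows >= 8, spec$cols >= 8)
  if (spec$base_radius <= 0) stop("base_radius must be > 0")
  if (spec$irregularity_amp < 0 || spec$irregularity_amp > 0.5)
    stop("irregularity_amp must lie in [0, 0.5]")
  if (spec$aspect <= 0) stop("aspect must be > 0")
  if (spec$lesion_intensity >= spec$background_intensity)
    stop("lesion must be darker than background (hypoechoic)")
  if (!is.infinite(spec$speckle_looks) && spec$speckle_looks <= 0)
    stop("speckle_looks must be positive")
  if (spec$shadow_strength < 0 || spec$shadow_strength > 1)
    stop("shadow_strength must lie in [0, 1]")
  # lesion (worst-case radius) plus 3 sigma of blur must fit inside the image
  rmax <- spec$base_radius * max(1, spec$aspect) * (1 + spec$irregularity_amp)
  margin <- 3 * spec$edge_blur_sigma
  lo_r <- spec$center[1] - rmax - margin
  hi_r <- spec$center[1] + rmax + margin
  lo_c <- spec$center[2] - rmax - margin
  hi_c <- spec$center[2] + rmax + margin
  if (lo_r < 1 || lo_c < 1 || hi_r > spec$rows || hi_c > spec$cols)
    stop(sprintf(paste0("lesion does not fit: needs margin of %.1f px ",
                        "(max radius %.1f + 3*edge_blur_sigma %.1f) around center ",
                        "(%.1f, %.1f) in a %d x %d image"),
                 rmax + margin, rmax, margin,
                 spec$center[1], spec$center[2], spec$rows, spec$cols))
  invisible(spec)
}

# polar lesion radius r(theta); phases come from the caller's seeded draw
phantom_radius <- function(theta, spec, phases) {
  a <- 1
  b <- spec$aspect
  s <- (a * b) / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  K <- spec$irregularity_harmonics
  pert <- 0
  if (spec$irregularity_amp > 0 && K > 0) {
    for (k in seq_len(K))
      pert <- pert + sin((k + 1) * theta + phases[k])
    pert <- spec$irregularity_amp * pert / K
  }
  spec$base_radius * s * (1 + pert)
}

#' Generate a synthetic ultrasound phantom
#'
#' Renders the lesion described by a [phantom_spec()] into a speckled
#' grayscale image, together with the binary ground-truth mask and the true
#' sub-pixel boundary contour.  The image is built as background plus a
#' blurred lesion step, optionally attenuated by a posterior shadow band
#' (rectangular band spanning the lesion's horizontal extent from its bottom
#' to the image bottom, with a linear horizontal taper), then multiplied by
#' mean-1 Gamma speckle and clipped to [0, 1].
#'
#' @param spec a [phantom_spec()].
#' @return A list with components \code{image} (rows x cols matrix in [0,1]),
#'   \code{mask} (logical matrix, TRUE inside the lesion), \code{contour}
#'   (the true boundary as a [bus_contour()]), and \code{spec}.
#' @examples
#' ph <- generate_phantom(phantom_spec(aspect = 0.5, seed = 7))
#' range(ph$image)
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  K <- spec$irregularity_harmonics
  phases <- if (K > 0) stats::runif(K, 0, 2 * pi) else numeric(0)

  rr <- matrix(seq_len(spec$rows), spec$rows, spec$cols)
  cc <- matrix(seq_len(spec$cols), spec$rows, spec$cols, byrow = TRUE)
  dy <- rr - spec$center[1]
  dx <- cc - spec$center[2]
  theta <- atan2(dy, dx)
  dist <- sqrt(dx^2 + dy^2)
  mask <- dist <= phantom_radius(theta, spec, phases)

  # true contour: dense polar sampling, oriented counter-clockwise for y-down
  th <- seq(0, 2 * pi, length.out = 721L)[-721L]
  r <- phantom_radius(th, spec, phases)
  cx <- spec$center[2] + r * cos(th)
  cy <- spec$center[1] + r * sin(th)
  contour <- bus_contour(rev(cx), rev(cy))

  img <- matrix(spec$background_intensity, spec$rows, spec$cols)
  lesion <- mask * 1
  if (spec$edge_blur_sigma > 0)
    lesion <- EBImage::gblur(lesion, sigma = spec$edge_blur_sigma)
  img <- img + (spec$lesion_intensity - spec$background_intensity) * lesion

  if (spec$shadow_enabled && spec$shadow_strength > 0) {
    cols_in <- which(apply(mask, 2, any))
    rows_in <- which(apply(mask, 1, any))
    if (length(cols_in) && length(rows_in)) {
      y_bottom <- max(rows_in)
      x_l <- min(cols_in); x_r <- max(cols_in)
      x_mid <- (x_l + x_r) / 2
      half <- max((x_r - x_l) / 2, 1)
      taper <- pmax(0, 1 - abs(seq(x_l, x_r) - x_mid) / half)
      if (y_bottom < spec$rows) {
        band <- img[(y_bottom + 1):spec$rows, x_l:x_r, drop = FALSE]
        fac <- matrix(1 - spec$shadow_strength * taper,
                      nrow = nrow(band), ncol = length(taper), byrow = TRUE)
        img[(y_bottom + 1):spec$rows, x_l:x_r] <- band * fac
      }
    }
  }

  if (is.finite(spec$speckle_looks)) {
    looks <- spec$speckle_looks
    fac <- matrix(stats::rgamma(length(img), shape = looks, rate = looks),
                  spec$rows, spec$cols)
    img <- img * fac
  }
  img <- pmin(pmax(img, 0), 1)

  list(image = img, mask = mask, contour = contour, spec = spec)
}

#' Printed divider-method example measurements
#'
#' Radius/count pairs from a published divider-method measurement of a
#' clinical breast-lesion contour, used as a reference trace for the
#' shape-complexity fit.
#'
#' @return A \code{bus_divider_trace} with radii 4..11 px.
#' @export
bus_divider_example <- function() {
  bus_divider_trace(R = 4:11, N_R = c(109L, 85L, 72L, 61L, 53L, 46L, 43L, 37L))
}

#' Published characteristic-feature example values
#'
#' Original (OV) and min-max-normalized (NV) characteristic-feature values
#' for six example breast-ultrasound lesions, three benign (a-c) and three
#' malignant (d-f), as printed in the literature.  Used as reference inputs
#' for normalization checks.
#'
#' @return A data frame with one row per lesion and columns
#'   \code{orientation_ov/nv}, \code{ei_ov/nv}, \code{ps_ov/nv},
#'   \code{sc_ov/nv} and \code{label} (1 = malignant).
#' @export
bus_cf_examples <- function() {
  data.frame(
    lesion = letters[1:6],
    orientation_ov = c(0.544, 0.670, 0.835, 0.878, 0.989, 0.772),
    orientation_nv = c(0, 0.283, 0.654, 0.751, 1, 0.512),
    ei_ov = c(27.530, 27.529, 35.151, 17.329, 30.194, 23.215),
    ei_nv = c(0.572, 0.572, 1, 0, 0.722, 0.330),
    ps_ov = c(2.751, 1.983, 2.248, 2.321, 2.474, 2.153),
    ps_nv = c(1, 0, 0.371, 0.440, 0.693, 0.221),
    sc_ov = c(-1.021, -1.025, -1.027, -1.077, -1.101, -1.034),
    sc_nv = c(0, 0.05, 0.008, 0.7, 1, 0.163),
    label = c(0L, 0L, 0L, 1L, 1L, 1L))
}
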