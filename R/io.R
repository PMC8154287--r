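#' Load a grayscale image
#'
#' Reads a PNG or TIFF image and returns a rows x cols intensity matrix in
#' [0, 1] (8/16-bit data are scaled by the dtype maximum on read).  RGB
#' images are converted to a single channel by Rec. 709 luminance.
#'
#' @param path image file path.
#' @return Numeric matrix with attributes \code{source_dim} (original
#'   dimensions) and \code{source_path}.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image '", path, "': ",
                                           conditionMessage(e)))
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3) {
    nch <- dim(d)[3]
    d <- if (nch >= 3) {
      0.2126 * d[, , 1] + 0.7152 * d[, , 2] + 0.0722 * d[, , 3]
    } else d[, , 1]
  }
  if (length(d) == 0) stop("empty image: ", path)
  out <- t(d)  # EBImage stores x (column) first; transpose to rows x cols
  out <- pmin(pmax(out, 0), 1)
  attr(out, "source_dim") <- dim(EBImage::imageData(img))
  attr(out, "source_path") <- path
  out
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask logical or 0/1 matrix (rows x cols).
#' @param path output path (PNG); inside pixels become 255, outside 0.
#' @export
save_mask <- function(mask, path) {
  EBImage::writeImage(t(mask * 1), path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @param image numeric matrix in [0, 1].
#' @param path output path.
#' @export
save_image <- function(image, path) {
  EBImage::writeImage(t(pmin(pmax(image, 0), 1)), path, type = "png",
                      bits.per.sample = 8L)
  invisible(path)
}

#' Write a contour to CSV
#'
#' Vertices are stored with header \code{x,y} in pixel units, 0-based (the
#' in-memory convention is 1-based R indexing).
#'
#' @param contour a [bus_contour()].
#' @param path output CSV path.
#' @export
write_contour <- function(contour, path) {
  v <- contour$vertices
  utils::write.csv(data.frame(x = v$x - 1, y = v$y - 1), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a contour from CSV
#'
#' @param path CSV with header \code{x,y}, 0-based pixel coordinates.
#' @return A [bus_contour()] (1-based in memory).
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("empty or header-only contour file: ", path)
  header <- strsplit(trimws(lines[1]), ",")[[1]]
  if (!identical(tolower(header), c("x", "y")))
    stop("contour CSV must have header 'x,y': ", path)
  parse_row <- function(i) {
    cells <- strsplit(trimws(lines[i]), ",")[[1]]
    vals <- suppressWarnings(as.numeric(cells))
    if (length(vals) != 2 || any(is.na(vals)))
      stop(sprintf("malformed contour row at line %d of %s", i, path))
    vals
  }
  xy <- t(vapply(2:length(lines), parse_row, numeric(2)))
  bus_contour(x = xy[, 1] + 1, y = xy[, 2] + 1)
}

#' Write a divider trace to CSV
#'
#' @param trace a [bus_divider_trace()].
#' @param path output CSV path with header \code{R,N_R}.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(R = trace$R, N_R = trace$N_R), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV with an \code{image} column plus numeric feature columns.
#' @return Data frame.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"image" %in% names(df)) stop("feature CSV needs an 'image' column: ", path)
  df
}

#' Read a label table from CSV
#'
#' @param path CSV with columns \code{image,label} (labels in {0, 1}).
#' @return Data frame.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("image", "label") %in% names(df)))
    stop("label CSV needs columns 'image' and 'label': ", path)
  if (!all(df$label %in% c(0, 1))) stop("labels must be 0 or 1: ", path)
  df
}

#' Read precomputed deep-feature vectors from CSV
#'
#' One row per image: an \code{image} key column followed by numeric
#' deep-feature columns of arbitrary count.
#'
#' @param path CSV path.
#' @return Data frame keyed by \code{image}.
#' @export
read_dlf <- function(path) {
  if (!file.exists(path)) stop("deep-feature file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"image" %in% names(df)) stop("deep-feature CSV needs an 'image' column: ", path)
  num <- df[setdiff(names(df), "image")]
  if (!all(vapply(num, is.numeric, logical(1))))
    stop("deep-feature columns must be numeric: ", path)
  df
}

# default segmentation-parameter config as a plain list (YAML-mirrorable)
default_seg_config <- function() {
  p <- drlse_params()
  p[c("mu", "lambda", "alpha", "epsilon", "tau", "c0", "sigma_g",
      "grad_scale", "max_iters", "zc_window", "zc_interval")]
}

#' Load DRLSE parameters from a YAML config file
#'
#' Keys mirror [drlse_params()] arguments; unknown keys are rejected so
#' typos fail loudly.  Missing keys fall back to the documented defaults.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return A [drlse_params()].
#' @export
load_seg_config <- function(path = NULL) {
  cfg <- default_seg_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), c(names(cfg), "lam"))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    if (!is.null(user$lam)) { user$lambda <- user$lam; user$lam <- NULL }
    cfg[names(user)] <- user
  }
  do.call(drlse_params, cfg)
}
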