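#' Fit a min-max normalizer
#'
#' Learns per-feature minimum and maximum from the fitting set and a
#' direction per feature: \code{"standard"} maps the minimum to 0 and the
#' maximum to 1 via \eqn{(x - min)/(max - min)}; \code{"inverted"} maps via
#' \eqn{(max - x)/(max - min)}, used for features where smaller (more
#' negative) raw values indicate the suspicious end of the scale.  By
#' default the shape-complexity slope \code{sc_score} is inverted and all
#' other features are standard.
#'
#' @param x data frame or matrix of features (named columns).
#' @param directions optional named character vector
#'   (\code{"standard"}/\code{"inverted"}) overriding the defaults.
#' @return Object of class \code{bus_norm} with \code{min}, \code{max},
#'   \code{direction} per feature.
#' @export
fit_normalizer <- function(x, directions = NULL) {
  x <- as.data.frame(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("features must be named")
  mins <- vapply(x, min, numeric(1))
  maxs <- vapply(x, max, numeric(1))
  const <- maxs <= mins
  if (any(const))
    stop("constant feature(s): ", paste(names(x)[const], collapse = ", "))
  dir <- stats::setNames(rep("standard", ncol(x)), names(x))
  if ("sc_score" %in% names(x)) dir["sc_score"] <- "inverted"
  if (!is.null(directions)) {
    bad <- setdiff(names(directions), names(x))
    if (length(bad)) stop("unknown feature(s) in directions: ",
                          paste(bad, collapse = ", "))
    dir[names(directions)] <- directions
  }
  if (!all(dir %in% c("standard", "inverted")))
    stop("directions must be 'standard' or 'inverted'")
  structure(list(min = mins, max = maxs, direction = dir),
            class = "bus_norm")
}

#' Apply a fitted min-max normalizer
#'
#' Transforms each feature with the affine map learned by
#' [fit_normalizer()].  Values outside the training range extrapolate
#' linearly beyond [0, 1] (they are not clipped); a warning reports how
#' many fell outside.
#'
#' @param params a \code{bus_norm}.
#' @param x data frame or matrix whose columns include the fitted features.
#' @return Data frame of normalized features (fitted features only, in the
#'   fitted order).
#' @export
apply_normalizer <- function(params, x) {
  x <- as.data.frame(x)
  missing <- setdiff(names(params$min), names(x))
  if (length(missing))
    stop("features absent from data: ", paste(missing, collapse = ", "))
  out <- lapply(names(params$min), function(f) {
    rng <- params$max[f] - params$min[f]
    if (params$direction[f] == "standard")
      (x[[f]] - params$min[f]) / rng
    else
      (params$max[f] - x[[f]]) / rng
  })
  out <- as.data.frame(stats::setNames(out, names(params$min)))
  n_out <- sum(vapply(out, function(v) sum(v < 0 | v > 1), numeric(1)))
  if (n_out > 0)
    warning(sprintf("%d normalized value(s) fall outside [0, 1] (linear extrapolation beyond the training range)", n_out))
  out
}

#' Serial fusion of characteristic and deep features
#'
#' Concatenates the 4-element characteristic-feature vector with an
#' optional precomputed deep-feature vector (CF first, then DLF), giving
#' the multi-feature (MF) representation.
#'
#' @param cf named numeric vector of the four characteristic features.
#' @param dlf numeric vector of deep features (may be empty).
#' @return Named numeric vector of length \code{4 + length(dlf)}.
#' @export
fuse <- function(cf, dlf = numeric(0)) {
  if (length(cf) != 4) stop("cf must have exactly 4 characteristic features")
  if (!all(is.finite(cf)) || !all(is.finite(dlf)))
    stop("non-finite feature values")
  if (is.null(names(cf)))
    names(cf) <- c("orientation", "ei_score", "ps_score", "sc_score")
  if (length(dlf) && is.null(names(dlf)))
    names(dlf) <- paste0("dlf", seq_along(dlf))
  c(cf, dlf)
}

#' SVM grid-search configuration
#'
#' @param c_grid soft-margin cost grid (positive; default powers of two
#'   from 2^-5 to 2^5).
#' @param g_grid RBF width grid for the kernel
#'   \eqn{K(u, v) = \exp(-g \|u - v\|^2)}.
#' @param folds number of cross-validation folds (default 3).
#' @param seed seed for the stratified fold assignment.
#' @return Object of class \code{bus_svm_config}.
#' @export
svm_config <- function(c_grid = 2^(-5:5), g_grid = 2^(-5:5),
                       folds = 3L, seed = 1L) {
  if (!length(c_grid) || !length(g_grid) ||
      any(c_grid <= 0) || any(g_grid <= 0))
    stop("c and g grids must be nonempty and positive")
  structure(list(c_grid = sort(c_grid), g_grid = sort(g_grid),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "bus_svm_config")
}

# seeded stratified fold assignment; error if any fold would miss a class
stratified_folds <- function(y, folds, seed) {
  y <- as.integer(y)
  idx <- integer(length(y))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  for (cls in unique(y)) {
    members <- which(y == cls)
    if (length(members) < folds)
      stop(sprintf("class %d has %d sample(s) but %d folds are required; add data or use stratification-compatible folds",
                   cls, length(members), folds))
    idx[members] <- rep_len(seq_len(folds), length(members))[sample.int(length(members))]
  }
  idx
}

#' Grid-search cross-validation for the RBF-SVM
#'
#' For every (c, g) pair of the grid, the data are split into
#' \code{folds} stratified parts (seeded); each part serves once as the
#' validation set for an SVM trained on the rest, and the pair's score is
#' the mean validation accuracy.  The winning pair maximizes that score,
#' with ties broken toward the smallest c, then the smallest g (prefer
#' simpler models).
#'
#' @param X numeric matrix/data frame of (normalized) features.
#' @param y labels, 1 = malignant, 0 = benign.
#' @param config a [svm_config()].
#' @return List with \code{best_c}, \code{best_g}, \code{best_accuracy}
#'   and the full \code{surface} (c x g matrix of mean accuracies).
#' @export
cross_validate_grid <- function(X, y, config = svm_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 (benign) or 1 (malignant)")
  if (min(table(y)) < config$folds)
    stop("need at least as many samples per class as folds")
  fold <- stratified_folds(y, config$folds, config$seed)
  yf <- factor(y, levels = c(0, 1))
  surface <- matrix(NA_real_, length(config$c_grid), length(config$g_grid),
                    dimnames = list(c = signif(config$c_grid, 6),
                                    g = signif(config$g_grid, 6)))
  for (ci in seq_along(config$c_grid)) for (gi in seq_along(config$g_grid)) {
    acc <- vapply(seq_len(config$folds), function(k) {
      tr <- fold != k
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
        stop("a fold is missing a class; use stratified folds or more data")
      fit <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = config$c_grid[ci], gamma = config$g_grid[gi],
                        scale = FALSE)
      mean(stats::predict(fit, X[!tr, , drop = FALSE]) == yf[!tr])
    }, numeric(1))
    surface[ci, gi] <- mean(acc)
  }
  best <- which(surface >= max(surface) - 1e-12, arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(best_c = config$c_grid[best[1]], best_g = config$g_grid[best[2]],
       best_accuracy = max(surface), surface = surface)
}

#' Train an RBF-SVM classifier
#'
#' Soft-margin support vector machine with Gaussian kernel
#' \eqn{K(u,v)=\exp(-g\|u-v\|^2)} at fixed cost \code{c} and kernel width
#' \code{g}.  Feature scaling is expected to be done beforehand (e.g. with
#' [apply_normalizer()]); \code{e1071}'s internal scaling is disabled.
#'
#' @param X numeric matrix/data frame of features.
#' @param y labels in {0, 1} with both classes present.
#' @param c cost parameter.
#' @param g RBF kernel width.
#' @param normalizer optional \code{bus_norm} to embed with the model.
#' @return Object of class \code{bus_svm} with the fitted model, the
#'   (c, g) pair, training accuracy and optional normalizer.
#' @export
train_svm <- function(X, y, c = 0.5, g = 0.25, normalizer = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 or 1")
  yf <- factor(y, levels = c(0, 1))
  fit <- e1071::svm(X, yf, kernel = "radial", cost = c, gamma = g,
                    scale = FALSE)
  train_acc <- mean(stats::predict(fit, X) == yf)
  structure(list(model = fit, c = c, g = g, train_accuracy = train_acc,
                 normalizer = normalizer, features = colnames(X)),
            class = "bus_svm")
}

#' Predict with a trained RBF-SVM
#'
#' @param object a \code{bus_svm} from [train_svm()].
#' @param newdata feature matrix/data frame; if the model embeds a
#'   normalizer, raw features are normalized first.
#' @param type \code{"class"} for {0, 1} labels, \code{"decision"} for the
#'   continuous decision score (larger = more malignant).
#' @param ... unused.
#' @return Integer labels or numeric scores.
#' @export
predict.bus_svm <- function(object, newdata, type = c("class", "decision"),
                            ...) {
  type <- match.arg(type)
  if (!is.null(object$normalizer))
    newdata <- apply_normalizer(object$normalizer, newdata)
  newdata <- as.matrix(newdata)
  if (type == "class") {
    as.integer(as.character(stats::predict(object$model, newdata)))
  } else {
    pr <- stats::predict(object$model, newdata, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    score <- dv[, 1]
    # e1071 orients the decision value toward the first factor level; make
    # larger scores mean class "1"
    if (grepl("^0/1$", colnames(dv)[1])) score <- -score
    unname(score)
  }
}

#' Confusion-matrix counts
#'
#' Counts with malignant (label 1) as the positive class: TP = truth 1 and
#' prediction 1, FP = truth 0 and prediction 1, FN = truth 1 and
#' prediction 0, TN = truth 0 and prediction 0.
#'
#' @param pred,truth equal-length vectors with values in {0, 1}.
#' @return Named integer vector \code{c(tp, fp, fn, tn)}.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (!all(pred %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  c(tp = sum(pred == 1 & truth == 1),
    fp = sum(pred == 1 & truth == 0),
    fn = sum(pred == 0 & truth == 1),
    tn = sum(pred == 0 & truth == 0))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/n,
#' F1 = 2TP/(2TP+FP+FN), precision TP/(TP+FP).  Ratios with a zero
#' denominator are reported as \code{NA} (undefined), never as 0.
#'
#' @param tp,fp,fn,tn non-negative counts (or a single named vector from
#'   [confusion()] passed as \code{tp}).
#' @return List of class \code{bus_metrics}.
#' @export
eval_metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.null(fp) && length(tp) == 4) {
    fp <- tp[["fp"]]; fn <- tp[["fn"]]; tn <- tp[["tn"]]; tp <- tp[["tp"]]
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("all counts are zero")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = (tp + tn) / n,
    f1 = safe_div(2 * tp, 2 * tp + fp + fn),
    precision = safe_div(tp, tp + fp)), class = "bus_metrics")
}

#' @export
print.bus_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("accuracy %.3f  sensitivity %.3f  specificity %.3f  precision %.3f  F1 %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Full-threshold ROC sweep and trapezoidal AUC (equivalently the
#' tie-averaged rank statistic), with larger scores meaning the positive
#' class (1).
#'
#' @param scores continuous decision scores.
#' @param labels true labels in {0, 1}, both classes present.
#' @return List with \code{points} (data frame of \code{fpr}, \code{tpr})
#'   and \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (!all(is.finite(scores))) stop("scores must be finite")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  list(points = pts, auc = as.numeric(r$auc))
}
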