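#' Benign-like and malignant-like phantom presets
#'
#' Draws a cohort of phantom specifications from two regimes chosen to
#' mirror the sonographic signs the characteristic features target: the
#' benign-like regime is wider than tall (aspect around 0.55), has a nearly
#' smooth boundary and no posterior shadow; the malignant-like regime is
#' nearly as tall as wide (aspect around 0.95), has a markedly irregular
#' boundary, more blurred margins and a posterior shadow.  Both regimes are
#' speckled (4 looks by default).
#'
#' @param n_benign,n_malignant cohort sizes.
#' @param seed integer seed controlling every random draw.
#' @param rows,cols image size.
#' @param speckle_looks speckle looks for both regimes.
#' @return List with \code{specs} (list of [phantom_spec()]) and
#'   \code{labels} (integer vector, 1 = malignant-like).
#' @export
phantom_cohort <- function(n_benign = 20L, n_malignant = 20L, seed = 1L,
                           rows = 96L, cols = 96L, speckle_looks = 4) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  make <- function(i, malignant) {
    if (malignant) {
      aspect <- stats::runif(1, 0.85, 1.05)
      amp <- stats::runif(1, 0.20, 0.30)
      blur <- stats::runif(1, 2.0, 3.0)
      shadow <- TRUE
      shadow_strength <- stats::runif(1, 0.2, 0.4)
    } else {
      aspect <- stats::runif(1, 0.45, 0.65)
      amp <- stats::runif(1, 0, 0.05)
      blur <- stats::runif(1, 1.0, 2.0)
      shadow <- FALSE
      shadow_strength <- 0
    }
    phantom_spec(rows = rows, cols = cols,
                 base_radius = stats::runif(1, 16, 21),
                 aspect = aspect, irregularity_amp = amp,
                 edge_blur_sigma = blur,
                 lesion_intensity = 0.25, background_intensity = 0.55,
                 speckle_looks = speckle_looks,
                 shadow_strength = shadow_strength, shadow_enabled = shadow,
                 seed = sample.int(2^31 - 1, 1))
  }
  specs <- c(lapply(seq_len(n_benign), make, malignant = FALSE),
             lapply(seq_len(n_malignant), make, malignant = TRUE))
  list(specs = specs,
       labels = c(rep(0L, n_benign), rep(1L, n_malignant)))
}

# seed rectangle inside the lesion derived from a phantom spec
phantom_seed_rect <- function(spec) {
  h <- max(4, round(spec$base_radius * min(1, spec$aspect) * 0.5))
  w <- max(4, round(spec$base_radius * 0.5))
  c(round(spec$center[2]) - w, round(spec$center[1]) - h,
    round(spec$center[2]) + w, round(spec$center[1]) + h)
}

#' Segment a phantom cohort and compute characteristic features
#'
#' Runs the full measurement chain (DRLSE segmentation from a seed
#' rectangle inside the lesion, then the four characteristic features on
#' the segmented contour) for every phantom of a [phantom_cohort()].
#'
#' @param cohort a [phantom_cohort()].
#' @param params segmentation parameters ([drlse_params()]).
#' @return Data frame with columns \code{image}, the four features and
#'   \code{label}.
#' @export
cohort_features <- function(cohort, params = drlse_params(max_iters = 400L)) {
  rows <- lapply(seq_along(cohort$specs), function(i) {
    spec <- cohort$specs[[i]]
    ph <- generate_phantom(spec)
    seg <- segment_lesion(ph$image, phantom_seed_rect(spec), params)
    cf <- characteristic_features(ph$image, seg$contour)
    data.frame(image = sprintf("phantom_%03d", i),
               orientation = cf[["orientation"]], ei_score = cf[["ei_score"]],
               ps_score = cf[["ps_score"]], sc_score = cf[["sc_score"]],
               label = cohort$labels[i])
  })
  do.call(rbind, rows)
}

#' Held-out classification accuracy on a phantom cohort
#'
#' End-to-end study at desk scale: generate a speckled phantom cohort,
#' segment and score every phantom, split stratified into train/test, fit
#' the min-max normalizer on the training split only, pick (c, g) by
#' stratified 3-fold grid-search cross-validation, train the RBF-SVM and
#' report held-out metrics.
#'
#' @param n_benign,n_malignant cohort sizes.
#' @param seed master seed (cohort, split, folds).
#' @param train_fraction fraction of each class used for training.
#' @param params segmentation parameters.
#' @param config SVM grid configuration (its seed is overridden by
#'   \code{seed}).
#' @return List with \code{metrics} ([eval_metrics()]), \code{auc},
#'   \code{model}, \code{features} (full feature table), \code{best_c},
#'   \code{best_g}.
#' @export
phantom_classification_study <- function(n_benign = 20L, n_malignant = 20L,
                                         seed = 1L, train_fraction = 0.5,
                                         params = drlse_params(max_iters = 400L),
                                         config = svm_config()) {
  cohort <- phantom_cohort(n_benign, n_malignant, seed = seed)
  feats <- cohort_features(cohort, params)
  config$seed <- seed

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed + 1L)
  tr <- logical(nrow(feats))
  for (cls in c(0L, 1L)) {
    members <- which(feats$label == cls)
    n_tr <- round(length(members) * train_fraction)
    tr[sample(members, n_tr)] <- TRUE
  }

  feat_cols <- c("orientation", "ei_score", "ps_score", "sc_score")
  norm <- fit_normalizer(feats[tr, feat_cols])
  Xtr <- apply_normalizer(norm, feats[tr, feat_cols])
  cv <- cross_validate_grid(Xtr, feats$label[tr], config)
  model <- train_svm(Xtr, feats$label[tr], c = cv$best_c, g = cv$best_g,
                     normalizer = norm)
  pred <- suppressWarnings(predict(model, feats[!tr, feat_cols]))
  score <- suppressWarnings(predict(model, feats[!tr, feat_cols],
                                    type = "decision"))
  met <- eval_metrics(confusion(pred, feats$label[!tr]))
  auc <- roc_auc(score, feats$label[!tr])$auc
  list(metrics = met, auc = auc, model = model, features = feats,
       train_index = tr, best_c = cv$best_c, best_g = cv$best_g)
}

#' Run the full pipeline from a config
#'
#' Drives the complete tool: phantom-cohort generation (or externally
#' listed images), DRLSE segmentation, characteristic-feature scoring,
#' optional fusion with precomputed deep features, and SVM training and
#' evaluation.  All randomness flows from \code{config$seed}.
#'
#' Config keys (YAML): \code{seed}; \code{segmentation} (keys of
#' [drlse_params()]); \code{svm} (\code{c_grid}, \code{g_grid},
#' \code{folds}); \code{phantoms} (\code{n_benign}, \code{n_malignant},
#' \code{rows}, \code{cols}, \code{speckle_looks}) or \code{images} (CSV
#' with columns \code{path,x0,y0,x1,y1} and optionally \code{label});
#' \code{dlf} (CSV path); \code{train_fraction}; \code{out_dir}.
#'
#' @param config named list or YAML path.
#' @return List with the feature table and, when labels are present, the
#'   trained model and held-out metrics.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- c("seed", "segmentation", "svm", "phantoms", "images", "dlf",
               "train_fraction", "out_dir")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  seg_cfg <- default_seg_config()
  if (!is.null(config$segmentation)) {
    unknown <- setdiff(names(config$segmentation), names(seg_cfg))
    if (length(unknown))
      stop("unknown segmentation key(s): ", paste(unknown, collapse = ", "))
    seg_cfg[names(config$segmentation)] <- config$segmentation
  }
  params <- do.call(drlse_params, seg_cfg)

  feat_cols <- c("orientation", "ei_score", "ps_score", "sc_score")
  if (!is.null(config$phantoms)) {
    ph <- config$phantoms
    cohort <- phantom_cohort(
      n_benign = if (is.null(ph$n_benign)) 20L else ph$n_benign,
      n_malignant = if (is.null(ph$n_malignant)) 20L else ph$n_malignant,
      seed = seed,
      rows = if (is.null(ph$rows)) 96L else ph$rows,
      cols = if (is.null(ph$cols)) 96L else ph$cols,
      speckle_looks = if (is.null(ph$speckle_looks)) 4 else ph$speckle_looks)
    feats <- cohort_features(cohort, params)
  } else if (!is.null(config$images)) {
    tbl <- utils::read.csv(config$images)
    need <- c("path", "x0", "y0", "x1", "y1")
    if (!all(need %in% names(tbl)))
      stop("image list CSV needs columns: ", paste(need, collapse = ", "))
    rows <- lapply(seq_len(nrow(tbl)), function(i) {
      img <- load_image(tbl$path[i])
      seg <- tryCatch(
        segment_lesion(img, as.numeric(tbl[i, c("x0", "y0", "x1", "y1")]) + 1,
                       params),
        error = function(e) stop(sprintf("image '%s', stage segmentation: %s",
                                         tbl$path[i], conditionMessage(e))))
      cf <- tryCatch(characteristic_features(img, seg$contour),
                     error = function(e) stop(sprintf(
                       "image '%s', stage features: %s",
                       tbl$path[i], conditionMessage(e))))
      out <- data.frame(image = basename(tbl$path[i]),
                        orientation = cf[["orientation"]],
                        ei_score = cf[["ei_score"]],
                        ps_score = cf[["ps_score"]],
                        sc_score = cf[["sc_score"]])
      if ("label" %in% names(tbl)) out$label <- tbl$label[i]
      out
    })
    feats <- do.call(rbind, rows)
  } else stop("config must provide either 'phantoms' or 'images'")

  if (!is.null(config$dlf)) {
    dlf <- read_dlf(config$dlf)
    feats <- merge(feats, dlf, by = "image", sort = FALSE)
    if (nrow(feats) == 0) stop("no images matched the deep-feature table")
    feat_cols <- c(feat_cols, setdiff(names(dlf), "image"))
  }

  train_fraction <- if (is.null(config$train_fraction)) 0.5 else config$train_fraction
  out <- list(features = feats)
  if ("label" %in% names(feats) && train_fraction > 0) {
    svm_cfg <- svm_config(seed = seed)
    if (!is.null(config$svm)) {
      known <- c("c_grid", "g_grid", "folds")
      unknown <- setdiff(names(config$svm), known)
      if (length(unknown))
        stop("unknown svm key(s): ", paste(unknown, collapse = ", "))
      if (!is.null(config$svm$c_grid)) svm_cfg$c_grid <- sort(unlist(config$svm$c_grid))
      if (!is.null(config$svm$g_grid)) svm_cfg$g_grid <- sort(unlist(config$svm$g_grid))
      if (!is.null(config$svm$folds)) svm_cfg$folds <- as.integer(config$svm$folds)
    }
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(seed + 1L)
    tr <- logical(nrow(feats))
    for (cls in unique(feats$label)) {
      members <- which(feats$label == cls)
      tr[sample(members, round(length(members) * train_fraction))] <- TRUE
    }
    norm <- fit_normalizer(feats[tr, feat_cols])
    Xtr <- apply_normalizer(norm, feats[tr, feat_cols])
    cv <- cross_validate_grid(Xtr, feats$label[tr], svm_cfg)
    model <- train_svm(Xtr, feats$label[tr], c = cv$best_c, g = cv$best_g,
                       normalizer = norm)
    pred <- suppressWarnings(predict(model, feats[!tr, feat_cols]))
    score <- suppressWarnings(predict(model, feats[!tr, feat_cols],
                                      type = "decision"))
    met <- eval_metrics(confusion(pred, feats$label[!tr]))
    out$model <- model
    out$metrics <- met
    out$auc <- roc_auc(score, feats$label[!tr])$auc
    out$best_c <- cv$best_c
    out$best_g <- cv$best_g
    out$train_index <- tr
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(feats, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(out$metrics)) {
      m <- out$metrics
      jsonlite::write_json(
        list(tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
             sensitivity = m$sensitivity, specificity = m$specificity,
             accuracy = m$accuracy, precision = m$precision, f1 = m$f1,
             auc = out$auc, best_c = out$best_c, best_g = out$best_g,
             seed = seed),
        file.path(config$out_dir, "metrics.json"), auto_unbox = TRUE,
        digits = NA)
      saveRDS(out$model, file.path(config$out_dir, "model.rds"))
    }
  }
  out
}
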