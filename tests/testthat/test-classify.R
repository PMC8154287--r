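test_that("min-max normalization reproduces the published example table", {
  ex <- bus_cf_examples()
  tol <- 6e-4  # half a unit in the last printed decimal place

  orient <- fit_normalizer(data.frame(orientation = ex$orientation_ov))
  nv <- apply_normalizer(orient, data.frame(orientation = ex$orientation_ov))
  expect_lt(max(abs(nv$orientation - ex$orientation_nv)), tol)

  ei <- fit_normalizer(data.frame(ei_score = ex$ei_ov))
  nv <- apply_normalizer(ei, data.frame(ei_score = ex$ei_ov))
  keep <- ex$lesion %in% c("a", "b", "d", "e", "f")
  expect_lt(max(abs(nv$ei_score[keep] - ex$ei_nv[keep])), tol)

  ps <- fit_normalizer(data.frame(ps_score = ex$ps_ov))
  nv <- apply_normalizer(ps, data.frame(ps_score = ex$ps_ov))
  keep <- ex$lesion %in% c("a", "b", "d", "f")
  expect_lt(max(abs(nv$ps_score[keep] - ex$ps_nv[keep])), tol)

  # shape-complexity uses the inverted direction by default
  sc <- fit_normalizer(data.frame(sc_score = ex$sc_ov))
  expect_identical(unname(sc$direction["sc_score"]), "inverted")
  nv <- apply_normalizer(sc, data.frame(sc_score = ex$sc_ov))
  keep <- ex$lesion %in% c("a", "b", "d", "e", "f")
  expect_lt(max(abs(nv$sc_score[keep] - ex$sc_nv[keep])), tol)
})

test_that("normalization round-trip pins minima at 0 and maxima at 1", {
  set.seed(2)
  X <- data.frame(orientation = runif(30, 0.4, 1.1),
                  ei_score = runif(30, 15, 40),
                  ps_score = runif(30, 1.5, 3),
                  sc_score = runif(30, -1.2, -1))
  norm <- fit_normalizer(X)
  Z <- apply_normalizer(norm, X)
  expect_equal(unname(vapply(Z, min, numeric(1))), rep(0, 4))
  expect_equal(unname(vapply(Z, max, numeric(1))), rep(1, 4))
  mid <- as.data.frame(as.list((norm$min + norm$max) / 2))
  expect_equal(unname(unlist(apply_normalizer(norm, mid))),
               c(0.5, 0.5, 0.5, 0.5))
})

test_that("out-of-range test values extrapolate linearly with a warning", {
  norm <- fit_normalizer(data.frame(f = c(1, 2, 3)))
  expect_warning(z <- apply_normalizer(norm, data.frame(f = 4)), "outside")
  expect_equal(z$f, 1.5)
  expect_error(fit_normalizer(data.frame(f = c(2, 2, 2))), "constant")
  expect_error(apply_normalizer(norm, data.frame(g = 1)), "absent")
})

test_that("serial fusion keeps characteristic features first", {
  cf <- c(orientation = 0.8, ei_score = 25, ps_score = 2.2, sc_score = -1.05)
  expect_length(fuse(cf), 4)
  mf <- fuse(cf, c(0.1, 0.2, 0.3, 0.4))
  expect_length(mf, 8)
  expect_identical(unname(mf[1:4]), unname(cf))
  expect_error(fuse(cf, c(1, NA)), "finite")
  expect_error(fuse(cf[1:3]), "4")
})

test_that("grid-search cross-validation separates well-separated clouds", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40, 0, 1), 20, 2), matrix(rnorm(40, 10, 1), 20, 2))
  y <- rep(c(0, 1), each = 20)
  cfg <- svm_config(c_grid = 2^(-2:2), g_grid = 2^(-2:2), seed = 7)
  cv <- cross_validate_grid(X, y, cfg)
  expect_equal(cv$best_accuracy, 1.0)
  cv2 <- cross_validate_grid(X, y, cfg)
  expect_identical(cv$surface, cv2$surface)  # seeded, bit-reproducible
})

test_that("CV accuracy approaches the Bayes rate for overlapping Gaussians", {
  set.seed(11)
  n <- 300
  X <- matrix(c(rnorm(n, 0, 1), rnorm(n, 1, 1)), ncol = 1)
  y <- rep(c(0, 1), each = n)
  cv <- cross_validate_grid(X, y, svm_config(c_grid = 2^(-3:3),
                                             g_grid = 2^(-3:3), seed = 3))
  expect_equal(cv$best_accuracy, pnorm(0.5), tolerance = 0.05 / pnorm(0.5))
})

test_that("grid ties break toward the smallest c then smallest g", {
  set.seed(6)
  X <- rbind(matrix(rnorm(60, 0, 0.5), 30, 2), matrix(rnorm(60, 8, 0.5), 30, 2))
  y <- rep(c(0, 1), each = 30)
  cv <- cross_validate_grid(X, y, svm_config(seed = 2))
  ties <- which(cv$surface >= max(cv$surface) - 1e-12, arr.ind = TRUE)
  expect_equal(cv$best_c, svm_config()$c_grid[min(ties[, 1])])
})

test_that("the RBF-SVM fits separable data and ignores sample order", {
  set.seed(8)
  X <- rbind(matrix(rnorm(40, 0, 1), 20, 2), matrix(rnorm(40, 8, 1), 20, 2))
  y <- rep(c(0L, 1L), each = 20)
  fit <- train_svm(X, y, c = 1, g = 0.5)
  expect_equal(fit$train_accuracy, 1.0)
  perm <- sample(40)
  fit2 <- train_svm(X[perm, ], y[perm], c = 1, g = 0.5)
  grid <- matrix(runif(40, -2, 10), 20, 2)
  expect_equal(predict(fit, grid), predict(fit2, grid))
  # vanishing cost: every point ends up a bounded support vector
  weak <- train_svm(X, y, c = 1e-6, g = 0.5)
  expect_equal(nrow(weak$model$SV), 40)
  expect_error(train_svm(X, rep(1L, 40), c = 1, g = 0.5), "classes")
})

test_that("decision scores rank the malignant class higher", {
  set.seed(9)
  X <- rbind(matrix(rnorm(60, 0, 1), 30, 2), matrix(rnorm(60, 6, 1), 30, 2))
  y <- rep(c(0L, 1L), each = 30)
  fit <- train_svm(X, y, c = 1, g = 0.25)
  sc <- predict(fit, X, type = "decision")
  expect_gt(mean(sc[y == 1]), mean(sc[y == 0]))
  expect_equal(roc_auc(sc, y)$auc, 1.0)
})

test_that("confusion counts follow the malignant-positive convention", {
  expect_equal(confusion(rep(c(1, 0), each = 20), rep(c(1, 0), each = 20)),
               c(tp = 20L, fp = 0L, fn = 0L, tn = 20L))
  expect_equal(confusion(rep(1, 40), rep(c(1, 0), each = 20)),
               c(tp = 20L, fp = 20L, fn = 0L, tn = 0L))
  set.seed(10)
  pred <- rbinom(25, 1, 0.4); truth <- rbinom(25, 1, 0.6)
  expect_equal(sum(confusion(pred, truth)), 25)
  expect_error(confusion(c(0, 1), c(1)), "length")
  expect_error(confusion(c(0, 2), c(1, 1)), "0 or 1")
})

test_that("metrics reproduce the published 40-sample confusion matrix", {
  m <- eval_metrics(tp = 19, fn = 1, fp = 2, tn = 18)
  expect_equal(m$accuracy, 0.925)
  expect_equal(m$sensitivity, 0.95)
  expect_equal(m$specificity, 0.90)
  expect_equal(m$precision, 19 / 21, tolerance = 1e-12)
  expect_equal(m$f1, 38 / 41, tolerance = 1e-12)

  m2 <- eval_metrics(1, 1, 1, 1)
  expect_equal(unname(unlist(m2[c("sensitivity", "specificity", "accuracy",
                                  "f1", "precision")])), rep(0.5, 5))
  expect_true(is.na(eval_metrics(tp = 0, fp = 0, fn = 3, tn = 5)$precision))
  expect_error(eval_metrics(0, 0, 0, 0), "zero")
})

test_that("accuracy decomposes into class-weighted sensitivity/specificity", {
  set.seed(12)
  for (i in 1:1000) {
    cnt <- rpois(4, 5) + c(1, 0, 0, 1)  # keep both classes populated
    m <- eval_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    P <- cnt[1] + cnt[3]; N <- cnt[2] + cnt[4]
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the brute-force pairwise rank statistic", {
  set.seed(13)
  y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(50) + y
  s[5] <- s[6]  # force a tie
  auc <- roc_auc(s, y)$auc
  pos <- s[y == 1]; neg <- s[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc, mean(cmp), tolerance = 1e-12)

  expect_equal(roc_auc(c(-1, -2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  set.seed(14)
  y0 <- rbinom(2000, 1, 0.5); s0 <- rnorm(2000)
  expect_equal(roc_auc(s0, y0)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(rnorm(5), rep(1, 5)), "classes")
})
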