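test_that("contour extremes match analytic tangent points", {
  ex <- contour_extremes(ellipse_contour(a = 40, b = 20, cx = 100, cy = 100))
  expect_equal(unname(ex$top), c(100, 80), tolerance = 1e-3)
  expect_equal(unname(ex$bottom), c(100, 120), tolerance = 1e-3)
  expect_equal(unname(ex$leftmost), c(60, 100), tolerance = 1e-3)
  expect_equal(unname(ex$rightmost), c(140, 100), tolerance = 1e-3)
})

test_that("flat extreme runs resolve to the side midpoints", {
  sq <- bus_contour(c(seq(0, 10), rep(10, 9), seq(10, 0), rep(0, 9)),
                    c(rep(0, 11), seq(1, 9), rep(10, 11), seq(9, 1)))
  ex <- contour_extremes(sq)
  expect_equal(unname(ex$top), c(5, 0))
  expect_equal(unname(ex$bottom), c(5, 10))
  expect_equal(unname(ex$leftmost), c(0, 5))
  expect_equal(unname(ex$rightmost), c(10, 5))
})

test_that("extreme points lie on the contour polyline", {
  set.seed(3)
  for (i in 1:5) {
    ph <- generate_phantom(phantom_spec(aspect = runif(1, 0.5, 1),
                                        irregularity_amp = runif(1, 0, 0.3),
                                        seed = i))
    v <- ph$contour$vertices
    ex <- contour_extremes(ph$contour)
    for (p in ex) {
      d <- min(sqrt((v$x - p["x"])^2 + (v$y - p["y"])^2))
      expect_lt(d, 0.5)
    }
  }
})

test_that("orientation is the height/width ratio and scale invariant", {
  expect_equal(orientation_score(contour_extremes(circle_contour())), 1,
               tolerance = 1e-6)
  ell <- contour_extremes(ellipse_contour(a = 40, b = 20))
  expect_equal(orientation_score(ell), 0.5, tolerance = 1e-6)
  # uniform scaling and translation leave the ratio unchanged
  th <- seq(0, 2 * pi, length.out = 500)[-500]
  base <- bus_contour(50 + 30 * cos(th), 60 + 18 * sin(th))
  moved <- bus_contour(500 + 90 * cos(th), 640 + 54 * sin(th))
  expect_equal(orientation_score(contour_extremes(base)),
               orientation_score(contour_extremes(moved)), tolerance = 1e-9)
})

test_that("edge patches are exact m x n crops and reject clipping", {
  img <- matrix(runif(100 * 100), 100, 100)
  p <- ei_patch(img, c(x = 50, y = 40), m = 21, n = 15)
  expect_equal(dim(p$values), c(21, 15))
  expect_equal(p$values, img[30:50, 43:57])
  expect_error(ei_patch(img, c(x = 50, y = 5)), "top")
  expect_error(ei_patch(img, c(x = 50, y = 97)), "bottom")
  expect_error(ei_patch(img, c(x = 4, y = 50)), "left")
  expect_error(ei_patch(img, c(x = 98, y = 50)), "right")
})

test_that("patch score matches the hand-computed standard deviations", {
  p <- structure(list(values = matrix(c(0, 1, 0, 1), 2, 2)),
                 class = "bus_ei_patch")
  expect_equal(ei_score_patch(p), 0.5)  # column stds 0.5, row stds 0
  const <- structure(list(values = matrix(0.3, 5, 7)), class = "bus_ei_patch")
  expect_equal(ei_score_patch(const), 0)
  # homogeneity: scaling intensities by c scales the score by |c|
  set.seed(1)
  v <- matrix(runif(21 * 15), 21, 15)
  p1 <- structure(list(values = v), class = "bus_ei_patch")
  p3 <- structure(list(values = 3 * v), class = "bus_ei_patch")
  expect_equal(ei_score_patch(p3), 3 * ei_score_patch(p1), tolerance = 1e-12)
})

test_that("lesion EI score averages the top and bottom patch scores", {
  # vertically symmetric image: both patches identical
  img <- matrix(rep(seq(0, 1, length.out = 81), 81), 81, 81)
  img <- (img + t(img)) / 2
  img <- (img + img[81:1, ]) / 2
  ex <- contour_extremes(circle_contour(r = 20, cx = 41, cy = 41, n = 400))
  up <- ei_score_patch(ei_patch(img, ex$top))
  expect_equal(ei_score(img, ex), up, tolerance = 1e-12)
})

test_that("EI decreases as phantom edges blur", {
  scores <- vapply(c(0.5, 1, 2, 4), function(s) {
    ph <- generate_phantom(phantom_spec(edge_blur_sigma = s, seed = 5))
    ei_score(ph$image, contour_extremes(ph$contour))
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("posterior region is the rectangle below the lesion", {
  img <- matrix(seq(0, 1, length.out = 200 * 200), 200, 200)
  ex <- contour_extremes(ellipse_contour(a = 40, b = 20, cx = 100, cy = 100))
  reg <- ps_region(img, ex)
  expect_equal(dim(reg), c(40, 81))  # depth = lesion height, width = x_l..x_r
  expect_equal(reg, img[121:160, 60:140])
  shallow <- ps_region(img, ex, depth = 10)
  expect_equal(dim(shallow), c(10, 81))
  # lesion touching the image bottom leaves no posterior region
  ex_low <- contour_extremes(ellipse_contour(a = 40, b = 20, cx = 100, cy = 180))
  expect_error(ps_region(img, ex_low), "posterior")
})

test_that("Hu-moment score reproduces the hand example", {
  reg <- matrix(c(1, 0, 0, 1), 2, 2)
  mom <- hu_moments(reg)
  expect_equal(mom$m[1, 1], 2)            # m00
  expect_equal(unname(mom$centroid), c(1.5, 1.5))
  expect_equal(mom$mu[3, 1], 0.5)         # mu20
  expect_equal(mom$mu[1, 3], 0.5)         # mu02
  expect_equal(mom$eta[3, 1] + mom$eta[1, 3], 0.25)
  expect_equal(hu_ps_score(reg), -log10(0.25), tolerance = 1e-9)
  expect_error(hu_ps_score(matrix(0, 4, 4)), "m00")
})

test_that("eta20 + eta02 is translation invariant and upsampling stable", {
  set.seed(7)
  block <- matrix(runif(15 * 12), 15, 12)
  eta_sum <- function(reg) {
    m <- hu_moments(reg)
    m$eta[3, 1] + m$eta[1, 3]
  }
  a <- matrix(0, 60, 60); a[3:17, 5:16] <- block
  b <- matrix(0, 60, 60); b[31:45, 40:51] <- block
  expect_equal(eta_sum(a), eta_sum(b), tolerance = 1e-12)
  # 2x nearest-neighbour upsampling: rho-normalization keeps it within 2%
  up <- block[rep(seq_len(15), each = 2), rep(seq_len(12), each = 2)]
  expect_equal(eta_sum(up), eta_sum(block), tolerance = 0.02)
})

test_that("central moments vanish at first order", {
  set.seed(8)
  mom <- hu_moments(matrix(runif(90), 9, 10))
  expect_lt(abs(mom$mu[2, 1]), 1e-9)
  expect_lt(abs(mom$mu[1, 2]), 1e-9)
})

test_that("divider counts on a circle match the chord-angle closed form", {
  circ <- circle_contour(r = 50)
  tr <- divider_counts(circ, radii = 4:11)
  oracle <- vapply(4:11, function(R) ceiling(2 * pi / (2 * asin(R / 100))),
                   numeric(1))
  expect_true(all(abs(tr$N_R - oracle) <= 1))
  expect_true(all(diff(tr$N_R) <= 0))
  expect_error(divider_counts(circle_contour(r = 5), radii = 4:11), "extent")
})

test_that("divider counts decrease with radius and peak at the smallest", {
  tr <- bus_divider_example()
  expect_equal(tr$N_R[tr$R == 4], max(tr$N_R))
  expect_equal(tr$N_R[tr$R == 11], min(tr$N_R))
  expect_true(all(diff(tr$N_R) <= 0))
})

test_that("shape-complexity fit equals the closed-form regression oracle", {
  # exact power law N = 100 / R
  tr <- bus_divider_trace(R = c(4, 5, 10, 20), N_R = c(25, 20, 10, 5))
  fit <- sc_score(tr)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)

  tr2 <- bus_divider_example()
  fit2 <- sc_score(tr2)
  oracle <- ols_oracle(log10(tr2$R), log10(tr2$N_R))
  expect_equal(fit2$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(fit2$intercept, unname(oracle["intercept"]), tolerance = 1e-12)
  expect_equal(fit2$slope, -1.045, tolerance = 0.005)

  expect_error(sc_score(bus_divider_trace(R = c(4, 5), N_R = c(9, 7))),
               "3")
})

test_that("a smooth convex contour has fractal slope near -1", {
  ph <- generate_phantom(phantom_spec(base_radius = 30, aspect = 0.8, seed = 4))
  fit <- sc_score(divider_counts(ph$contour, radii = 4:11))
  expect_equal(fit$slope, -1, tolerance = 0.05)
})

test_that("characteristic features assemble in fixed order, deterministically", {
  ph <- generate_phantom(phantom_spec(seed = 10, speckle_looks = 16))
  cf1 <- characteristic_features(ph$image, ph$contour)
  cf2 <- characteristic_features(ph$image, ph$contour)
  expect_identical(names(cf1),
                   c("orientation", "ei_score", "ps_score", "sc_score"))
  expect_length(cf1, 4)
  expect_identical(cf1, cf2)
  expect_true(all(is.finite(cf1)))
})

test_that("malignant-like phantoms score taller and more complex than benign-like", {
  benign <- generate_phantom(phantom_spec(aspect = 0.55, irregularity_amp = 0.02,
                                          seed = 12, speckle_looks = 16))
  malignant <- generate_phantom(phantom_spec(aspect = 0.95, irregularity_amp = 0.28,
                                             base_radius = 24, seed = 12,
                                             speckle_looks = 16))
  cf_b <- characteristic_features(benign$image, benign$contour)
  cf_m <- characteristic_features(malignant$image, malignant$contour)
  expect_gt(cf_m[["orientation"]], cf_b[["orientation"]])
  expect_gt(abs(cf_m[["sc_score"]]), abs(cf_b[["sc_score"]]))
})

test_that("typical phantom PS scores bracket the published clinical range", {
  scores <- vapply(1:6, function(i) {
    ph <- generate_phantom(phantom_spec(seed = i, speckle_looks = 4,
                                        shadow_enabled = i %% 2 == 0,
                                        shadow_strength = 0.3))
    hu_ps_score(ps_region(ph$image, contour_extremes(ph$contour)) * 255)
  }, numeric(1))
  expect_true(all(scores > 1.5 & scores < 3.5))
})
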