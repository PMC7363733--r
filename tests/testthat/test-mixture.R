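test_that("monostable models give a single mode of weight one", {
  m <- model_preset("neg_fb_fig3", epsilon = 0.05)
  br <- cached_branch("neg_fb_fig3", n_grid = 1001L)
  mix <- mixture_approx(m, br)
  expect_identical(nrow(mix$modes), 1L)
  expect_equal(mix$modes$weight, 1)
  # active-protein marginal is exactly the truncated Poisson at x_0
  expect_equal(marginal_s(mix), qss_distribution(m, mix$modes$x_star),
               tolerance = 1e-12)
})

test_that("the discrete Gaussian marginal has the prescribed moments", {
  m <- model_preset("neg_fb_fig3", epsilon = 0.02)
  br <- cached_branch("neg_fb_fig3", n_grid = 1001L)
  mix <- mixture_approx(m, br, epsilon = 0.02)
  pX <- marginal_X(mix)
  X <- as.integer(names(pX))
  mu <- sum(X * pX)
  v <- sum(X^2 * pX) - mu^2
  expect_lt(abs(mu - mix$modes$x_star / 0.02), 1)
  expect_equal(v, 1 / (0.02 * mix$modes$curvature), tolerance = 0.02)
})

test_that("bistable weights are normalised and obey the ratio identity", {
  m <- model_preset("pos_fb_fig4")
  br <- cached_branch("pos_fb_fig4")
  mix <- mixture_approx(m, br, epsilon = 0.05)
  md <- mix$modes
  expect_identical(nrow(md), 2L)
  expect_equal(sum(md$weight), 1, tolerance = 1e-12)
  expect_true(all(md$weight > 0))
  ratio <- (md$prefactor_value[1] / md$prefactor_value[2]) *
    sqrt(md$curvature[2] / md$curvature[1]) *
    exp(-(md$phi[1] - md$phi[2]) / 0.05)
  expect_equal(md$weight[1] / md$weight[2], ratio, tolerance = 1e-10)
})

test_that("the deeper well takes all the weight as epsilon shrinks", {
  m <- model_preset("pos_fb_fig4")
  br <- cached_branch("pos_fb_fig4")
  # here Phi(x_minus) > Phi(x_plus): the upper mode dominates
  expect_gt(br$phi[br$fp_idx[1]], br$phi[br$fp_idx[3]])
  wplus <- vapply(c(0.1, 0.05, 0.02, 0.005), function(eps)
    mixture_approx(m, br, epsilon = eps)$modes$weight[2], numeric(1))
  expect_true(all(diff(wplus) > 0))
  expect_gt(wplus[4], 0.95)
})

test_that("weights depend only on potential differences", {
  m <- model_preset("pos_fb_fig4")
  br <- cached_branch("pos_fb_fig4")
  br_shift <- br
  br_shift$phi <- br$phi + 3.7
  w0 <- mixture_approx(m, br, epsilon = 0.05)$modes$weight
  w1 <- mixture_approx(m, br_shift, epsilon = 0.05)$modes$weight
  expect_equal(w1, w0, tolerance = 1e-12)
})

test_that("the joint mixture density is normalised and QSS-conditioned", {
  m <- model_preset("pos_fb_fig4", epsilon = 0.05)
  br <- cached_branch("pos_fb_fig4")
  mix <- mixture_approx(m, br, epsilon = 0.05)
  xs <- seq(0, 20, by = 0.01)
  total <- 0
  for (s in 0:m$s_max)
    total <- total + sum(joint_density(mix, xs, s)) * 0.01
  expect_equal(total, 1, tolerance = 1e-3)
  # conditional over s at a mode location equals the truncated Poisson
  x1 <- mix$modes$x_star[1]
  cond <- vapply(0:m$s_max, function(s) joint_density(mix, x1, s),
                 numeric(1))
  cond <- cond / sum(cond)
  expect_lt(tv_distance(cond, qss_distribution(m, x1)), 1e-3)
  # bistable X marginal is bimodal near x_pm / epsilon
  pX <- marginal_X(mix)
  X <- as.integer(names(pX))
  loc_max <- X[which(diff(sign(diff(pX))) == -2) + 1L]
  expect_length(loc_max, 2L)
  expect_true(all(abs(loc_max - mix$modes$x_star / 0.05) < 3))
})

test_that("total variation distance behaves like a metric on padded supports", {
  expect_equal(tv_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(tv_distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(tv_distance(c(0.5, 0.5), c(0.5, 0.25, 0.25)), 0.25)
})
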