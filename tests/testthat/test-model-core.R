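test_that("mean/Fano family pmfs reproduce their moments and MGF", {
  cases <- list(c(1, 0), c(4, 0), c(2, 0.5), c(1, 1), c(3, 1),
                c(1, 2), c(2, 1.5))
  for (cs in cases) {
    d <- burst_distribution(cs[1], cs[2])
    j <- d$support
    expect_equal(sum(d$pmf), 1, tolerance = 1e-10)
    expect_true(all(d$pmf >= 0))
    expect_equal(sum(j * d$pmf), cs[1], tolerance = 1e-9)
    v <- sum(j^2 * d$pmf) - sum(j * d$pmf)^2
    expect_equal(v, cs[2] * cs[1], tolerance = 1e-8)
    # closed-form MGF against direct pmf summation; positive theta
    # amplifies the truncated tail of unbounded pmfs (and the negative
    # binomial MGF only converges below log(F/(F-1))), so stay tight on
    # theta <= 0 and truncation-aware above
    tmax <- if (cs[2] > 1) 0.9 * log(cs[2] / (cs[2] - 1)) else 1
    for (th in seq(-2, 0, by = 0.5))
      expect_equal(burst_mgf(d, th),
                   sum(d$pmf * exp(j * th)), tolerance = 1e-9)
    for (th in c(0.5, 1)[c(0.5, 1) < tmax])
      expect_equal(burst_mgf(d, th),
                   sum(d$pmf * exp(j * th)), tolerance = 2e-3)
    expect_equal(burst_mgf(d, 0), 1, tolerance = 1e-12)
    expect_equal(burst_mgf(d, 0, 1), cs[1], tolerance = 1e-9)
    expect_equal(burst_mgf(d, 0, 2), cs[2] * cs[1] + cs[1]^2,
                 tolerance = 1e-8)
  }
})

test_that("family special cases match their textbook forms", {
  # binomial: mean 2, Fano 0.5 -> Binomial(4, 1/2)
  b <- burst_distribution(2, 0.5)
  expect_identical(b$family, "binomial")
  expect_equal(b$pmf, c(1, 4, 6, 4, 1) / 16, tolerance = 1e-12)
  # fixed burst: point mass, MGF e^{B theta}
  f4 <- burst_distribution(4, 0)
  expect_equal(f4$pmf, c(0, 0, 0, 0, 1))
  expect_equal(burst_mgf(f4, 0.5), exp(2), tolerance = 1e-12)
  f1 <- burst_distribution(1, 0)
  expect_equal(which(f1$pmf == 1) - 1L, 1L)
  # geometric: Fano = 1 + mean, MGF (1 + <B>(1 - e^theta))^(-1)
  g <- burst_distribution(1.5, 2.5)
  for (th in c(-1, -0.3, 0, 0.2))
    expect_equal(burst_mgf(g, th), 1 / (1 + 1.5 * (1 - exp(th))),
                 tolerance = 1e-12)
})

test_that("family pmf converges to the Poisson pmf as Fano -> 1", {
  lam <- 2
  pois <- burst_distribution(lam, 1)
  # fano = 1 -/+ 1e-6: binomial with 2e6 trials / negative binomial with
  # size 2e6, both within a hair of the Poisson limit
  for (fano in c(1 - 1e-6, 1 + 1e-6)) {
    d <- burst_distribution(lam, fano)
    k <- 0:8
    expect_equal(d$pmf[k + 1L], pois$pmf[k + 1L], tolerance = 1e-5)
  }
})

test_that("invalid burst parameters are rejected; fractional binomial is MGF-only", {
  expect_error(burst_distribution(-1, 0), "positive")
  expect_error(burst_distribution(1, -0.5), "non-negative")
  expect_error(burst_distribution(2.5, 0), "integer")
  # mean 1, Fano 0.25: trial count 4/3 -> analytic family, no pmf
  d <- burst_distribution(1, 0.25)
  expect_null(d$pmf)
  expect_equal(burst_mgf(d, 0), 1, tolerance = 1e-14)
  expect_equal(burst_mgf(d, 0, 1), 1, tolerance = 1e-12)
  m <- burst_model(d, list(s_thresh = 6, a0 = 2, a1 = 10))
  expect_error(cme_generator(m, 10), "pmf")
  expect_error(ssa_simulate(m, t_end = 1), "pmf")
  # explicit pmf path
  e <- burst_distribution(pmf = c(0.25, 0.5, 0.25))
  expect_identical(e$family, "explicit")
  expect_equal(e$mean, 1)
  expect_equal(burst_mgf(e, 0.3), sum(c(0.25, 0.5, 0.25) * exp(0:2 * 0.3)))
})

test_that("step responses handle interior and out-of-range thresholds", {
  r <- step_response(20, 6, a0 = 2, a1 = 10)
  expect_length(r$rates, 21L)
  expect_equal(r$rates[6], 2)   # s = 5
  expect_equal(r$rates[7], 10)  # s = 6
  expect_equal(step_response(20, 0, 7, 3)$rates, rep(3, 21))
  expect_equal(step_response(20, 21, 7, 3)$rates, rep(7, 21))
  expect_error(step_response(20, 6, -1, 3), "non-negative")
  expect_error(step_response(20, 25, 1, 3), "s_thresh")
})

test_that("the cap rule doubles the maximal mean production rate", {
  expect_identical(choose_smax(burst_distribution(1, 0), 10), 20L)
  expect_identical(choose_smax(burst_distribution(4, 0), 2.5), 20L)
  expect_identical(choose_smax(burst_distribution(1, 0), 0.5), 1L)
  expect_error(choose_smax(burst_distribution(1, 0), 0), "positive")
})

test_that("model construction validates and auto-sizes the cap", {
  m <- burst_model(burst_distribution(1, 0),
                   list(s_thresh = 6, a0 = 2, a1 = 10), epsilon = 0.05)
  expect_identical(m$s_max, 20L)
  expect_length(m$feedback$rates, m$s_max + 1L)
  expect_error(burst_model(burst_distribution(1, 0),
                           list(s_thresh = 6, a0 = 2, a1 = 10),
                           epsilon = 0), "epsilon")
  expect_error(burst_model(burst_distribution(1, 0),
                           feedback_response(c(1, 2, 3)), s_max = 5),
               "s_max")
})

test_that("model configurations round-trip through YAML", {
  m <- model_preset("neg_fb_fig3", epsilon = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(m, path)
  m2 <- read_model_config(path)
  expect_equal(m2$feedback$rates, m$feedback$rates)
  expect_equal(m2$burst$pmf, m$burst$pmf)
  expect_equal(m2$epsilon, m$epsilon)
  expect_identical(m2$s_max, m$s_max)
  # explicit-table model round-trips too
  me <- burst_model(burst_distribution(pmf = c(0.5, 0.5)),
                    feedback_response(c(1, 2, 0.5)), epsilon = 0.2)
  write_model_config(me, path)
  me2 <- read_model_config(path)
  expect_equal(me2$feedback$rates, me$feedback$rates)
  expect_equal(me2$burst$pmf, me$burst$pmf)
  # malformed config names the offending key
  writeLines("burst:\n  mean: 1\nmodel:\n  epsilon: 0.1", path)
  expect_error(read_model_config(path), "feedback")
  writeLines(
    "burst:\n  mean: 1\nfeedback:\n  s_thresh: 6\n  a0: 1\nmodel:\n  epsilon: 0.1",
    path)
  expect_error(read_model_config(path), "a1")
})
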