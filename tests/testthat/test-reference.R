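test_that("the lattice generator is a proper rate matrix", {
  m <- model_preset("neg_fb_fig3", epsilon = 0.1)
  G <- cme_generator(m, X_max = 40)
  expect_identical(dim(G), rep((m$s_max + 1L) * 41L, 2))
  expect_lt(max(abs(Matrix::colSums(G))), 1e-12)
  offdiag <- G
  Matrix::diag(offdiag) <- 0
  expect_true(min(offdiag) >= 0)
  expect_error(cme_generator(m, 1e6), "guard")
})

test_that("a silenced gene collapses the steady state onto the origin", {
  m <- burst_model(burst_distribution(1, 0), feedback_response(rep(0, 6)),
                   epsilon = 0.1)
  sol <- cme_steady_state(m, X_max = 5)
  expect_equal(sol$probs[1, 1], 1, tolerance = 1e-12)
  expect_equal(sum(sol$probs), 1, tolerance = 1e-12)
})

test_that("the CME nullvector is an accurate stationary distribution", {
  m <- model_preset("neg_fb_fig3", epsilon = 0.1)
  sol <- cme_steady_state(m)
  expect_equal(sum(sol$probs), 1, tolerance = 1e-12)
  expect_true(all(sol$probs >= 0))
  expect_lt(sol$residual, 1e-10)
  expect_lt(sol$boundary_mass, 1e-6)
  # doubling the truncation leaves the s-marginal unchanged
  sol2 <- cme_steady_state(m, X_max = 2L * sol$X_max)
  expect_lt(tv_distance(marginal_s(sol), marginal_s(sol2)), 1e-8)
})

test_that("the bistable CME marginals are bimodal at the fixed points", {
  eps <- 0.02  # modes well separated; at eps = 0.05 the weak upper
               # s-mode survives only as a shoulder
  m <- model_preset("pos_fb_fig4", epsilon = eps)
  fp <- fixed_points(m)
  sol <- cme_steady_state(m)
  ps <- marginal_s(sol)
  s <- seq_along(ps) - 1L
  loc_max <- s[which(diff(sign(diff(ps))) == -2) + 1L]
  expect_identical(length(loc_max), 2L)
  expect_true(all(abs(sort(loc_max) - fp$x[fp$stable]) < 1.5))
  pX <- marginal_X(sol)
  X <- as.integer(names(pX))
  Xmax_loc <- X[which(diff(sign(diff(pX))) == -2) + 1L]
  expect_true(all(abs(sort(Xmax_loc) - fp$x[fp$stable] / eps) < 12))
})

test_that("Gillespie runs respect the cap and are seed-reproducible", {
  m <- model_preset("neg_fb_fig3", epsilon = 0.1)
  r1 <- ssa_simulate(m, t_end = 30, burn_in = 2, seed = 99)
  r2 <- ssa_simulate(m, t_end = 30, burn_in = 2, seed = 99)
  expect_identical(r1$probs, r2$probs)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(r1$trace$s <= m$s_max))
  expect_true(all(r1$trace$X >= 0))
  expect_true(all(diff(r1$trace$t) > 0))
  expect_equal(sum(r1$probs), 1, tolerance = 1e-12)
  r3 <- ssa_simulate(m, t_end = 30, burn_in = 2, seed = 100)
  expect_false(identical(r1$probs, r3$probs))
})

test_that("SSA occupancy approaches the CME solution", {
  m <- model_preset("neg_fb_fig3", epsilon = 0.1)
  cme <- cme_steady_state(m)
  ssa <- ssa_simulate(m, t_end = 2000, burn_in = 50, seed = 7)
  K <- min(nrow(ssa$probs), cme$X_max + 1L)
  tv <- tv_distance(as.numeric(ssa$probs[seq_len(K), ]),
                    as.numeric(cme$probs))
  expect_lt(tv, 0.1)  # a short run; the deep check runs in acceptance
  expect_gt(ssa$events, 1e5)
})

test_that("burst sampling follows the pmf inside the simulator", {
  # geometric bursts: compare simulated production increments with b_j
  m <- burst_model(burst_distribution(2, 3),
                   feedback_response(rep(4, 11)), epsilon = 0.2)
  r <- ssa_simulate(m, t_end = 400, burn_in = 0, seed = 123)
  jumps <- diff(r$trace$X)
  jumps <- jumps[jumps > 0]  # production events with j >= 1
  expect_gt(length(jumps), 500)
  d <- m$burst$pmf
  pj <- d[-1L] / sum(d[-1L])  # burst pmf conditioned on j >= 1
  emp <- tabulate(jumps, nbins = length(d) - 1L)
  emp <- emp / sum(emp)
  expect_lt(tv_distance(emp, pj), 0.05)
})
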