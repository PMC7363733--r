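test_that("saddle linearisation matches the analytic and differenced forms", {
  m <- model_preset("pos_fb_fig4")
  fp <- fixed_points(m)
  for (xs in fp$x) {
    sd <- saddle_linearization(m, xs)
    # mixed derivative is the stability eigenvalue of the rate equation
    expect_equal(sd$H_xtheta,
                 m$burst$mean * effective_rate_deriv(m, xs) - 1,
                 tolerance = 1e-12)
    # second theta-derivative against a central second difference of H
    h <- 1e-3
    fd <- (hamiltonian(m, xs, h) - 2 * hamiltonian(m, xs, 0) +
             hamiltonian(m, xs, -h)) / h^2
    expect_equal(sd$H_thetatheta, fd, tolerance = 1e-4)
    expect_equal(sd$slope, -2 * sd$H_xtheta / sd$H_thetatheta,
                 tolerance = 1e-12)
    # consistency of the singular solve
    A0 <- operator_matrix(m, xs, 0)
    rhs <- -operator_dtheta(m, xs, 0) %*% qss_distribution(m, xs)
    expect_lt(max(abs(A0 %*% sd$v_tilde - rhs)), 1e-9)
    expect_lt(abs(sum(sd$v_tilde)), 1e-9)
  }
  expect_error(saddle_linearization(m, 3.3), "not a fixed point")
})

test_that("the curvature formula is gauge invariant in v_tilde", {
  m <- model_preset("pos_fb_fig4")
  xs <- fixed_points(m)$x[1]
  sd <- saddle_linearization(m, xs)
  rho <- qss_distribution(m, xs)
  dAt <- operator_dtheta(m, xs, 0)
  B2 <- burst_mgf(m$burst, 0, 2L)
  for (cc in c(-1, 1, 10)) {
    vt <- sd$v_tilde + cc * rho
    Htt <- xs * (1 + B2 / m$burst$mean) + 2 * sum(dAt %*% vt)
    expect_equal(Htt, sd$H_thetatheta, tolerance = 1e-9)
  }
})

test_that("the traced branch is the Lyapunov zero-level set", {
  m <- model_preset("pos_fb_fig4")
  br <- cached_branch("pos_fb_fig4")
  # theta vanishes exactly at the fixed points, is continuous between
  expect_equal(br$theta[br$fp_idx], rep(0, 3))
  expect_lt(max(abs(diff(br$theta))), 0.1)
  # the whole branch lies on the zero-level set of H
  expect_lt(max(abs(br$H_resid)), 1e-6)
  # potential derivative opposes the deterministic flow off fixed points
  off <- setdiff(seq_along(br$grid), br$fp_idx)
  rhs <- rate_rhs(m, br$grid[off])
  expect_true(all(br$theta[off] * rhs < 0))
  # branch slope at each saddle matches the linearisation within 1%
  for (j in seq_along(br$fp_idx)) {
    i0 <- br$fp_idx[j]
    fd <- (br$theta[i0 + 1L] - br$theta[i0 - 1L]) /
      (br$grid[i0 + 1L] - br$grid[i0 - 1L])
    expect_equal(fd, br$saddles[[j]]$slope, tolerance = 0.01)
  }
})

test_that("the potential has the double-well / single-well geometry", {
  br4 <- cached_branch("pos_fb_fig4")
  idx <- br4$fp_idx
  # local minima at stable, maximum at unstable fixed points
  expect_lt(br4$phi[idx[1]], br4$phi[idx[2]])
  expect_gt(br4$phi[idx[2]], br4$phi[idx[3]])
  expect_equal(min(br4$phi[idx[c(1, 3)]]), 0)
  expect_true(all(br4$phi2[idx[c(1, 3)]] > 0))
  expect_lt(br4$phi2[idx[2]], 0)
  # monostable: decreasing then increasing with the minimum at x_0
  br3 <- cached_branch("neg_fb_fig3", n_grid = 1001L)
  i0 <- br3$fp_idx[1]
  expect_true(all(diff(br3$phi[1:i0]) < 0))
  expect_true(all(diff(br3$phi[i0:length(br3$phi)]) > 0))
  expect_equal(br3$phi[i0], 0)
})

test_that("the potential flattens as production becomes burstier", {
  # same rate equation, 4x burst size and a quarter the frequency
  d1 <- well_depths(cached_branch("pos_fb_fig1"))
  d4 <- well_depths(cached_branch("pos_fb_fig4"))
  expect_length(d1, 2L)
  expect_true(all(d4 < d1))
})

test_that("the prefactor satisfies its solvability condition", {
  m <- model_preset("pos_fb_fig4")
  br <- cached_branch("pos_fb_fig4")
  expect_true(all(br$k > 0))
  expect_equal(br$k[br$fp_idx[1]], 1)  # gauge at the leftmost stable point
  # substitute k back into the first-order equation
  kp <- burstwkb:::fd_gradient(br$grid, br$k)
  num <- br$integrand * br$denom
  res <- abs(kp * br$denom + br$k * num) / max(abs(br$k * num))
  ok <- rep(TRUE, length(res))
  for (j in br$fp_idx)
    ok[max(1, j - 5L):min(length(res), j + 5L)] <- FALSE
  ok[1:20] <- FALSE
  ok[(length(res) - 19L):length(res)] <- FALSE
  expect_lt(max(res[ok]), 1e-3)
  # sum_s l_s alpha_s is H_theta along the branch
  i <- seq(25, length(br$grid) - 25L, by = 150)
  ht <- vapply(i, function(j)
    unname(grad_hamiltonian(m, br$grid[j], br$theta[j])["H_theta"]),
    numeric(1))
  expect_equal(br$denom[i], ht, tolerance = 1e-6)
})

test_that("conditional distributions equal the QSS only at critical points", {
  m <- model_preset("pos_fb_fig4")
  br <- cached_branch("pos_fb_fig4")
  fp <- br$fps
  for (xs in fp$x)
    expect_lt(max(abs(conditional_distribution(br, xs) -
                        qss_distribution(m, xs))), 1e-6)
  xm <- mean(fp$x[1:2])  # non-critical
  wm <- conditional_distribution(br, xm)
  expect_equal(sum(wm), 1, tolerance = 1e-12)
  expect_gt(tv_distance(wm, qss_distribution(m, xm)), 1e-3)
  expect_error(conditional_distribution(br, max(br$grid) + 1), "outside")
})

test_that("branch tables export with the documented columns", {
  br <- cached_branch("neg_fb_fig3", n_grid = 1001L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_branch(br, path)
  tab <- read.delim(path)
  expect_identical(names(tab)[1:4], c("x", "theta", "phi", "k"))
  expect_identical(ncol(tab), 4L + 21L)
  expect_equal(tab$phi, br$phi, tolerance = 1e-9)
})
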