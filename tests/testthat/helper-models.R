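# shared fixtures and small numerical helpers

# a small cheap model for operator-level checks: s_max = 5
tiny_model <- function(theta_feedback = c(2, 2, 2, 5, 5, 5), epsilon = 0.1,
                       mean = 2, fano = 0.5) {
  burst_model(burst_distribution(mean, fano),
              feedback_response(theta_feedback), epsilon = epsilon)
}

# classical fourth-order Runge-Kutta for the Hamiltonian flow
rk4_flow <- function(model, x, theta, dt, nstep) {
  z <- c(x, theta)
  f <- function(z) unname(hamiltonian_flow(model, z[1], z[2]))
  for (i in seq_len(nstep)) {
    k1 <- f(z); k2 <- f(z + dt / 2 * k1); k3 <- f(z + dt / 2 * k2)
    k4 <- f(z + dt * k3)
    z <- z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  z
}

# branches are expensive; build each regime once per test run
branch_cache <- new.env(parent = emptyenv())
cached_branch <- function(preset, n_grid = 2001L) {
  key <- paste0(preset, "_", n_grid)
  if (is.null(branch_cache[[key]]))
    branch_cache[[key]] <- wkb_branch(model_preset(preset),
                                      n_grid = n_grid)
  branch_cache[[key]]
}
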