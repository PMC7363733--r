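#' Gaussian/Poisson mixture approximation of the stationary distribution
#'
#' Laplace expansion of the WKB solution around the minima of the
#' quasipotential. Each stable fixed point `x_*` contributes one mode: the
#' inactive protein is Gaussian with mean `x_*/epsilon` and variance
#' `1/(epsilon * Phi''(x_*))` in copy-number units, the active protein a
#' truncated Poisson `rho_s(x_*)`. The mode weights are
#' \deqn{\omega_* = \frac{C\,k(x_*)}{\sqrt{\Phi''(x_*)}}
#'   \exp(-\Phi(x_*)/\varepsilon),}
#' with `C` fixed by `sum(omega) = 1`. A monostable rate equation gives a
#' single mode of weight 1; with more stable fixed points each contributes
#' a term (the paper cases are one and two).
#'
#' @inheritParams operator_matrix
#' @param branch a fully filled `wkb_branch` (see [wkb_branch()]);
#'   computed if `NULL`.
#' @param epsilon timescale parameter; defaults to `model$epsilon`.
#' @return an object of class `mixture_approx`: list with `modes` (data
#'   frame with columns `x_star`, `phi`, `curvature`, `prefactor_value`,
#'   `weight`), `epsilon`, `C`, and the generating `model`/`branch`.
#' @examples
#' \donttest{
#' m <- model_preset("pos_fb_fig4", epsilon = 0.05)
#' mix <- mixture_approx(m)
#' mix$modes
#' }
#' @export
mixture_approx <- function(model, branch = NULL, epsilon = model$epsilon) {
  stopifnot(inherits(model, "burst_model"))
  if (is.null(branch)) branch <- wkb_branch(model)
  stopifnot(!is.null(branch$phi), !is.null(branch$k))
  idx <- branch$fp_idx[branch$fps$stable]
  if (length(idx) == 0) stop("no stable fixed point")
  curv <- branch$phi2[idx]
  if (any(curv <= 0))
    stop("non-positive potential curvature at a stable fixed point")
  raw <- branch$k[idx] / sqrt(curv) * exp(-branch$phi[idx] / epsilon)
  C <- 1 / sum(raw)
  modes <- data.frame(x_star = branch$grid[idx], phi = branch$phi[idx],
                      curvature = curv, prefactor_value = branch$k[idx],
                      weight = raw * C)
  out <- list(modes = modes, epsilon = epsilon, C = C, model = model,
              branch = branch)
  class(out) <- "mixture_approx"
  out
}

#' @export
#' @method print mixture_approx
print.mixture_approx <- function(x, ...) {
  cat("Gaussian/Poisson mixture approximation (epsilon =", x$epsilon,
      ")\n")
  print(x$modes, digits = 4)
  invisible(x)
}

#' Marginal distributions of a steady-state approximation or solution
#'
#' `marginal_s()` returns the stationary marginal of the active-protein
#' copy number `s = 0..s_max`; `marginal_X()` the marginal of the
#' inactive-protein copy number on an integer grid. Methods exist for the
#' WKB [mixture_approx()] (mixture of truncated Poissons / of discretised
#' Gaussians), for the truncated-CME [cme_steady_state()] solution, and
#' for an SSA occupancy histogram ([ssa_simulate()]).
#'
#' @param object a `mixture_approx`, `lattice_distribution` or `ssa_result`.
#' @param ... passed to methods; `marginal_X.mixture_approx()` accepts
#'   `X_grid`, the integer copy-number grid (default
#'   `0 .. 4*ceiling(max(x_star)/epsilon)`, matching the CME lattice).
#' @return a numeric probability vector; for `marginal_X` it carries the
#'   grid as names.
#' @export
marginal_s <- function(object, ...) UseMethod("marginal_s")

#' @rdname marginal_s
#' @export
marginal_X <- function(object, ...) UseMethod("marginal_X")

#' @export
marginal_s.mixture_approx <- function(object, ...) {
  m <- object$modes
  out <- 0
  for (i in seq_len(nrow(m)))
    out <- out + m$weight[i] *
      qss_distribution(object$model, m$x_star[i])
  out
}

#' @export
marginal_X.mixture_approx <- function(object, X_grid = NULL, ...) {
  m <- object$modes
  eps <- object$epsilon
  if (is.null(X_grid))
    X_grid <- 0:(4L * ceiling(max(m$x_star) / eps))
  dens <- 0
  for (i in seq_len(nrow(m)))
    dens <- dens + m$weight[i] *
      dnorm(X_grid, mean = m$x_star[i] / eps,
            sd = sqrt(1 / (eps * m$curvature[i])))
  dens <- dens / sum(dens)
  names(dens) <- X_grid
  dens
}

#' Joint WKB mixture density
#'
#' Evaluates the mixture approximation of the stationary joint density
#' `p(x, s)`: a sum over modes of
#' `weight * rho_s(x_star) * Normal(x; x_star, epsilon/Phi''(x_star))`.
#' Continuous in the concentration `x`, discrete in `s`.
#'
#' @param mix a [mixture_approx()].
#' @param x concentration (vectorised).
#' @param s active-protein count in `0..s_max` (scalar).
#' @return density values, same length as `x`.
#' @export
joint_density <- function(mix, x, s) {
  stopifnot(inherits(mix, "mixture_approx"))
  if (length(s) != 1L || s < 0 || s > mix$model$s_max)
    stop("s must be a single value in 0..s_max")
  m <- mix$modes
  out <- 0
  for (i in seq_len(nrow(m))) {
    rho <- qss_distribution(mix$model, m$x_star[i])
    out <- out + m$weight[i] * rho[s + 1L] *
      dnorm(x, mean = m$x_star[i],
            sd = sqrt(mix$epsilon / m$curvature[i]))
  }
  out
}

#' Total variation distance between two probability vectors
#'
#' Half the l1 distance. Vectors are compared elementwise over the longer
#' support, padding the shorter with zeros (so distributions on different
#' lattice truncations can be compared directly).
#'
#' @param p,q non-negative vectors summing to (approximately) 1.
#' @return a scalar in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  sum(abs(p - q)) / 2
}
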