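#' WKB steady-state analysis of a delayed-feedback bursty model
#'
#' The main driver. Runs the full slow-activation analysis: fixed points
#' of the emergent rate equation, saddle linearisations, the nontrivial
#' zero-level branch of the Hamiltonian (quasipotential derivative), the
#' potential and prefactor, and the Gaussian/Poisson mixture approximation
#' of the stationary joint distribution with WKB mode weights.
#'
#' @inheritParams operator_matrix
#' @param epsilon timescale parameter; defaults to `model$epsilon`.
#' @param n_grid branch grid size.
#' @param margin outer branch margin (see [trace_branch()]).
#' @return an object of class `wkb_fit` with components `model`,
#'   `epsilon`, `fps` ([fixed_points()] table), `branch` (filled
#'   [wkb_branch()]) and `mixture` ([mixture_approx()]). Supports
#'   `print()`, `summary()`, `coef()` (mode locations, weights,
#'   curvatures), `predict()` (marginal/joint densities and the
#'   potential), `plot()` and `simulate()` (Gillespie paths).
#' @examples
#' \donttest{
#' fit <- wkb_steady_state(model_preset("pos_fb_fig4", epsilon = 0.05))
#' summary(fit)
#' coef(fit)
#' }
#' @export
wkb_steady_state <- function(model, epsilon = model$epsilon,
                             n_grid = 2001L, margin = NULL) {
  stopifnot(inherits(model, "burst_model"))
  fps <- fixed_points(model)
  branch <- wkb_branch(model, fps = fps, margin = margin, n_grid = n_grid)
  mixture <- mixture_approx(model, branch, epsilon = epsilon)
  out <- list(model = model, epsilon = epsilon, fps = fps,
              branch = branch, mixture = mixture)
  class(out) <- "wkb_fit"
  out
}

#' @export
#' @method print wkb_fit
print.wkb_fit <- function(x, ...) {
  nstab <- sum(x$fps$stable)
  cat("WKB steady-state analysis (epsilon = ", x$epsilon, ")\n", sep = "")
  cat("  regime:", if (nstab == 1) "monostable" else
    paste0(nstab, "-modal"), "\n")
  cat("  modes (x_star, weight):\n")
  m <- x$mixture$modes
  for (i in seq_len(nrow(m)))
    cat(sprintf("    x = %.4f   omega = %.4f\n", m$x_star[i],
                m$weight[i]))
  invisible(x)
}

#' @export
#' @method summary wkb_fit
summary.wkb_fit <- function(object, ...) {
  out <- list(epsilon = object$epsilon, fps = object$fps,
              modes = object$mixture$modes,
              H_resid = max(abs(object$branch$H_resid)),
              well_depths = well_depths(object$branch))
  class(out) <- "summary.wkb_fit"
  out
}

#' @export
#' @method print summary.wkb_fit
print.summary.wkb_fit <- function(x, ...) {
  cat("Fixed points of the rate equation:\n")
  print(as.data.frame(x$fps), digits = 5)
  cat("\nMixture modes (epsilon =", x$epsilon, "):\n")
  print(x$modes, digits = 5)
  if (length(x$well_depths))
    cat("\nPotential well depths:",
        paste(format(x$well_depths, digits = 4), collapse = ", "), "\n")
  cat("max |H| along branch:", format(x$H_resid, digits = 3), "\n")
  invisible(x)
}

#' @export
coef.wkb_fit <- function(object, ...) {
  m <- object$mixture$modes
  stats::setNames(
    c(m$x_star, m$weight, m$curvature),
    c(paste0("x_star", seq_len(nrow(m))),
      paste0("weight", seq_len(nrow(m))),
      paste0("curvature", seq_len(nrow(m)))))
}

#' Predict stationary densities from a WKB fit
#'
#' @param object a [wkb_steady_state()] fit.
#' @param type `"marginal_X"` (inactive-protein copy-number pmf on an
#'   integer grid), `"marginal_s"` (active-protein pmf),
#'   `"joint"` (density at concentration `x` and count `s`), or
#'   `"potential"` (quasipotential interpolated at `x`).
#' @param x,s evaluation points for `"joint"`/`"potential"`.
#' @param X_grid integer grid for `"marginal_X"`.
#' @param ... unused.
#' @return a numeric vector (named by state for the marginals).
#' @export
predict.wkb_fit <- function(object,
                            type = c("marginal_X", "marginal_s",
                                     "joint", "potential"),
                            x = NULL, s = NULL, X_grid = NULL, ...) {
  type <- match.arg(type)
  switch(type,
    marginal_X = marginal_X(object$mixture, X_grid = X_grid),
    marginal_s = marginal_s(object$mixture),
    joint = {
      if (is.null(x) || is.null(s))
        stop("type = 'joint' needs x and s")
      joint_density(object$mixture, x, s)
    },
    potential = {
      if (is.null(x)) stop("type = 'potential' needs x")
      stats::approx(object$branch$grid, object$branch$phi, xout = x)$y
    })
}

#' @export
plot.wkb_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  br <- x$branch
  plot(br$grid, br$phi, type = "l", xlab = "concentration x",
       ylab = expression(Phi(x)), main = "WKB potential")
  abline(v = x$fps$x, lty = ifelse(x$fps$stable, 2, 3), col = "grey50")
  pX <- marginal_X(x$mixture)
  plot(as.integer(names(pX)), pX, type = "l", xlab = "copy number X",
       ylab = "probability", main = "inactive-protein marginal")
  abline(v = x$fps$x[x$fps$stable] / x$epsilon, lty = 2, col = "grey50")
  invisible(x)
}

#' Simulate Gillespie paths from a fitted model
#'
#' Runs the exact stochastic simulation of the underlying reaction
#' channels at the fit's `epsilon`. With `nsim > 1` returns a list of
#' independent runs.
#'
#' @param object a `wkb_fit`.
#' @param nsim number of runs.
#' @param seed optional seed (applies once, before all runs).
#' @param t_end,burn_in simulation horizon, passed to [ssa_simulate()].
#' @param ... further arguments to [ssa_simulate()].
#' @return an `ssa_result`, or a list of them when `nsim > 1`.
#' @export
simulate.wkb_fit <- function(object, nsim = 1, seed = NULL, t_end = 100,
                             burn_in = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(seq_len(nsim), function(i)
    ssa_simulate(object$model, t_end = t_end, burn_in = burn_in,
                 epsilon = object$epsilon, ...))
  if (nsim == 1) runs[[1]] else runs
}

#' Potential well depths
#'
#' For each stable fixed point, the barrier height from the well bottom to
#' the lowest unstable maximum of the quasipotential. Well depths quantify
#' mode stability: they shrink as production becomes more bursty (larger
#' burst size at fixed mean production, or larger burst-size Fano factor),
#' even though the deterministic rate equation is unchanged.
#'
#' @param branch a `wkb_branch` with `phi` filled.
#' @return named numeric vector, one entry per stable fixed point
#'   (empty for a monostable potential, which has no barrier).
#' @export
well_depths <- function(branch) {
  stopifnot(!is.null(branch$phi))
  fp <- branch$fps
  idx <- branch$fp_idx
  depths <- numeric(0)
  for (j in which(fp$stable)) {
    phi0 <- branch$phi[idx[j]]
    barriers <- branch$phi[idx[!fp$stable]]
    if (length(barriers) == 0) next
    depths <- c(depths, min(barriers) - phi0)
  }
  stats::setNames(depths, fp$role[fp$stable][seq_along(depths)])
}
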