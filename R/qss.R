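#' Quasi-steady-state distribution of the active protein
#'
#' At a frozen inactive-protein concentration `x`, the active protein is a
#' birth-death process with constant birth rate `x` (while `s < s_max`) and
#' linear death rate `s` — the M/M/s_max/s_max loss queue. Its equilibrium
#' is the truncated Poisson distribution
#' \deqn{\rho_s(x) = \mathcal{N}(x)\, x^s / s!,\quad s = 0..s_{max}.}
#' Computed in log space (log-factorial accumulation with log-sum-exp
#' normalisation), so large `x` does not overflow. The top cell
#' `rho_smax(x)` is Erlang's loss formula.
#'
#' @inheritParams operator_matrix
#' @return numeric probability vector of length `s_max + 1`.
#' @export
qss_distribution <- function(model, x) {
  stopifnot(inherits(model, "burst_model"))
  if (x < 0) stop("x must be non-negative")
  s <- 0:model$s_max
  if (x == 0) return(c(1, rep(0, model$s_max)))
  lw <- s * log(x) - lfactorial(s)
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Effective (mollified) burst frequency and the emergent rate equation
#'
#' `effective_rate()` averages the instantaneous burst frequency `f_s` over
#' the quasi-steady-state distribution:
#' \eqn{\bar f(x) = \sum_s f_s \rho_s(x)}. Averaging smooths ("mollifies")
#' sharp features of `f_s`; a step response becomes a smooth sigmoid.
#' `effective_rate_deriv()` evaluates the exact derivative
#' \deqn{\bar f'(x) = \sum_{s<s_{max}} (f_{s+1}-f_s)\rho_s(x)
#'   + (\bar f(x) - f_{s_{max}})\rho_{s_{max}}(x).}
#' `rate_rhs()` is the right-hand side \eqn{\langle B\rangle\bar f(x) - x}
#' of the deterministic rate equation that governs the inactive-protein
#' concentration in the slow-activation limit.
#'
#' @inheritParams operator_matrix
#' @param x concentration(s); all three functions are vectorised in `x`.
#' @return numeric vector of the same length as `x`.
#' @export
effective_rate <- function(model, x) {
  f <- model$feedback$rates
  vapply(x, function(xi) sum(f * qss_distribution(model, xi)), numeric(1))
}

#' @rdname effective_rate
#' @export
effective_rate_deriv <- function(model, x) {
  f <- model$feedback$rates
  n <- model$s_max + 1L
  vapply(x, function(xi) {
    rho <- qss_distribution(model, xi)
    fbar <- sum(f * rho)
    sum((f[-1L] - f[-n]) * rho[-n]) + (fbar - f[n]) * rho[n]
  }, numeric(1))
}

#' @rdname effective_rate
#' @export
rate_rhs <- function(model, x) {
  model$burst$mean * effective_rate(model, x) - x
}

#' Fixed points of the emergent rate equation
#'
#' Locates all roots of \eqn{\langle B\rangle\bar f(x) - x = 0} on
#' `[0, x_upper]` by a sign-change scan on a uniform grid followed by
#' Brent refinement and a Newton polish, and classifies each root as
#' stable or unstable via the sign of \eqn{\langle B\rangle\bar f'(x_*)-1}.
#' Roles follow the one-dimensional phase-line structure: a single stable
#' root is the monostable state `x_0`; a stable-unstable-stable triple is
#' `(x_minus, x_zero, x_plus)`.
#'
#' Exactly tangent (double) roots are degenerate for the downstream WKB
#' construction and raise an error rather than being classified.
#'
#' @inheritParams operator_matrix
#' @param x_upper upper end of the search bracket; defaults to
#'   `2 * <B> * max(f)`, above which the decay term dominates.
#' @param n_scan grid size of the sign-change scan.
#' @return a data frame of class `fixed_points` with columns `x`, `stable`
#'   (logical), `lambda` (the stability eigenvalue
#'   \eqn{\langle B\rangle\bar f'(x_*) - 1}) and `role` (one of `"x_0"`,
#'   `"x_minus"`, `"x_zero"`, `"x_plus"`).
#' @examples
#' fixed_points(model_preset("neg_fb_fig3"))  # one stable point
#' fixed_points(model_preset("pos_fb_fig4"))  # bistable triple
#' @export
fixed_points <- function(model, x_upper = NULL, n_scan = 2000L) {
  stopifnot(inherits(model, "burst_model"))
  if (is.null(x_upper))
    x_upper <- 2 * model$burst$mean * max(model$feedback$rates)
  xs <- seq(0, x_upper, length.out = n_scan + 1L)
  fx <- rate_rhs(model, xs)
  # grid points that hit a root exactly (including x = 0 when f_0 = 0)
  roots <- xs[abs(fx) < 1e-12]
  sgn <- sign(fx)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    r <- uniroot(function(z) rate_rhs(model, z), c(xs[i], xs[i + 1L]),
                 tol = .Machine$double.eps^0.75)$root
    # Newton polish to push |rhs| to the 1e-10 scale and beyond
    for (k in 1:3) {
      d <- model$burst$mean * effective_rate_deriv(model, r) - 1
      if (abs(d) < 1e-12) break
      r <- r - rate_rhs(model, r) / d
    }
    roots <- c(roots, r)
  }
  roots <- sort(roots)
  if (length(roots) == 0)
    stop("no fixed points found on [0, x_upper]; widen the bracket?")
  if (length(roots) %% 2L == 0L)
    stop("even number of fixed points: pathological response or ",
         "bracket too small")
  lam <- model$burst$mean * effective_rate_deriv(model, roots) - 1
  if (any(abs(lam) < 1e-8))
    stop("tangent (degenerate) fixed point detected; not classified")
  stable <- lam < 0
  role <- if (length(roots) == 1L && stable[1]) "x_0"
          else if (length(roots) == 3L &&
                   identical(stable, c(TRUE, FALSE, TRUE)))
            c("x_minus", "x_zero", "x_plus")
          else rep(NA_character_, length(roots))
  out <- data.frame(x = roots, stable = stable, lambda = lam, role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("fixed_points", "data.frame")
  out
}
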