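#' Lattice truncation bound for the inactive protein
#'
#' The truncated master equation lives on the lattice
#' `{0..X_max} x {0..s_max}` with `X_max = 4 * ceiling(x_top / epsilon)`,
#' where `x_top` is the uppermost stable fixed point of the rate equation
#' (the monostable state when there is only one). Sample paths essentially
#' never exceed this bound; the residual boundary mass is checked by
#' [cme_steady_state()].
#'
#' @inheritParams operator_matrix
#' @param fps optional [fixed_points()] table (computed if `NULL`).
#' @param epsilon timescale parameter; defaults to `model$epsilon`.
#' @return integer truncation bound.
#' @export
default_Xmax <- function(model, fps = NULL, epsilon = model$epsilon) {
  if (is.null(fps)) fps <- fixed_points(model)
  x_top <- max(fps$x[fps$stable])
  if (!is.finite(x_top)) stop("no stable fixed point")
  4L * as.integer(ceiling(x_top / epsilon))
}

#' Sparse generator of the truncated chemical master equation
#'
#' Builds the transition-rate matrix of the Markov chain of Table-style
#' channels on the finite lattice, column-stochastically (each column sums
#' to zero; entry (target, source) is a rate). Channels from state
#' `(X, s)`:
#' production bursts to `(X + j, s)` at rate `f_s b_j / epsilon` for
#' `j >= 1` (bursts overshooting the lattice are lumped into
#' `X = X_max`, which conserves probability); activation to
#' `(X - 1, min(s + 1, s_max))` at rate `X`; decay to `(X, s - 1)` at rate
#' `s / epsilon`. States are stacked with `s` varying fastest.
#'
#' @inheritParams default_Xmax
#' @param X_max lattice bound for the inactive protein.
#' @param max_order guard on the matrix order
#'   `(s_max + 1) * (X_max + 1)`.
#' @return a `dgCMatrix` of order `(s_max + 1) * (X_max + 1)`.
#' @export
cme_generator <- function(model, X_max, epsilon = model$epsilon,
                          max_order = 4e6) {
  stopifnot(inherits(model, "burst_model"))
  if (is.null(model$burst$pmf))
    stop("CME generator needs an explicit burst pmf ",
         "(MGF-only distribution supplied)")
  X_max <- as.integer(X_max)
  if (X_max < 1L) stop("X_max must be at least 1")
  n <- model$s_max + 1L
  N <- n * (X_max + 1L)
  if (N > max_order)
    stop("lattice order ", N, " exceeds the memory guard of ", max_order)
  f <- model$feedback$rates
  Xv <- rep(0:X_max, each = n)
  sv <- rep.int(0:model$s_max, X_max + 1L)
  idx <- seq_len(N)
  state <- function(X, s) X * n + s + 1L

  ii <- jj <- integer(0); xx <- numeric(0)
  # production bursts, j >= 1, overshoot lumped at X_max
  bj <- model$burst$pmf
  for (j in model$burst$support) {
    if (j == 0L || bj[j + 1L] <= 0) next
    tgt <- state(pmin(Xv + j, X_max), sv)
    ii <- c(ii, tgt); jj <- c(jj, idx)
    xx <- c(xx, f[sv + 1L] * bj[j + 1L] / epsilon)
  }
  # activation
  act <- Xv >= 1L
  ii <- c(ii, state(Xv[act] - 1L, pmin(sv[act] + 1L, model$s_max)))
  jj <- c(jj, idx[act]); xx <- c(xx, Xv[act])
  # decay
  dec <- sv >= 1L
  ii <- c(ii, state(Xv[dec], sv[dec] - 1L))
  jj <- c(jj, idx[dec]); xx <- c(xx, sv[dec] / epsilon)
  # diagonal: minus total outflow (self-loops cancel automatically)
  out_rate <- f[sv + 1L] * sum(bj[model$burst$support >= 1L]) / epsilon +
    Xv + sv / epsilon
  ii <- c(ii, idx); jj <- c(jj, idx); xx <- c(xx, -out_rate)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
}

#' Steady state of the truncated master equation
#'
#' Computes the normalised nullvector of the sparse generator. One balance
#' equation is deleted (the chain is irreducible, so the nullspace is
#' one-dimensional and any single equation is redundant): the probability
#' of a reference state is pinned to 1 and the remaining sparse system is
#' solved by LU factorisation, after which the vector is renormalised.
#' Deleting an equation, rather than overwriting one with a dense
#' normalisation row, keeps the matrix sparse and the factorisation cheap;
#' the reference state is placed at the uppermost stable fixed point,
#' where the stationary mass is large, so the pinned solve is well
#' conditioned. Entries more negative than `-1e-12` (relative) raise an
#' error; smaller negative noise is clamped to zero before renormalising.
#'
#' @inheritParams cme_generator
#' @param X_max lattice bound; [default_Xmax()] when `NULL`.
#' @return an object of class `lattice_distribution`: list with `probs`
#'   (matrix, rows `X = 0..X_max`, columns `s = 0..s_max`), `X_max`,
#'   `s_max`, `epsilon`, `residual` (max-norm of generator times
#'   solution) and `boundary_mass` (stationary mass on the `X = X_max`
#'   rim, small when the truncation is adequate).
#' @export
cme_steady_state <- function(model, X_max = NULL,
                             epsilon = model$epsilon) {
  fps <- tryCatch(fixed_points(model), error = function(e) NULL)
  if (is.null(X_max)) {
    if (is.null(fps)) stop("X_max not given and no fixed point found")
    X_max <- default_Xmax(model, fps, epsilon = epsilon)
  }
  G <- cme_generator(model, X_max, epsilon = epsilon)
  N <- nrow(G)
  n <- model$s_max + 1L
  # reference state near the uppermost stable fixed point
  x_top <- if (is.null(fps)) 0 else max(fps$x[fps$stable])
  ref <- min(round(x_top / epsilon), X_max) * n +
    round(min(x_top, model$s_max)) + 1L
  p <- numeric(N)
  p[ref] <- 1
  p[-ref] <- as.numeric(Matrix::solve(G[-ref, -ref], -G[-ref, ref]))
  if (min(p) < -1e-12 * max(p))
    stop("nullvector has significantly negative entries; ",
         "nullspace dimension may exceed one")
  p[p < 0] <- 0
  p <- p / sum(p)
  resid <- max(abs(G %*% p))
  n <- model$s_max + 1L
  probs <- t(matrix(p, nrow = n))
  out <- list(probs = probs, X_max = X_max, s_max = model$s_max,
              epsilon = epsilon, residual = resid,
              boundary_mass = sum(probs[X_max + 1L, ]))
  class(out) <- "lattice_distribution"
  out
}

#' @export
#' @method print lattice_distribution
print.lattice_distribution <- function(x, ...) {
  cat("Truncated-CME steady state on {0..", x$X_max, "} x {0..", x$s_max,
      "} (epsilon = ", x$epsilon, ")\n", sep = "")
  cat("  residual ", format(x$residual, digits = 3),
      ", boundary mass ", format(x$boundary_mass, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' @export
marginal_s.lattice_distribution <- function(object, ...) {
  colSums(object$probs)
}

#' @export
marginal_X.lattice_distribution <- function(object, ...) {
  out <- rowSums(object$probs)
  names(out) <- 0:object$X_max
  out
}
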