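#' Boundary-modified shift operators on active-protein sequences
#'
#' For a sequence `v_s`, `s = 0..s_max`, the left shift returns `v_{s+1}`
#' (0 at `s = s_max`); the right shift returns `v_{s-1}` (0 at `s = 0`) and
#' at the boundary the sum `v_{s_max-1} + v_{s_max}`. The boundary rules
#' encode the activation reset `s -> min(s+1, s_max)`: decay cannot feed in
#' from the inadmissible state `s_max + 1`, and activation out of `s_max`
#' keeps the state at the cap, so the right shift preserves the sum of the
#' sequence.
#'
#' @param v numeric vector indexed by `s = 0..s_max` (so element 1 is
#'   `v_0`).
#' @return numeric vector of the same length.
#' @examples
#' shift_left(c(1, 2, 3))   # 2 3 0
#' shift_right(c(1, 2, 3))  # 0 1 5
#' @export
shift_left <- function(v) {
  n <- length(v)
  if (n == 1L) return(0 * v)
  c(v[-1L], 0)
}

#' @rdname shift_left
#' @export
shift_right <- function(v) {
  n <- length(v)
  if (n == 1L) return(v)  # s_max = 0: the single state maps to itself
  out <- c(0, v[-n])
  out[n] <- out[n] + v[n]
  out
}

#' Tridiagonal WKB matrix A(x, theta) and its partial derivatives
#'
#' `operator_matrix()` assembles the matrix representation of the linear
#' operator
#' \deqn{\mathcal{A}v = e^{-\theta}x\,\mathcal{R}v + \mathcal{L}(s v)
#'   - (f_s(1 - M(\theta)) + x + s)v,}
#' acting on sequences over `s = 0..s_max`: superdiagonal `1, ..., s_max`,
#' subdiagonal constant `exp(-theta) * x`, main diagonal
#' `-f_s (1 - M(theta)) - x - s` except for the last entry, which picks up
#' the boundary term of the right shift and reads
#' `-f_smax (1 - M(theta)) - x (1 - exp(-theta)) - s_max`. At `theta = 0`
#' the matrix is the generator of the M/M/s_max/s_max birth-death process
#' with arrival rate `x` and unit per-server service rate (columns sum to
#' zero).
#'
#' `operator_dx()` and `operator_dtheta()` return the matrix forms of
#' \eqn{\partial\mathcal{A}/\partial x\, v = e^{-\theta}\mathcal{R}v - v}
#' and \eqn{\partial\mathcal{A}/\partial\theta\, v
#'   = M'(\theta) f_s v - e^{-\theta} x \mathcal{R} v}.
#'
#' @param model a [burst_model()].
#' @param x inactive-protein concentration, `x >= 0`.
#' @param theta conjugate momentum (real).
#' @return dense numeric matrix of order `s_max + 1`.
#' @export
operator_matrix <- function(model, x, theta) {
  stopifnot(inherits(model, "burst_model"))
  if (x < 0) stop("x must be non-negative")
  n <- model$s_max + 1L
  f <- model$feedback$rates
  M0 <- burst_mgf(model$burst, theta, 0L)
  s <- 0:model$s_max
  A <- matrix(0, n, n)
  diag(A) <- -f * (1 - M0) - x - s
  A[n, n] <- A[n, n] + x * exp(-theta)  # right-shift boundary lump
  if (n > 1L) {
    A[cbind(1:(n - 1L), 2:n)] <- 1:(n - 1L)       # L(s v): (s+1) v_{s+1}
    A[cbind(2:n, 1:(n - 1L))] <- exp(-theta) * x  # e^-theta x R v
  }
  A
}

#' @rdname operator_matrix
#' @export
operator_dx <- function(model, theta) {
  n <- model$s_max + 1L
  D <- diag(-1, n)
  if (n > 1L) D[cbind(2:n, 1:(n - 1L))] <- exp(-theta)
  D[n, n] <- D[n, n] + exp(-theta)
  D
}

#' @rdname operator_matrix
#' @export
operator_dtheta <- function(model, x, theta) {
  n <- model$s_max + 1L
  M1 <- burst_mgf(model$burst, theta, 1L)
  D <- diag(M1 * model$feedback$rates, n)
  if (n > 1L) D[cbind(2:n, 1:(n - 1L))] <- -exp(-theta) * x
  D[n, n] <- D[n, n] - exp(-theta) * x
  D
}

#' Apply the operator A to a sequence via the shift operators
#'
#' Operator form of [operator_matrix()]; used mainly as an independent
#' cross-check of the matrix assembly.
#'
#' @inheritParams operator_matrix
#' @param v sequence of length `s_max + 1`.
#' @return numeric vector `A v`.
#' @export
apply_operator <- function(model, x, theta, v) {
  f <- model$feedback$rates
  s <- 0:model$s_max
  M0 <- burst_mgf(model$burst, theta, 0L)
  exp(-theta) * x * shift_right(v) + shift_left(s * v) -
    (f * (1 - M0) + x + s) * v
}
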