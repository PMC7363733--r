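#' Principal eigenvalue and eigenvectors of the WKB matrix
#'
#' The matrix `A(x, theta)` has no negative off-diagonal entries, so by
#' Perron-Frobenius its eigenvalue of largest real part (the principal
#' eigenvalue) is real with positive left and right eigenvectors. The
#' triple is normalised so that `sum(v) = 1` and `u . v = 1`; with this
#' gauge the eigenvector sandwich formulas
#' \eqn{H_x = u^\top (\partial A/\partial x) v} and
#' \eqn{H_\theta = u^\top (\partial A/\partial\theta) v} hold.
#'
#' @param A square matrix with non-negative off-diagonal entries, as built
#'   by [operator_matrix()].
#' @return a list with elements `H` (principal eigenvalue), `u` and `v`
#'   (positive left/right eigenvectors, normalised as above).
#' @export
principal_triple <- function(A) {
  n <- nrow(A)
  fix_sign <- function(w) {
    w <- Re(w)
    if (w[which.max(abs(w))] < 0) w <- -w
    # clamp numerical noise near the positivity boundary
    floor_val <- 1e-300
    tiny <- abs(w) < 1e-12 * max(abs(w))
    if (any(w[tiny] < 0)) w[tiny] <- floor_val
    if (any(w < 0))
      stop("principal eigenvector has negative components; invalid matrix?")
    pmax(w, floor_val)
  }
  er <- eigen(A)
  ir <- which.max(Re(er$values))
  H <- Re(er$values[ir])
  v <- fix_sign(er$vectors[, ir])
  el <- eigen(t(A))
  il <- which.max(Re(el$values))
  u <- fix_sign(el$vectors[, il])
  v <- v / sum(v)
  u <- u / sum(u * v)
  if (max(abs(A %*% v - H * v)) > 1e-7 * max(1, max(abs(A))) ||
      max(abs(crossprod(A, u) - H * u)) > 1e-7 * max(1, max(abs(A))))
    stop("principal eigenpair residual too large")
  list(H = H, u = as.numeric(u), v = as.numeric(v))
}

# eigenvalue-only fast path used heavily by the branch tracer
principal_eigenvalue <- function(A) {
  max(Re(eigen(A, only.values = TRUE)$values))
}

#' Hamiltonian of the slow-activation WKB problem
#'
#' `hamiltonian()` evaluates \eqn{H(x,\theta)}, the principal eigenvalue of
#' the matrix `A(x, theta)`; its zero-level set contains the deterministic
#' flow (`theta = 0`) and the nontrivial branch `theta = Phi'(x)` that
#' defines the quasipotential derivative. `grad_hamiltonian()` returns the
#' exact gradient via the eigenvector sandwich formulas, and
#' `hamiltonian_flow()` the associated Hamiltonian vector field
#' `(H_theta, -H_x)`. On the invariant x-axis (`theta = 0`) the flow
#' reduces to the emergent rate equation: `H_x = 0` and
#' `H_theta = <B> fbar(x) - x`.
#'
#' @inheritParams operator_matrix
#' @return `hamiltonian()`: a scalar. `grad_hamiltonian()`: named vector
#'   `c(H_x =, H_theta =)`. `hamiltonian_flow()`: named vector
#'   `c(xdot =, thetadot =)`.
#' @examples
#' m <- model_preset("pos_fb_fig1")
#' hamiltonian(m, x = 5, theta = 0)      # 0 to machine precision
#' grad_hamiltonian(m, x = 5, theta = 0) # (0, <B> fbar(5) - 5)
#' @export
hamiltonian <- function(model, x, theta) {
  principal_eigenvalue(operator_matrix(model, x, theta))
}

#' @rdname hamiltonian
#' @export
grad_hamiltonian <- function(model, x, theta) {
  tr <- principal_triple(operator_matrix(model, x, theta))
  Hx <- sum(tr$u * (operator_dx(model, theta) %*% tr$v))
  Ht <- sum(tr$u * (operator_dtheta(model, x, theta) %*% tr$v))
  c(H_x = Hx, H_theta = Ht)
}

#' @rdname hamiltonian
#' @export
hamiltonian_flow <- function(model, x, theta) {
  g <- grad_hamiltonian(model, x, theta)
  c(xdot = unname(g["H_theta"]), thetadot = -unname(g["H_x"]))
}
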