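# Heteroclinic branch of the Hamiltonian zero-level set, the quasipotential
# and the next-order prefactor.

# convergence boundary of the MGF in theta (negative binomial only)
theta_upper_bound <- function(dist) {
  if (dist$family %in% c("poisson", "explicit")) return(Inf)
  if (dist$fano > 1) log(dist$fano / (dist$fano - 1)) else Inf
}

#' Saddle linearisation of the Hamiltonian system at a fixed point
#'
#' Every fixed point `x_*` of the rate equation lifts to a saddle
#' `(x_*, 0)` of the Hamiltonian system. The linearisation has eigenvalues
#' \eqn{\pm H_{x\theta}} with the nontrivial eigenvector
#' `(1, -2 H_{x\theta}/H_{\theta\theta})`; its second component is the
#' local slope `d theta / d x` of the nontrivial branch, i.e. the potential
#' curvature `Phi''(x_*)`. The second derivatives are evaluated exactly:
#' \eqn{H_{x\theta} = \langle B\rangle \bar f'(x_*) - 1} and
#' \deqn{H_{\theta\theta} = x_*(1 + \langle B^2\rangle/\langle B\rangle)
#'   + 2\,\mathbf{1}^\top (\partial A/\partial\theta)\tilde v,}
#' where \eqn{\tilde v} solves the (consistent) singular system
#' \eqn{A(x_*,0)\tilde v = -(\partial A/\partial\theta)\rho(x_*)}. The
#' solution is gauge-fixed by `sum(v_tilde) = 0`; the formula is invariant
#' under the residual gauge freedom `v_tilde + c * rho`.
#'
#' @inheritParams operator_matrix
#' @param x_star a fixed point of the rate equation.
#' @return a list with `x_star`, `H_xtheta`, `H_thetatheta`, `slope`
#'   (`= -2 H_xtheta / H_thetatheta`), and the auxiliary vector `v_tilde`.
#' @export
saddle_linearization <- function(model, x_star) {
  stopifnot(inherits(model, "burst_model"))
  if (abs(rate_rhs(model, x_star)) > 1e-6)
    stop("x_star is not a fixed point of the rate equation")
  n <- model$s_max + 1L
  A0 <- operator_matrix(model, x_star, 0)
  dAt <- operator_dtheta(model, x_star, 0)
  rho <- qss_distribution(model, x_star)
  rhs <- -as.numeric(dAt %*% rho)
  # consistent singular solve, gauge sum(v_tilde) = 0 via a stacked system
  vt <- qr.solve(rbind(A0, rep(1, n)), c(rhs, 0))
  if (max(abs(A0 %*% vt - rhs)) > 1e-8 * max(1, max(abs(rhs))))
    stop("singular system for v_tilde did not solve to tolerance")
  B2 <- burst_mgf(model$burst, 0, 2L)
  Hxt <- model$burst$mean * effective_rate_deriv(model, x_star) - 1
  Htt <- x_star * (1 + B2 / model$burst$mean) +
    2 * sum(dAt %*% vt)
  list(x_star = x_star, H_xtheta = Hxt, H_thetatheta = Htt,
       slope = -2 * Hxt / Htt, v_tilde = as.numeric(vt))
}

# Solve H(x, theta) = 0 for the nontrivial root, given a same-sign guess.
# Works on the chord function g(theta) = H(x, theta)/theta, which is
# nondecreasing (H is convex in theta with H(x, 0) = 0), so any sign-change
# bracket encloses the unique nontrivial root.
solve_branch_theta <- function(model, x, guess) {
  tmax <- theta_upper_bound(model$burst)
  g <- function(th) hamiltonian(model, x, th) / th
  sgn <- sign(guess)
  a <- sgn * max(abs(guess) / 4, 1e-14)
  b <- sgn * abs(guess) * 4
  if (sgn > 0 && tmax < Inf) b <- min(b, 0.999 * tmax)
  ga <- g(a); gb <- g(b)
  it <- 0L
  while (sign(ga) == sign(gb)) {
    it <- it + 1L
    if (it > 60L) stop("failed to bracket the nontrivial branch at x = ", x)
    a <- a / 4
    b <- b * 4
    if (sgn > 0 && tmax < Inf) b <- min(b, 0.999999 * tmax)
    ga <- g(a); gb <- g(b)
  }
  uniroot(g, sort(c(a, b)), f.lower = if (a < b) ga else gb,
          f.upper = if (a < b) gb else ga, tol = 1e-12)$root
}

#' Trace the nontrivial branch theta = Phi'(x) of the zero-level set
#'
#' Builds a concentration grid spanning the fixed points of the rate
#' equation (plus outer margins) and, at each grid point, finds the
#' nontrivial root of `H(x, theta) = 0` by continuation: the root solver
#' works on the monotone chord function `H/theta` and is seeded by the
#' saddle eigenvector slope near each fixed point and by extrapolation from
#' the previous grid point elsewhere. At the fixed points themselves
#' `theta = 0` exactly. The principal eigenvectors along the branch are
#' stored: the l1-normalised right eigenvector gives the WKB conditional
#' distribution `w_s(x)`, the left eigenvector `l_s(x)` enters the
#' prefactor solvability condition.
#'
#' The grid is anchored so that every fixed point is a grid node. The lower
#' margin is floored at 5 percent of the lowest fixed point: the branch
#' momentum diverges as `x -> 0` for bursty production, and the mixture
#' approximation only needs the potential near the wells.
#'
#' @inheritParams operator_matrix
#' @param fps optional [fixed_points()] table (computed if `NULL`).
#' @param margin outer margin beyond the outermost fixed points; default
#'   half the fixed-point span, or 1.0 for a single fixed point.
#' @param n_grid approximate number of grid points (default 2001).
#' @return an object of class `wkb_branch`: a list with `grid`, `theta`,
#'   `H_resid` (Hamiltonian residual along the branch), matrices `w` and
#'   `l` (rows = grid points), fixed-point table `fps`, their grid indices
#'   `fp_idx`, and per-fixed-point `saddles`. `phi`, `phi2`, `k` are filled
#'   by [compute_potential()] and [compute_prefactor()].
#' @seealso [wkb_branch()] for the one-call version.
#' @export
trace_branch <- function(model, fps = NULL, margin = NULL, n_grid = 2001L) {
  stopifnot(inherits(model, "burst_model"))
  if (is.null(fps)) fps <- fixed_points(model)
  xf <- fps$x
  span <- max(xf) - min(xf)
  if (is.null(margin)) margin <- if (span > 0) 0.5 * span else 1.0
  x_lo <- max(0.05 * min(xf), min(xf) - margin)
  x_hi <- max(xf) + margin
  knots <- c(x_lo, xf, x_hi)

  # proportional allocation with exact knots
  seg_len <- diff(knots)
  seg_n <- pmax(3L, round(n_grid * seg_len / sum(seg_len)))
  grid <- numeric(0)
  for (i in seq_along(seg_len)) {
    seg <- seq(knots[i], knots[i + 1L], length.out = seg_n[i])
    if (i > 1L) seg <- seg[-1L]
    grid <- c(grid, seg)
  }
  ng <- length(grid)
  fp_idx <- vapply(xf, function(z) which.min(abs(grid - z)), integer(1))
  grid[fp_idx] <- xf  # exact anchoring

  saddles <- lapply(xf, function(z) saddle_linearization(model, z))
  n <- model$s_max + 1L
  theta <- rep(NA_real_, ng)
  Hres <- numeric(ng)
  w <- matrix(NA_real_, ng, n)
  l <- matrix(NA_real_, ng, n)

  fill_point <- function(i, guess) {
    th <- solve_branch_theta(model, grid[i], guess)
    tr <- principal_triple(operator_matrix(model, grid[i], th))
    theta[i] <<- th
    Hres[i] <<- tr$H
    w[i, ] <<- tr$v
    l[i, ] <<- tr$u
  }
  walk <- function(idx, sl, x0) {
    # idx ordered outward from the fixed point at x0 with branch slope sl
    prev <- 0; prev2 <- NA
    for (i in idx) {
      guess <- if (prev == 0) sl * (grid[i] - x0)
               else if (!is.na(prev2) &&
                        sign(2 * prev - prev2) == sign(prev))
                 2 * prev - prev2
               else prev
      if (guess == 0 || !is.finite(guess)) guess <- prev
      fill_point(i, guess)
      prev2 <- prev; prev <- theta[i]
    }
  }

  for (j in seq_along(xf)) {
    i0 <- fp_idx[j]
    theta[i0] <- 0
    Hres[i0] <- 0
    w[i0, ] <- qss_distribution(model, xf[j])
    l[i0, ] <- rep(1, n)
    # walk left (towards previous knot) and right (towards next knot)
    if (j == 1L && i0 > 1L)
      walk(seq(i0 - 1L, 1L), saddles[[j]]$slope, xf[j])
    right_stop <- if (j == length(xf)) ng else fp_idx[j + 1L] - 1L
    if (i0 < right_stop)
      walk(seq(i0 + 1L, right_stop), saddles[[j]]$slope, xf[j])
  }

  out <- list(model = model, grid = grid, theta = theta, H_resid = Hres,
              w = w, l = l, fps = fps, fp_idx = fp_idx, saddles = saddles,
              phi = NULL, phi2 = NULL, k = NULL)
  class(out) <- "wkb_branch"
  out
}

# cumulative trapezoidal quadrature
cumtrapz1 <- function(x, y) {
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

# gradient by central differences on a (possibly mildly non-uniform) grid
fd_gradient <- function(x, y) {
  nx <- length(x)
  g <- numeric(nx)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[nx] <- (y[nx] - y[nx - 1]) / (x[nx] - x[nx - 1])
  if (nx > 2) {
    i <- 2:(nx - 1)
    g[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  g
}

#' Quasipotential along the traced branch
#'
#' Integrates the branch momentum, `Phi(x) = int theta dx`, by composite
#' trapezoidal quadrature over the branch grid, anchoring the additive
#' constant so that the minimum of `Phi` over the stable fixed points is 0.
#' Also fills the curvature `Phi'' = d theta / d x` (central differences,
#' overridden at the fixed points by the exact saddle slope). `Phi` is a
#' Lyapunov function of the rate equation: it decreases along
#' non-stationary deterministic trajectories, with local minima (maxima)
#' at stable (unstable) fixed points.
#'
#' @param branch a `wkb_branch` from [trace_branch()].
#' @return the branch with `phi` and `phi2` filled.
#' @export
compute_potential <- function(branch) {
  stopifnot(inherits(branch, "wkb_branch"))
  phi <- cumtrapz1(branch$grid, branch$theta)
  anchor <- min(phi[branch$fp_idx[branch$fps$stable]])
  branch$phi <- phi - anchor
  phi2 <- fd_gradient(branch$grid, branch$theta)
  phi2[branch$fp_idx] <- vapply(branch$saddles, `[[`, numeric(1), "slope")
  branch$phi2 <- phi2
  branch
}

# interpolate y over a masked window by a local polynomial fitted to
# flanking unmasked points (removable 0/0 singularities of the prefactor
# integrand at the fixed points)
repair_removable <- function(x, y, mask, n_side = 4L, degree = 3L) {
  bad <- which(mask)
  if (length(bad) == 0) return(y)
  runs <- split(bad, cumsum(c(1, diff(bad) != 1)))
  for (r in runs) {
    lo <- min(r); hi <- max(r)
    left <- if (lo > 1) seq(max(1, lo - n_side), lo - 1) else integer(0)
    right <- if (hi < length(x)) seq(hi + 1, min(length(x), hi + n_side))
             else integer(0)
    pts <- c(left, right)
    pts <- pts[!mask[pts]]
    if (length(pts) < degree + 1)
      stop("not enough points to repair the prefactor integrand")
    ctr <- mean(x[r])
    fit <- stats::lm.fit(outer(x[pts] - ctr, 0:degree, `^`), y[pts])
    y[r] <- drop(outer(x[r] - ctr, 0:degree, `^`) %*% fit$coefficients)
  }
  y
}

#' WKB prefactor from the next-order solvability condition
#'
#' At the next order of the WKB expansion the prefactor `k(x)` of the
#' leading-order solution `k(x) w_s(x) exp(-Phi(x)/eps)` satisfies a linear
#' homogeneous first-order ODE obtained by requiring the inhomogeneous
#' term to be orthogonal to the left nullvector `l_s(x)`:
#' \deqn{k'(x)\sum_s l_s\alpha_s + k(x)\sum_s l_s\beta_s = 0,}
#' with
#' \eqn{\alpha_s = M'(\theta) f_s w_s - e^{-\theta}x\,\mathcal{R}w_s} and
#' \eqn{\beta_s = M'(\theta) f_s w_s' + \tfrac12\Phi'' M''(\theta) f_s w_s
#'  - e^{-\theta}[(1-\tfrac12\Phi'' x)\mathcal{R}w_s + x\mathcal{R}w_s']}.
#' Hence `k(x) = exp(-int (sum l beta / sum l alpha) dx)` up to a
#' multiplicative constant, fixed here by `k = 1` at the leftmost stable
#' fixed point (only ratios of `k` between stable fixed points enter the
#' mode weights). The integrand is 0/0 at the fixed points (the
#' denominator equals `H_theta` on the branch, which vanishes there); the
#' singularity is removable and is repaired by local polynomial
#' interpolation across a small window.
#'
#' @inheritParams operator_matrix
#' @param branch a `wkb_branch` with `phi`/`phi2` filled
#'   (see [compute_potential()]).
#' @return the branch with `k`, and diagnostic fields `integrand` and
#'   `denom` (`= sum_s l_s alpha_s`, equal to `H_theta` on the branch),
#'   filled.
#' @export
compute_prefactor <- function(model, branch) {
  stopifnot(inherits(branch, "wkb_branch"), !is.null(branch$phi2))
  ng <- length(branch$grid)
  f <- model$feedback$rates
  M1 <- burst_mgf(model$burst, branch$theta, 1L)
  M2 <- burst_mgf(model$burst, branch$theta, 2L)
  wprime <- apply(branch$w, 2, function(col)
    fd_gradient(branch$grid, col))
  num <- den <- numeric(ng)
  for (i in seq_len(ng)) {
    wi <- branch$w[i, ]; wpi <- wprime[i, ]
    Rw <- shift_right(wi); Rwp <- shift_right(wpi)
    x <- branch$grid[i]; th <- branch$theta[i]; p2 <- branch$phi2[i]
    alpha <- M1[i] * f * wi - exp(-th) * x * Rw
    beta <- M1[i] * f * wpi + 0.5 * p2 * M2[i] * f * wi -
      exp(-th) * ((1 - 0.5 * p2 * x) * Rw + x * Rwp)
    num[i] <- sum(branch$l[i, ] * beta)
    den[i] <- sum(branch$l[i, ] * alpha)
  }
  ratio <- num / den
  mask <- rep(FALSE, ng)
  for (i0 in branch$fp_idx)
    mask[max(1, i0 - 2L):min(ng, i0 + 2L)] <- TRUE
  ratio <- repair_removable(branch$grid, ratio, mask)
  if (any(!is.finite(ratio)))
    stop("prefactor integrand blow-up not removable by extrapolation")
  logk <- -cumtrapz1(branch$grid, ratio)
  i_ref <- branch$fp_idx[branch$fps$stable][1]
  branch$k <- exp(logk - logk[i_ref])
  branch$integrand <- ratio
  branch$denom <- den
  branch
}

#' One-call branch construction
#'
#' Runs [trace_branch()], [compute_potential()] and [compute_prefactor()].
#'
#' @inheritParams trace_branch
#' @return a fully filled `wkb_branch`.
#' @export
wkb_branch <- function(model, fps = NULL, margin = NULL, n_grid = 2001L) {
  br <- trace_branch(model, fps = fps, margin = margin, n_grid = n_grid)
  br <- compute_potential(br)
  compute_prefactor(model, br)
}

#' @export
#' @method print wkb_branch
print.wkb_branch <- function(x, ...) {
  cat("WKB branch on [", format(min(x$grid)), ",", format(max(x$grid)),
      "], ", length(x$grid), " points\n", sep = "")
  cat("  fixed points at x =", paste(format(x$fps$x, digits = 4),
                                     collapse = ", "), "\n")
  cat("  max |H| residual:", format(max(abs(x$H_resid)), digits = 3), "\n")
  cat("  filled:", paste(c("theta", if (!is.null(x$phi)) "phi",
                           if (!is.null(x$k)) "prefactor"),
                         collapse = ", "), "\n")
  invisible(x)
}

#' WKB conditional distribution of the active protein at a concentration
#'
#' Interpolates `w_s(x) = v_s(x, Phi'(x))` (the l1-normalised right
#' principal eigenvector along the branch) linearly between grid points.
#' At critical points of the potential this equals the quasi-steady-state
#' truncated Poisson `rho_s(x_*)`; away from them it differs.
#'
#' @param branch a `wkb_branch`.
#' @param x concentration inside the branch grid range.
#' @return probability vector over `s = 0..s_max`.
#' @export
conditional_distribution <- function(branch, x) {
  g <- branch$grid
  if (x < min(g) || x > max(g))
    stop("x outside the branch grid; refusing to extrapolate")
  i <- findInterval(x, g, all.inside = TRUE)
  t <- (x - g[i]) / (g[i + 1L] - g[i])
  ws <- (1 - t) * branch$w[i, ] + t * branch$w[i + 1L, ]
  ws / sum(ws)
}

#' Export a branch table
#'
#' Writes a tab-separated table with columns `x`, `theta`, `phi`, `k` and
#' the conditional distribution columns `w_0 .. w_smax`.
#'
#' @param branch a filled `wkb_branch`.
#' @param path output file path.
#' @export
write_branch <- function(branch, path) {
  stopifnot(!is.null(branch$phi), !is.null(branch$k))
  tab <- data.frame(x = branch$grid, theta = branch$theta,
                    phi = branch$phi, k = branch$k, branch$w)
  names(tab)[-(1:4)] <- paste0("w_", seq_len(ncol(branch$w)) - 1L)
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
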