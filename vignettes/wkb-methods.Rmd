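---
title: "WKB analysis of bursty gene expression with a one-step production delay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{WKB analysis of bursty gene expression with a one-step production delay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstwkb)
```

## The model

`burstwkb` analyses a two-species stochastic model of autoregulated gene
expression with a production delay. An *inactive* protein X is produced in
bursts: each production event adds a random number $B \ge 0$ of molecules,
drawn independently from a pmf $b_j$ with mean $\langle B\rangle$ and Fano
factor $F$. Each X molecule independently matures, through a single
memoryless step, into an *active* protein S; biologically this step can be
a chemical modification, folding, or compartmental transport, and because
it is exponential it implements the simplest distributed production delay.
The active protein decays and, crucially, feeds back: the burst frequency
is a function $f_s$ of the current active count $s$. The three channels
are

| channel    | rate                 | reset                                   |
|------------|----------------------|-----------------------------------------|
| production | $\varepsilon^{-1}f_s$ | $X \to X + B$                          |
| activation | $X$                  | $X \to X-1$, $s \to \min(s+1, s_{\max})$ |
| decay      | $\varepsilon^{-1}s$  | $s \to s - 1$                           |

The cap $s_{\max}$ keeps all linear algebra finite; it is chosen by the
rule implemented in `choose_smax()` — the smallest $s$ whose decay rate is
at least twice the maximal mean production rate
$\langle B\rangle \max_s f_s$ — so that the cap is essentially never
visited. The timescale parameter $\varepsilon \in (0,1]$ separates the
slow activation ($O(1)$ rates) from fast production and decay
($O(1/\varepsilon)$ rates). The package addresses the slow-activation
regime $\varepsilon \ll 1$, in which X is present at $O(1/\varepsilon)$
copy numbers, measured by the concentration $x = \varepsilon X$, while S
stays at $O(1)$ copies.

## From the master equation to a Hamiltonian

Writing the stationary master equation for $p(x, s)$ and inserting the WKB
ansatz
$$p(x,s;\varepsilon) = \bigl(r_s^0(x) + \varepsilon r_s^1(x) + \dots\bigr)
  e^{-\Phi(x)/\varepsilon},$$
the leading order demands that the vector $r^0(x)$ be a positive
nullvector of a tridiagonal matrix $A(x, \theta)$, where
$\theta = \Phi'(x)$ and $A$ couples neighbouring $s$-states through the
boundary-modified shift operators (`operator_matrix()`, `shift_left()`,
`shift_right()`; the boundary rules encode the capped activation reset).
By Perron–Frobenius, a positive nullvector exists exactly when the
*principal* eigenvalue — the Hamiltonian
$H(x,\theta) = \lambda_1(A(x,\theta))$ — vanishes. The stationary problem
therefore reduces to tracing the zero-level set of $H$.

The level set has two branches. On $\theta = 0$ the matrix $A(x,0)$ is
the generator of the $M/M/s_{\max}/s_{\max}$ loss queue: its equilibrium
is the truncated Poisson $\rho_s(x)$ (`qss_distribution()`), and the flow
along this branch is the emergent deterministic rate equation
$$\dot x = \langle B\rangle \bar f(x) - x, \qquad
  \bar f(x) = \sum_s f_s \rho_s(x),$$
with the *mollified* response $\bar f$ (`effective_rate()`): averaging
over the fast Poissonian fluctuations of $s$ smooths any sharp feature of
$f_s$, turning a step into a sigmoid. The nontrivial branch
$\theta = \Phi'(x)$ leaves the fixed points $(x_*, 0)$ along the
non-horizontal saddle eigenvector and defines the quasipotential $\Phi$, a
Lyapunov function of the rate equation whose well depths control the
stability of the expression modes.

## Numerical design

**Principal eigenpairs.** $A$ is dense and small (order
$s_{\max}+1 \le$ a few hundred), so `principal_triple()` uses a full dense
eigendecomposition and picks the largest real part; eigenvector signs are
fixed positive, tiny negative noise (below $10^{-12}$ of the maximum
entry) is clamped. Normalisation $\sum_s v_s = 1$, $u^\top v = 1$ makes
the sandwich formulas $H_x = u^\top A_x v$, $H_\theta = u^\top A_\theta v$
exact, avoiding eigenvalue differencing.

**Branch tracing by continuation rather than ODE integration.** The
branch satisfies $d\theta/dx = -H_x/H_\theta$, but this equation is $0/0$
at the saddles and accumulates drift away from the zero-level set if
integrated directly. `trace_branch()` instead *solves* $H(x,\theta)=0$ at
every grid point: the chord function $g(\theta) = H(x,\theta)/\theta$ is
nondecreasing (the principal eigenvalue is convex in $\theta$ and vanishes
at $\theta = 0$), so the nontrivial root is unique and bracketable. The
solver is seeded near each fixed point by the saddle slope
$-2H_{x\theta}/H_{\theta\theta}$ — with $H_{x\theta}$ and
$H_{\theta\theta}$ from the exact linearisation formulas in
`saddle_linearization()`, the latter via the gauge-invariant auxiliary
solve for $\tilde v$ — and elsewhere by extrapolation from the previous
grid point. The branch then satisfies $|H| < 10^{-6}$ by construction;
in practice residuals are at the $10^{-13}$ level.

**Grid.** 2001 points by default, spanning the fixed points with an outer
margin of half the fixed-point span (1.0 for a single fixed point), with
every fixed point an exact grid node. The lower end is floored at 5 % of
the lowest fixed point because $\Phi'(x) \to -\infty$ as $x \to 0$ for
bursty production; the mixture approximation only needs the potential near
the wells, so the margins are quadrature headroom, not a claim about the
tail.

**Potential and prefactor.** $\Phi$ is the trapezoidal quadrature of
$\theta$, anchored to zero at the deepest stable well; curvatures
$\Phi''$ come from central differences, overridden at fixed points by the
exact saddle slope. The next-order prefactor obeys
$k' \sum_s l_s\alpha_s + k \sum_s l_s\beta_s = 0$, the solvability
condition for the first-order correction; the denominator equals
$H_\theta$ on the branch and vanishes at the fixed points, a removable
$0/0$ repaired by local cubic interpolation across a $\pm 2$-point window.
The integration constant is fixed at $k = 1$ at the leftmost stable fixed
point — only ratios of $k$ between wells enter the weights — and the
quadrature runs continuously through the unstable point so that both wells
share one gauge.

**Mixture approximation.** Laplace expansion about each stable fixed
point gives, per mode, a truncated Poisson in $s$ located at $x_*$ and a
Gaussian in $X$ with mean $x_*/\varepsilon$ and variance
$1/(\varepsilon\Phi''(x_*))$, with weights
$\omega_* \propto k(x_*)\,\Phi''(x_*)^{-1/2} e^{-\Phi(x_*)/\varepsilon}$
normalised to one. The code supports any number of stable fixed points
(the formulas are mode-local), though the bundled regimes have one or two.

**Reference solvers.** `cme_steady_state()` truncates the lattice at
$X_{\max} = 4\lceil x_+/\varepsilon\rceil$ ($x_+$ the uppermost stable
fixed point) and computes the nullvector of the sparse generator by
deleting one balance equation, pinning the probability of a reference
state chosen at the uppermost stable fixed point, and solving with a
sparse LU; this keeps the factorisation sparse (a dense normalisation row
causes severe fill-in) and is well conditioned because the pinned state
carries large mass. Bursts overshooting the lattice are lumped into the
boundary column, which conserves probability; the stationary boundary mass
is reported and checked to be negligible, and doubling $X_{\max}$ moves
the marginals by less than $10^{-8}$ in total variation.
`ssa_simulate()` is an exact Gillespie simulator (compiled inner loop,
inverse-CDF burst sampling, R's RNG for reproducibility) returning a
time-weighted occupancy histogram.

## Burst-size families and a deliberate extension

The mean/Fano MGF family
$M(\theta) = (F + (1-F)e^\theta)^{\langle B\rangle/(1-F)}$ interpolates
fixed ($F=0$), binomial ($0<F<1$), Poisson ($F=1$) and negative binomial
($F>1$, geometric at $F = 1+\langle B\rangle$) burst sizes. For
$0 < F < 1$ a pmf exists only when the trial count
$\langle B\rangle/(1-F)$ is an integer; for fractional counts the MGF is
still a perfectly good analytic object, and the whole Hamiltonian/
potential machinery needs nothing else. `burst_distribution()` therefore
returns an MGF-only object in that case, and Fano-factor sweeps at fixed
mean (e.g. mean 1 with $F \in \{0, 0.25, 0.5, 0.75\}$) run through the
WKB pipeline, while the CME and SSA solvers — which genuinely need burst
samples — refuse such inputs. Unbounded pmfs are truncated at upper-tail
mass $10^{-12}$ and renormalised; MGF values always use the closed form.
The feedback response is kept real-valued (the example regimes use rates
like 2.5), not integer-valued.

## Tunable parameters

| parameter | meaning | default |
|---|---|---|
| `epsilon` | activation/turnover timescale ratio (dimensionless) | 0.1; validation uses 0.1, 0.05, 0.02 |
| `s_max` | active-protein cap (molecules) | `choose_smax()` rule; 20 in all bundled regimes |
| `n_grid` | branch grid points | 2001 |
| `margin` | branch margin beyond outer fixed points (concentration) | half the fixed-point span |
| `tail_cutoff` | burst pmf truncation mass | 1e-12 |
| `X_max` | CME lattice bound (molecules) | $4\lceil x_+/\varepsilon\rceil$ |

## What the example regimes probe, and known limitations

The four bundled step-feedback regimes (`model_preset()`) pair a
negative-feedback monostable case with a positive-feedback bistable case,
each at burst size 1 and at burst size 4 with frequencies divided by four.
Each pair shares the same rate equation, isolating the effect of
burstiness: the potential wells of the burstier member are strictly
shallower (`well_depths()`), as are wells under increasing burst-size
Fano factor — burstier production inflates fluctuations and eases escape
from a well without moving the deterministic attractors.

These are synthetic regimes: step feedback, one protein species, Markovian
kinetics, a single exponential delay stage. Passing validation here shows
the asymptotic machinery is implemented correctly, not that real gene
circuits satisfy the model's assumptions (cooperative sigmoidal feedback,
timescale separation, stationarity).

Accuracy of the final mixture is limited by the parabolic (Laplace) step,
not by the WKB solution itself. In the bistable regime the mode weights
agree with the basin masses of the truncated-CME reference to a few parts
in a thousand already at $\varepsilon = 0.05$, and the *unexpanded* WKB
marginal $k(x)e^{-\Phi(x)/\varepsilon}$ matches the CME inactive-protein
marginal to total variation $\approx 0.008$ at $\varepsilon = 0.02$; the
Gaussian mode shapes, however, ignore the skewness of the shallow wells
and leave a per-mode total-variation error of order $0.06$ at these
$\varepsilon$, shrinking only like $\sqrt{\varepsilon}$. The
active-protein (Poisson-mixture) marginal converges faster and is within
0.03 of the CME at $\varepsilon = 0.02$ for all bundled regimes. Escape
rates between modes, multi-stage (phase-type) delays, and coupled
multi-gene circuits are outside the package's scope.

Degenerate inputs are reported rather than guessed at: tangent (double)
fixed points raise an error, as does a branch point where the chord
function cannot be bracketed (which would signal $H_\theta = 0$ between
saddles — not observed in any bundled regime).

## Problem sizes used in validation

The shipped test-and-validation suite runs entirely on synthetic inputs
generated in code: branch grids of 801–2001 points, CME lattices up to
order $\sim 4\times 10^4$, and Gillespie runs of $1$–$2 \times 10^6$
events, sizes at which every check completes in seconds to a few minutes
on a single core while leaving the asymptotic comparisons
($\varepsilon$ down to 0.02) well resolved.

## A worked bistable example

```{r example, eval = FALSE}
model <- model_preset("pos_fb_fig4", epsilon = 0.05)
fit <- wkb_steady_state(model)
summary(fit)
plot(fit)

# reference comparison
cme <- cme_steady_state(model)
tv_distance(marginal_s(fit$mixture), marginal_s(cme))

# stochastic path from the fitted mechanism
sim <- simulate(fit, seed = 1, t_end = 200, burn_in = 20)
```
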