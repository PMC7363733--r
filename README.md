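# burstwkb

Steady-state analysis of stochastic gene expression with **bursty
production**, a **one-step (exponential) production delay**, and
**feedback** in the burst frequency — for quantitative/systems biologists
and applied mathematicians studying noise-driven multimodality in gene
circuits.

## The model and the method

Two species: an inactive protein X, produced in bursts of size
$B \sim b_j$ (mean $\langle B\rangle$, Fano factor $F$) at rate
$\varepsilon^{-1} f_s$, and an active protein S obtained from X by a
single memoryless activation step (rate $X$), decaying at rate
$\varepsilon^{-1} s$; the feedback response $f_s$ (e.g. a step function
with levels $a_0, a_1$ at threshold $s_{\rm thresh}$) closes the loop. In
the slow-activation regime $\varepsilon \ll 1$ the inactive protein
concentration $x = \varepsilon X$ obeys an emergent rate equation
$\dot x = \langle B\rangle \bar f(x) - x$, where
$\bar f(x) = \sum_s f_s \rho_s(x)$ averages the response over the
truncated-Poisson quasi-steady state $\rho_s(x)$ of the fast
active-protein loss queue.

The stationary distribution is built by a WKB (large-deviation) expansion
$p(x,s) \sim k(x)\,w_s(x)\,e^{-\Phi(x)/\varepsilon}$:

* the Hamiltonian $H(x, \theta)$ is the principal eigenvalue of a
  tridiagonal matrix $A(x,\theta)$ assembled from the reaction channels;
* the quasipotential derivative $\Phi'(x)$ is the nontrivial branch of
  the zero-level set $H = 0$, traced between the saddles at the
  rate-equation fixed points;
* the prefactor $k(x)$ solves the next-order solvability condition;
* around each stable fixed point $x_*$ the distribution collapses to a
  mode — Gaussian in $X$ (mean $x_*/\varepsilon$, variance
  $1/\varepsilon\Phi''(x_*)$), truncated Poisson $\rho_s(x_*)$ in $s$ —
  with weight
  $\omega_* \propto k(x_*)\,\Phi''(x_*)^{-1/2}\,e^{-\Phi(x_*)/\varepsilon}$.

Ground truth comes from a sparse nullvector solve of the truncated
chemical master equation and an exact Gillespie simulator (compiled inner
loop).

## Worked example: a bistable positive-feedback circuit

```r
library(burstwkb)
model <- model_preset("pos_fb_fig4", epsilon = 0.05)  # B = 4, a0 = 0.5, a1 = 2.5
fit <- wkb_steady_state(model)
summary(fit)
```

```
Fixed points of the rate equation:
       x stable   lambda    role
1 2.1988   TRUE -0.61987 x_minus
2 4.8202  FALSE  0.39910  x_zero
3 9.1399   TRUE -0.54413  x_plus

Mixture modes (epsilon = 0.05 ):
  x_star      phi curvature prefactor_value  weight
1 2.1988 0.021597  0.115312         1.00000 0.57142
2 9.1399 0.000000  0.024891         0.22624 0.42858

Potential well depths: 0.06486, 0.08646
max |H| along branch: 1.98e-13
```

The rate equation is bistable: low- and high-expression states at
concentrations 2.20 and 9.14 separated by an unstable point at 4.82
(`lambda` is the linear relaxation rate). The high well is deeper
(potential difference 0.0216), but its smaller curvature and prefactor
leave the weights balanced at this $\varepsilon$: the cell population
splits roughly 57/43 between the low and high modes. As $\varepsilon$
decreases the deeper well takes all the weight. The WKB branch lies on
the Hamiltonian zero-level set to $2\times 10^{-13}$.

```r
cme <- cme_steady_state(model)             # truncated-CME reference
tv_distance(marginal_s(fit$mixture), marginal_s(cme))
#> 0.0455
sim <- simulate(fit, seed = 1, t_end = 200, burn_in = 20)  # Gillespie
```

`plot(fit)` draws the double-well potential and the bimodal
inactive-protein marginal; `run_pipeline("pos_fb_fig4", out_dir = "out")`
writes the branch table, mode summary, marginals, comparison metrics and
a run manifest as delimited text/YAML. A thin command-line wrapper lives
in `inst/scripts/burstwkb`.

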