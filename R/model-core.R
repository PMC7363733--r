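#' Burst-size distributions parametrised by mean and Fano factor
#'
#' Constructs the burst-size distribution of the one-parameter MGF family
#' \deqn{M(\theta) = (F + (1-F)e^\theta)^{\langle B\rangle/(1-F)},}
#' parametrised by the mean \eqn{\langle B\rangle > 0} and the Fano factor
#' \eqn{F \ge 0} (variance-to-mean ratio), or an explicit pmf. The family
#' interpolates the standard burst models of stochastic gene expression:
#' \describe{
#'   \item{`fano = 0`}{a fixed (deterministic) burst size `B = mean`
#'     (`mean` must then be a positive integer);}
#'   \item{`0 < fano < 1`}{a binomial distribution with `mean/(1-fano)`
#'     trials and success probability `1-fano`;}
#'   \item{`fano = 1`}{a Poisson distribution with rate `mean`;}
#'   \item{`fano > 1`}{a negative binomial distribution; `fano = 1 + mean`
#'     gives the geometric burst-size distribution.}
#' }
#'
#' For the binomial regime the trial count `mean/(1-fano)` must be a
#' positive integer for a pmf to exist. When it is fractional the MGF above
#' is still a perfectly good analytic object and drives the whole WKB
#' machinery (Hamiltonian, potential, prefactor), so the distribution is
#' constructed in "MGF-only" form with `pmf = NULL`; operations that need
#' actual burst sampling or lattice bursts (the CME generator, the Gillespie
#' simulator) refuse such distributions.
#'
#' Unbounded pmfs (Poisson, negative binomial) are truncated where the
#' upper-tail mass drops below `tail_cutoff` and renormalised; MGF values
#' always use the closed-form family expression.
#'
#' @param mean positive mean burst size \eqn{\langle B\rangle}.
#' @param fano non-negative Fano factor \eqn{F}. Ignored when `pmf` is given.
#' @param pmf optional explicit probability vector `b_j` over burst sizes
#'   `j = 0, 1, ...` (element 1 is `b_0`). Overrides `mean`/`fano`.
#' @param tail_cutoff tail-mass tolerance for truncating unbounded pmfs.
#' @return an object of class `burst_distribution`: a list with elements
#'   `family` (one of `"fixed"`, `"binomial"`, `"poisson"`,
#'   `"negative_binomial"`, `"explicit"`), `mean`, `fano`, `pmf` (or `NULL`
#'   for MGF-only binomial), and `support` (integer burst sizes of `pmf`).
#' @seealso [burst_mgf()], [burst_model()]
#' @examples
#' burst_distribution(mean = 2, fano = 0.5)$pmf   # binomial(4, 1/2)
#' burst_distribution(mean = 4, fano = 0)         # fixed burst size 4
#' geo <- burst_distribution(mean = 1, fano = 2)  # geometric
#' burst_mgf(geo, -0.3)
#' @export
burst_distribution <- function(mean, fano = 0, pmf = NULL,
                               tail_cutoff = 1e-12) {
  if (!is.null(pmf)) {
    if (any(pmf < 0) || any(!is.finite(pmf)))
      stop("explicit pmf must be non-negative and finite")
    if (abs(sum(pmf) - 1) > 1e-8)
      stop("explicit pmf must sum to 1")
    pmf <- pmf / sum(pmf)
    j <- seq_along(pmf) - 1L
    m <- sum(j * pmf)
    v <- sum(j^2 * pmf) - m^2
    out <- list(family = "explicit", mean = m,
                fano = if (m > 0) v / m else 0,
                pmf = pmf, support = j)
    class(out) <- "burst_distribution"
    return(out)
  }
  stopifnot(is.numeric(mean), length(mean) == 1L, is.numeric(fano),
            length(fano) == 1L)
  if (mean <= 0) stop("mean burst size must be positive")
  if (fano < 0) stop("Fano factor must be non-negative")

  if (fano == 0) {
    if (abs(mean - round(mean)) > 1e-9)
      stop("a fixed burst size (fano = 0) requires an integer mean")
    B <- as.integer(round(mean))
    p <- c(rep(0, B), 1)
    fam <- "fixed"
  } else if (fano < 1) {
    ntrial <- mean / (1 - fano)
    if (abs(ntrial - round(ntrial)) > 1e-9 * max(1, ntrial)) {
      # fractional trial count: analytic MGF family without a pmf
      out <- list(family = "binomial", mean = mean, fano = fano,
                  pmf = NULL, support = NULL)
      class(out) <- "burst_distribution"
      return(out)
    }
    n <- as.integer(round(ntrial))
    p <- dbinom(0:n, size = n, prob = 1 - fano)
    fam <- "binomial"
  } else if (fano == 1) {
    jmax <- max(stats::qpois(1 - tail_cutoff, lambda = mean), 2)
    p <- dpois(0:jmax, lambda = mean)
    p <- p / sum(p)
    fam <- "poisson"
  } else {
    size <- mean / (fano - 1)
    jmax <- max(stats::qnbinom(1 - tail_cutoff, size = size,
                               prob = 1 / fano), 2)
    p <- dnbinom(0:jmax, size = size, prob = 1 / fano)
    p <- p / sum(p)
    fam <- "negative_binomial"
  }
  out <- list(family = fam, mean = mean, fano = fano, pmf = p,
              support = seq_along(p) - 1L)
  class(out) <- "burst_distribution"
  out
}

#' @export
#' @method print burst_distribution
print.burst_distribution <- function(x, ...) {
  cat("Burst-size distribution (", x$family, ")\n", sep = "")
  cat("  mean <B> =", format(x$mean), "  Fano factor F =", format(x$fano),
      "\n")
  if (is.null(x$pmf))
    cat("  MGF-only (fractional binomial trial count); no pmf available\n")
  else
    cat("  pmf support 0..", max(x$support), "\n", sep = "")
  invisible(x)
}

#' Moment generating function of a burst-size distribution
#'
#' Evaluates \eqn{M(\theta) = \sum_j b_j e^{j\theta}} or its first or second
#' derivative in \eqn{\theta}. For the mean/Fano families the closed-form
#' expression of the MGF family is used (exact even where the stored pmf is
#' truncated); for explicit pmfs the defining sum is evaluated. Note
#' `burst_mgf(d, 0, 1)` is the mean burst size and `burst_mgf(d, 0, 2)` the
#' second moment \eqn{\langle B^2\rangle}.
#'
#' @param dist a [burst_distribution()].
#' @param theta real argument; vectorised.
#' @param order derivative order, one of 0, 1, 2.
#' @return numeric vector of the same length as `theta`.
#' @export
burst_mgf <- function(dist, theta, order = 0L) {
  stopifnot(inherits(dist, "burst_distribution"))
  if (!(length(order) == 1L && order %in% 0:2))
    stop("order must be 0, 1 or 2")
  if (dist$family == "explicit") {
    j <- dist$support
    return(vapply(theta, function(th)
      sum(dist$pmf * j^order * exp(j * th)), numeric(1)))
  }
  m <- dist$mean
  Fa <- dist$fano
  if (dist$family == "poisson") {
    lam <- m
    M <- exp(lam * (exp(theta) - 1))
    return(switch(as.character(order),
                  "0" = M,
                  "1" = lam * exp(theta) * M,
                  "2" = (lam * exp(theta) + (lam * exp(theta))^2) * M))
  }
  # common closed form for fixed / binomial / negative binomial
  r <- m / (1 - Fa)
  base <- Fa + (1 - Fa) * exp(theta)
  if (any(base <= 0))
    stop("MGF undefined: theta beyond the convergence boundary")
  q <- (1 - Fa) * exp(theta)                 # d base / d theta
  switch(as.character(order),
         "0" = base^r,
         "1" = r * q * base^(r - 1),
         "2" = r * q * base^(r - 2) * ((r - 1) * q + base))
}

#' Step feedback response and explicit response tables
#'
#' `step_response()` builds the step burst-frequency response
#' \eqn{f_s = a_0} for `s < s_thresh` and \eqn{f_s = a_1} for
#' `s >= s_thresh`, on `s = 0, ..., s_max`. `feedback_response()` wraps an
#' arbitrary non-negative rate table.
#'
#' @param s_max upper bound on the active protein count (response has
#'   `s_max + 1` entries).
#' @param s_thresh integer threshold in `0..s_max+1`; a threshold of 0 gives
#'   the constant response `a1`, a threshold of `s_max + 1` the constant
#'   response `a0`.
#' @param a0,a1 non-negative burst frequencies below/above the threshold.
#' @return an object of class `feedback_response` with elements `rates`
#'   (length `s_max + 1`), `s_max`, and for step responses `s_thresh`,
#'   `a0`, `a1`.
#' @examples
#' step_response(20, 6, a0 = 2, a1 = 10)$rates
#' @export
step_response <- function(s_max, s_thresh, a0, a1) {
  s_max <- as.integer(s_max)
  if (s_max < 0) stop("s_max must be non-negative")
  if (a0 < 0 || a1 < 0) stop("rates must be non-negative")
  if (s_thresh < 0 || s_thresh > s_max + 1)
    stop("s_thresh must lie in 0..s_max+1")
  s <- 0:s_max
  rates <- ifelse(s < s_thresh, a0, a1)
  out <- list(rates = as.numeric(rates), s_max = s_max,
              s_thresh = as.integer(s_thresh), a0 = a0, a1 = a1)
  class(out) <- "feedback_response"
  out
}

#' @rdname step_response
#' @param rates explicit non-negative rate vector `f_s`, `s = 0..s_max`.
#' @export
feedback_response <- function(rates) {
  if (any(rates < 0) || any(!is.finite(rates)))
    stop("feedback rates must be non-negative and finite")
  out <- list(rates = as.numeric(rates), s_max = length(rates) - 1L,
              s_thresh = NULL, a0 = NULL, a1 = NULL)
  class(out) <- "feedback_response"
  out
}

#' @export
#' @method print feedback_response
print.feedback_response <- function(x, ...) {
  cat("Feedback response on s = 0..", x$s_max, "\n", sep = "")
  if (!is.null(x$s_thresh))
    cat("  step: a0 =", x$a0, "below s_thresh =", x$s_thresh,
        ", a1 =", x$a1, "above\n")
  else cat("  explicit table; range [", min(x$rates), ",", max(x$rates),
           "]\n")
  invisible(x)
}

#' Choose the active-protein cap from the maximal production rate
#'
#' Returns the smallest integer `s` whose decay rate `s` is at least twice
#' the maximal mean production rate `<B> * max_rate`. With this choice the
#' cap is reached rarely and its effect on the dynamics is negligible.
#'
#' @param burst a [burst_distribution()].
#' @param max_rate maximal burst frequency `max_s f_s`.
#' @return integer cap `s_max`.
#' @examples
#' choose_smax(burst_distribution(1, 0), 10)  # 20
#' @export
choose_smax <- function(burst, max_rate) {
  stopifnot(inherits(burst, "burst_distribution"))
  if (max_rate <= 0) stop("max_rate must be positive")
  as.integer(ceiling(2 * burst$mean * max_rate))
}

#' Delayed-feedback bursty expression model
#'
#' Bundles a burst-size distribution, a feedback response, the active
#' protein cap `s_max` and the timescale-separation parameter `epsilon`
#' into a model object. The model has three reaction channels: production
#' of a burst of `B` inactive proteins at rate `f_s / epsilon`, activation
#' of one inactive protein at rate `X` (capping `s` at `s_max`), and decay
#' of one active protein at rate `s / epsilon`. `epsilon << 1` is the
#' slow-activation (large production delay) regime in which the WKB
#' analysis applies.
#'
#' @param burst a [burst_distribution()].
#' @param feedback a [feedback_response()], or a list
#'   `list(s_thresh=, a0=, a1=)` of step parameters (then `s_max` may be
#'   `NULL`/`"auto"` to apply the [choose_smax()] rule).
#' @param epsilon timescale parameter in (0, 1].
#' @param s_max optional explicit cap; must agree with the feedback length
#'   when a full `feedback_response` is given.
#' @return an object of class `burst_model`.
#' @examples
#' m <- burst_model(burst_distribution(1, 0),
#'                  list(s_thresh = 6, a0 = 2, a1 = 10), epsilon = 0.05)
#' m$s_max  # 20, from the doubled-maximal-production rule
#' @export
burst_model <- function(burst, feedback, epsilon = 0.1, s_max = NULL) {
  stopifnot(inherits(burst, "burst_distribution"))
  if (!(is.numeric(epsilon) && length(epsilon) == 1L && epsilon > 0 &&
        epsilon <= 1))
    stop("epsilon must lie in (0, 1]")
  if (inherits(feedback, "feedback_response")) {
    if (!is.null(s_max) && !identical(s_max, "auto") &&
        as.integer(s_max) != feedback$s_max)
      stop("s_max disagrees with the length of the feedback response")
    s_max <- feedback$s_max
  } else if (is.list(feedback) &&
             all(c("s_thresh", "a0", "a1") %in% names(feedback))) {
    if (is.null(s_max) || identical(s_max, "auto"))
      s_max <- choose_smax(burst, max(feedback$a0, feedback$a1))
    feedback <- step_response(s_max, feedback$s_thresh, feedback$a0,
                              feedback$a1)
  } else stop("feedback must be a feedback_response or step parameters")
  out <- list(burst = burst, feedback = feedback,
              s_max = as.integer(s_max), epsilon = epsilon)
  class(out) <- "burst_model"
  out
}

#' @export
#' @method print burst_model
print.burst_model <- function(x, ...) {
  cat("Delayed-feedback bursty expression model\n")
  cat("  s_max =", x$s_max, " epsilon =", x$epsilon, "\n")
  print(x$burst)
  print(x$feedback)
  invisible(x)
}

#' Read or write a model configuration file
#'
#' The configuration is a YAML file with sections `burst` (`mean`, `fano`
#' or an explicit `pmf`), `feedback` (`s_thresh`, `a0`, `a1` or an explicit
#' `rates` table) and `model` (`s_max`, possibly `"auto"`, and `epsilon`).
#'
#' @param path file path.
#' @return `read_model_config()` returns a [burst_model()];
#'   `write_model_config()` invisibly returns `path`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in c("burst", "feedback", "model"))
    if (is.null(cfg[[sec]]))
      stop("config is missing the [", sec, "] section")
  b <- cfg$burst
  burst <- if (!is.null(b$pmf)) burst_distribution(pmf = as.numeric(b$pmf))
           else {
             if (is.null(b$mean)) stop("config key burst.mean is missing")
             burst_distribution(mean = b$mean,
                                fano = if (is.null(b$fano)) 0 else b$fano)
           }
  mo <- cfg$model
  if (is.null(mo$epsilon)) stop("config key model.epsilon is missing")
  s_max <- if (is.null(mo$s_max)) "auto" else mo$s_max
  fb <- cfg$feedback
  if (!is.null(fb$rates)) {
    feedback <- feedback_response(as.numeric(fb$rates))
  } else {
    for (k in c("s_thresh", "a0", "a1"))
      if (is.null(fb[[k]])) stop("config key feedback.", k, " is missing")
    feedback <- list(s_thresh = fb$s_thresh, a0 = fb$a0, a1 = fb$a1)
  }
  burst_model(burst, feedback, epsilon = mo$epsilon, s_max = s_max)
}

#' @rdname read_model_config
#' @param model a [burst_model()].
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "burst_model"))
  fb <- model$feedback
  cfg <- list(
    burst = if (model$burst$family == "explicit")
      list(pmf = as.numeric(model$burst$pmf))
    else list(mean = model$burst$mean, fano = model$burst$fano),
    feedback = if (!is.null(fb$s_thresh))
      list(s_thresh = fb$s_thresh, a0 = fb$a0, a1 = fb$a1)
    else list(rates = as.numeric(fb$rates)),
    model = list(s_max = model$s_max, epsilon = model$epsilon))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
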