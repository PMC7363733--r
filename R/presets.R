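#' Bundled example parameter regimes
#'
#' Four step-feedback regimes used throughout the package's examples and
#' validation, plus a Fano-factor sweep family:
#' \describe{
#'   \item{`"neg_fb_fig1"`}{negative feedback, fixed burst `B = 1`,
#'     `a0 = 10`, `a1 = 2`;}
#'   \item{`"pos_fb_fig1"`}{positive feedback, fixed burst `B = 1`,
#'     `a0 = 2`, `a1 = 10` (bistable);}
#'   \item{`"neg_fb_fig3"`}{negative feedback, fixed burst `B = 4`,
#'     `a0 = 2.5`, `a1 = 0.5` (monostable);}
#'   \item{`"pos_fb_fig4"`}{positive feedback, fixed burst `B = 4`,
#'     `a0 = 0.5`, `a1 = 2.5` (bistable);}
#'   \item{`"fano_sweep_fig2"`}{mean burst size 1 with a tunable Fano
#'     factor (`fano` argument), `a0 = 2`, `a1 = 10`.}
#' }
#' All presets use the step threshold `s_thresh = 6` and derive
#' `s_max = 20` from the doubled-maximal-production rule ([choose_smax()]).
#' Note the `B = 4` regimes divide the burst frequencies of the `B = 1`
#' regimes by four, so each pair shares the same deterministic rate
#' equation while differing in burstiness.
#'
#' @param name preset name.
#' @param epsilon timescale parameter for the returned model.
#' @param fano Fano factor for `"fano_sweep_fig2"` (default 0; fractional
#'   binomial trial counts give MGF-only distributions usable by the WKB
#'   machinery but not by the CME/SSA solvers).
#' @return a [burst_model()].
#' @examples
#' model_preset("pos_fb_fig4")$feedback$a1  # 2.5
#' @export
model_preset <- function(name = c("neg_fb_fig1", "pos_fb_fig1",
                                  "neg_fb_fig3", "pos_fb_fig4",
                                  "fano_sweep_fig2"),
                         epsilon = 0.05, fano = 0) {
  name <- match.arg(name)
  par <- switch(name,
    neg_fb_fig1 = list(mean = 1, fano = 0, a0 = 10, a1 = 2),
    pos_fb_fig1 = list(mean = 1, fano = 0, a0 = 2, a1 = 10),
    neg_fb_fig3 = list(mean = 4, fano = 0, a0 = 2.5, a1 = 0.5),
    pos_fb_fig4 = list(mean = 4, fano = 0, a0 = 0.5, a1 = 2.5),
    fano_sweep_fig2 = list(mean = 1, fano = fano, a0 = 2, a1 = 10))
  burst_model(burst_distribution(par$mean, par$fano),
              list(s_thresh = 6L, a0 = par$a0, a1 = par$a1),
              epsilon = epsilon, s_max = "auto")
}

#' Timescale parameters used in the scaled validation runs
#'
#' The slow-activation values at which the mixture approximation is
#' compared against the truncated-CME reference.
#'
#' @return numeric vector `c(0.1, 0.05, 0.02)`.
#' @export
preset_epsilons <- function() c(0.1, 0.05, 0.02)
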