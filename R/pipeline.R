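#' End-to-end analysis pipeline with file outputs
#'
#' Runs fixed points -> branch -> potential -> prefactor -> mixture ->
#' truncated-CME reference (and optionally a Gillespie cross-check) for a
#' model or named preset, and writes delimited-text outputs plus a
#' machine-readable run manifest to `out_dir`:
#' `branch.tsv` (x, theta, phi, k, w_0..w_smax), `mixture_modes.tsv`,
#' `wkb_marginal_X.tsv`, `wkb_marginal_s.tsv`, `cme_marginal_X.tsv`,
#' `cme_marginal_s.tsv`, optional `ssa_marginal_*.tsv`, `metrics.yaml`
#' (total-variation distances, residuals, boundary mass) and
#' `manifest.yaml` (parameters, seed, grid sizes).
#'
#' @param model a [burst_model()] or a preset name for [model_preset()].
#' @param epsilon timescale parameter (overrides the model's).
#' @param out_dir output directory, created if needed; `NULL` skips all
#'   file output.
#' @param seed integer seed controlling the (optional) SSA stage.
#' @param run_ssa also run the Gillespie cross-check.
#' @param ssa_t_end,ssa_burn_in SSA horizon (model time units).
#' @param n_grid branch grid size.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with `fit` (the [wkb_steady_state()]
#'   object), `cme`, optional `ssa`, and `metrics`.
#' @export
run_pipeline <- function(model, epsilon = NULL, out_dir = NULL, seed = 1L,
                         run_ssa = FALSE, ssa_t_end = 2000,
                         ssa_burn_in = 50, n_grid = 2001L,
                         quiet = FALSE) {
  if (is.character(model)) model <- model_preset(model)
  stopifnot(inherits(model, "burst_model"))
  if (is.null(epsilon)) epsilon <- model$epsilon
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  fit <- stage("wkb", wkb_steady_state(model, epsilon = epsilon,
                                       n_grid = n_grid))
  cme <- stage("cme", cme_steady_state(model, epsilon = epsilon))
  wkb_pX <- marginal_X(fit$mixture, X_grid = 0:cme$X_max)
  wkb_ps <- marginal_s(fit$mixture)
  metrics <- list(
    tv_marginal_X = tv_distance(wkb_pX, marginal_X(cme)),
    tv_marginal_s = tv_distance(wkb_ps, marginal_s(cme)),
    cme_residual = cme$residual,
    cme_boundary_mass = cme$boundary_mass,
    max_H_residual = max(abs(fit$branch$H_resid)))
  ssa <- NULL
  if (run_ssa) {
    ssa <- stage("ssa", ssa_simulate(model, t_end = ssa_t_end,
                                     burn_in = ssa_burn_in, seed = seed,
                                     epsilon = epsilon))
    metrics$tv_ssa_cme_joint <- tv_distance(
      as.numeric(ssa$probs[seq_len(min(nrow(ssa$probs),
                                       cme$X_max + 1L)), ]),
      as.numeric(cme$probs))
    metrics$ssa_events <- ssa$events
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    two_col <- function(p, path, key = "state") {
      tab <- data.frame(seq_along(p) - 1L, as.numeric(p))
      names(tab) <- c(key, "probability")
      write.table(tab, file.path(out_dir, path), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    }
    write_branch(fit$branch, file.path(out_dir, "branch.tsv"))
    write.table(fit$mixture$modes, file.path(out_dir, "mixture_modes.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    two_col(wkb_pX, "wkb_marginal_X.tsv", "X")
    two_col(wkb_ps, "wkb_marginal_s.tsv", "s")
    two_col(marginal_X(cme), "cme_marginal_X.tsv", "X")
    two_col(marginal_s(cme), "cme_marginal_s.tsv", "s")
    joint_tab <- function(probs, path) {
      tab <- as.data.frame(probs)
      names(tab) <- paste0("s_", seq_len(ncol(probs)) - 1L)
      write.table(tab, file.path(out_dir, path), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    }
    joint_tab(cme$probs, "cme_joint.tsv")
    if (run_ssa) {
      two_col(marginal_X(ssa), "ssa_marginal_X.tsv", "X")
      two_col(marginal_s(ssa), "ssa_marginal_s.tsv", "s")
      joint_tab(ssa$probs, "ssa_joint.tsv")
    }
    yaml::write_yaml(metrics, file.path(out_dir, "metrics.yaml"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("burstwkb")),
      parameters = list(
        burst_mean = model$burst$mean, burst_fano = model$burst$fano,
        burst_family = model$burst$family, s_max = model$s_max,
        epsilon = epsilon,
        feedback = if (!is.null(model$feedback$s_thresh))
          list(s_thresh = model$feedback$s_thresh,
               a0 = model$feedback$a0, a1 = model$feedback$a1)
        else list(rates = as.numeric(model$feedback$rates))),
      n_grid = n_grid, X_max = cme$X_max, seed = seed,
      run_ssa = run_ssa)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(list(fit = fit, cme = cme, ssa = ssa, metrics = metrics))
}
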