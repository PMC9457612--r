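#' Time course of the three beta-catenin forms
#'
#' Domain integrals of unphosphorylated, primed (P1) and fully
#' phosphorylated (P4) beta-catenin at every recorded step.  The cascade
#' only converts between the three forms, so their summed integral is
#' conserved.
#'
#' @param traj A trajectory from [ch_run()] / [run_sim()].
#' @return Data frame with columns `step, time, bcat, bcat_p1, bcat_p4,
#'   total`.
#' @export
species_timecourse <- function(traj) {
  d <- traj$diagnostics
  need <- c("total_BCAT", "total_BCAT_P1", "total_BCAT_P4")
  if (!all(need %in% names(d))) {
    stop("trajectory does not carry the beta-catenin components")
  }
  out <- data.frame(step = d$step, time = d$time,
                    bcat = d$total_BCAT, bcat_p1 = d$total_BCAT_P1,
                    bcat_p4 = d$total_BCAT_P4)
  out$total <- out$bcat + out$bcat_p1 + out$bcat_p4
  out
}

#' Nucleation efficiency of beta-catenin processing
#'
#' Compares the ratio of integrated P4-beta-catenin to beta-catenin between
#' otherwise-identical simulations with and without a nucleator:
#' `efficiency = [P4/bcat]_nucleated / [P4/bcat]_free` at `eval_step`.
#' Values above 1 mean the nucleated system processed beta-catenin more
#' completely.
#'
#' @param traj_nucleated,traj_free Paired trajectories (see
#'   [paired_configs()]).
#' @param eval_step Step at which to evaluate; default the last step
#'   recorded in both trajectories.
#' @param floor Lower bound on the integrated beta-catenin below which the
#'   ratio is considered numerically hazardous (default 1e-12 of the
#'   domain).
#' @return An `efficiency_result` list: `ratio_nucleated, ratio_free,
#'   efficiency, eval_step`.
#' @export
nucleation_efficiency <- function(traj_nucleated, traj_free,
                                  eval_step = NULL, floor = 1e-12) {
  dn <- traj_nucleated$diagnostics
  df <- traj_free$diagnostics
  if (is.null(eval_step)) eval_step <- min(max(dn$step), max(df$step))
  rn <- dn[dn$step == eval_step, ]
  rf <- df[df$step == eval_step, ]
  if (nrow(rn) != 1L || nrow(rf) != 1L) {
    stop("eval_step ", eval_step, " is not recorded in both trajectories")
  }
  if (rn$total_BCAT < floor || rf$total_BCAT < floor) {
    stop("integrated beta-catenin below floor; ratio is ill-defined")
  }
  ratio_n <- rn$total_BCAT_P4 / rn$total_BCAT
  ratio_f <- rf$total_BCAT_P4 / rf$total_BCAT
  structure(list(ratio_nucleated = ratio_n, ratio_free = ratio_f,
                 efficiency = ratio_n / ratio_f,
                 eval_step = as.integer(eval_step)),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf(
    "<efficiency_result> step %d: P4/bcat nucleated %.4g, free %.4g, efficiency %.4g\n",
    x$eval_step, x$ratio_nucleated, x$ratio_free, x$efficiency))
  invisible(x)
}

#' Partition coefficient of a component over a region
#'
#' Mean volume fraction over the masked region divided by the mean over its
#' complement — the simulation analogue of a puncta:cytoplasm fluorescence
#' ratio, measuring enrichment at the nucleator.
#'
#' @param state A [field_state()].
#' @param mask Logical matrix marking the region (non-empty, non-full).
#' @param component Component role or index.
#' @return Scalar enrichment ratio.
#' @export
partition_coefficient <- function(state, mask, component) {
  if (!any(mask) || all(mask)) stop("mask must be non-empty and non-full")
  k <- component_index(component, state$components)
  u <- state$phi[, , k]
  mean(u[mask]) / mean(u[!mask])
}
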