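# Parameter scans of the nucleation-efficiency statistic.  Every scan point
# runs a matched nucleated/free pair sharing the same seed, so efficiency
# differences are attributable to nucleation alone, and each output row
# carries the nucleated config hash + seed for bit-identical re-runs.

run_efficiency_pair <- function(nucleated_cfg, eval_step = NULL) {
  pair <- paired_configs(nucleated_cfg)
  tn <- run_sim(pair$nucleated)
  tf <- run_sim(pair$free)
  list(eff = nucleation_efficiency(tn, tf, eval_step = eval_step),
       nucleated = tn, free = tf,
       hash = config_hash(pair$nucleated))
}

scan_row <- function(eff, hash, seed, extra) {
  cbind(extra,
        data.frame(ratio_nucleated = eff$ratio_nucleated,
                   ratio_free = eff$ratio_free,
                   efficiency = eff$efficiency,
                   eval_step = eff$eval_step,
                   config_hash = hash, seed = seed,
                   stringsAsFactors = FALSE))
}

#' Scan nucleation efficiency over the phosphorylation rates
#'
#' Runs one matched nucleated/free pair for every `(k1, k2)` combination
#' and records the efficiency — the in-silico analogue of mapping how fast
#' kinetics erase the benefit of nucleated condensation.
#'
#' @param k1_values,k2_values Positive rate values for the CK1alpha priming
#'   and GSK3beta completion steps.
#' @param base_config Template [run_config()] (its nucleator defines the
#'   nucleated twin).
#' @param seed Root seed shared by every pair.
#' @param eval_step Efficiency evaluation step (default: final step).
#' @return Data frame, one row per grid cell (`k1, k2, ratio_nucleated,
#'   ratio_free, efficiency, eval_step, config_hash, seed`).
#' @export
scan_rates <- function(k1_values, k2_values, base_config = run_config(),
                       seed = 1L, eval_step = NULL) {
  if (any(k1_values <= 0) || any(k2_values <= 0)) {
    stop("rate values must be positive")
  }
  cfg <- validate_run_config(base_config)
  cfg$seed <- as.integer(seed)
  rows <- list()
  for (k1 in k1_values) {
    for (k2 in k2_values) {
      cell <- cfg
      cell$rates <- list(k1 = k1, k2 = k2)
      res <- tryCatch(run_efficiency_pair(cell, eval_step), error = function(e) {
        stop(sprintf("scan cell (k1=%g, k2=%g) failed: %s", k1, k2,
                     conditionMessage(e)), call. = FALSE)
      })
      rows[[length(rows) + 1L]] <-
        scan_row(res$eff, res$hash, seed, data.frame(k1 = k1, k2 = k2))
    }
  }
  do.call(rbind, rows)
}

#' Scan nucleation efficiency over a client-cytoplasm interaction
#'
#' Varies only the chi between one DC client and the cytoplasm (all other
#' interactions at their defaults) and records, per value, the efficiency
#' and the client's partition coefficient at the nucleator in the final
#' nucleated state.  Increasing the free-energy penalty of client-
#' cytoplasm mixing drives greater client accumulation at the nucleator.
#'
#' @param chi_values Chi values for the client-cytoplasm pair (e.g. a sweep
#'   from separating, +2, down to neutral, 0).
#' @param client One of `GSK3B, CK1A, BCAT, BCAT_P1`.
#' @inheritParams scan_rates
#' @return Data frame, one row per chi value, including a
#'   `partition_coefficient` column.
#' @export
scan_client_chi <- function(chi_values, client = "GSK3B",
                            base_config = run_config(), seed = 1L,
                            eval_step = NULL) {
  client <- match.arg(client, c("GSK3B", "CK1A", "BCAT", "BCAT_P1"))
  cfg <- validate_run_config(base_config)
  cfg$seed <- as.integer(seed)
  chi0 <- config_chi(cfg)
  if (is.null(cfg$nucleator)) stop("base_config must carry a nucleator")
  rows <- list()
  for (cv in chi_values) {
    cell <- cfg
    cell$chi <- unclass(set_client_cytoplasm_chi(chi0, client, cv))
    res <- tryCatch(run_efficiency_pair(cell, eval_step), error = function(e) {
      stop(sprintf("scan cell (chi=%g) failed: %s", cv, conditionMessage(e)),
           call. = FALSE)
    })
    final <- snapshot_at(res$nucleated)
    mask <- nucleator_mask(final$grid, cfg$nucleator)
    pc <- partition_coefficient(final, mask, client)
    rows[[length(rows) + 1L]] <-
      scan_row(res$eff, res$hash, seed,
               data.frame(client = client, chi = cv,
                          partition_coefficient = pc,
                          stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Scan nucleation efficiency over the nucleator size
#'
#' One matched pair per disk radius; the free twin is always nucleator-free.
#'
#' @param radii Nucleator radii (fractions of the domain length).
#' @inheritParams scan_rates
#' @return Data frame, one row per radius.
#' @export
scan_nucleator_size <- function(radii, base_config = run_config(),
                                seed = 1L, eval_step = NULL) {
  cfg <- validate_run_config(base_config)
  cfg$seed <- as.integer(seed)
  base_spec <- if (!is.null(cfg$nucleator)) cfg$nucleator else nucleator_spec()
  rows <- list()
  for (r in radii) {
    cell <- cfg
    spec <- base_spec
    spec$radius <- r
    cell$nucleator <- do.call(nucleator_spec, unclass(spec))
    res <- tryCatch(run_efficiency_pair(cell, eval_step), error = function(e) {
      stop(sprintf("scan cell (radius=%g) failed: %s", r, conditionMessage(e)),
           call. = FALSE)
    })
    rows[[length(rows) + 1L]] <-
      scan_row(res$eff, res$hash, seed, data.frame(radius = r))
  }
  do.call(rbind, rows)
}
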