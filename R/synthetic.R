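# Synthetic-data generators: every input the pipeline consumes is built
# here from a (config, seed) pair, so all stages run without external data
# and every fixture regenerates bit-identically.

#' Two-component benchmark configuration
#'
#' Minimal solute + cytoplasm system used to validate the Cahn-Hilliard
#' core against the classical regimes: a separating chi drives spinodal
#' demixing (spatial variance of the noisy field grows), a binding or
#' neutral chi keeps the mixture homogeneous (variance decays by surface-
#' energy smoothing).
#'
#' @param grid Grid fields (default 64x64 unit square).
#' @param chi12 Solute-cytoplasm interaction parameter.
#' @param mean_fraction Mean solute fraction in (0, 1) (default 0.5, the
#'   symmetric deep-quench composition).
#' @param seed Root seed for the +/-5% initialization noise.
#' @param n_steps Steps to run (default 50).
#' @return A [run_config()] with components `SOLUTE, CYTOPLASM`.
#' @export
gen_benchmark_binary <- function(grid = list(nx = 64, ny = 64, lx = 1, ly = 1),
                                 chi12 = 2, mean_fraction = 0.5, seed = 1L,
                                 n_steps = 50L) {
  if (mean_fraction <= 0 || mean_fraction >= 1) {
    stop("mean_fraction must lie in (0, 1)")
  }
  chi <- matrix(c(0, chi12, chi12, 0), 2, 2,
                dimnames = list(c("SOLUTE", "CYTOPLASM"),
                                c("SOLUTE", "CYTOPLASM")))
  run_config(grid = grid, chi = chi, rates = NULL,
             means = c(SOLUTE = mean_fraction),
             nucleator = NULL,
             solver = list(n_steps = n_steps, snapshot_every = n_steps),
             seed = seed, components = c("SOLUTE", "CYTOPLASM"))
}

#' Default destruction-complex scenario (paired)
#'
#' The full 7-component system — default chi matrix, two-reaction
#' phosphorylation cascade, centrosome-like nucleator — as matched
#' nucleated/free configurations.  `overrides` patches any subset of the
#' default configuration (nested lists are merged; unknown keys are
#' rejected by validation).
#'
#' @param overrides Named list of [run_config()] fields to override, e.g.
#'   `list(rates = list(k1 = 1000, k2 = 1000))`.
#' @param seed Root seed shared by both twins.
#' @return List with `nucleated` and `free` [run_config()]s.
#' @export
gen_dc_scenario <- function(overrides = list(), seed = 1L) {
  cfg <- unclass(run_config(seed = seed))
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg <- validate_run_config(cfg)
  paired_configs(cfg, seed = seed)
}

#' Synthetic FRAP recovery trace
#'
#' Model curve `a (1 - exp(-b t))` sampled uniformly on `[0, t_max]` with
#' seeded multiplicative Gaussian noise, emulating a normalized
#' puncta:cytoplasm recovery measurement.
#'
#' @param a Plateau.
#' @param b Rate constant (1/s).
#' @param n_points Number of samples (>= 4).
#' @param t_max Last sample time, seconds.
#' @param noise_sd Standard deviation of the multiplicative noise
#'   (`intensity = model * (1 + eps)`, `eps ~ N(0, noise_sd^2)`).
#' @param seed Integer seed; identical seeds reproduce the trace exactly.
#' @return A [frap_trace()].
#' @export
gen_frap_trace <- function(a, b, n_points = 60L, t_max = 120,
                           noise_sd = 0.05, seed = 1L) {
  if (n_points < 4L) stop("n_points must be >= 4")
  if (t_max <= 0) stop("t_max must be positive")
  times <- seq(0, t_max, length.out = n_points)
  model <- frap_model(times, a, b)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  eps <- rnorm(n_points, 0, noise_sd)
  frap_trace(times, model * (1 + eps))
}

#' Write a fixture set to a directory
#'
#' Materializes the standard synthetic inputs — the paired DC scenario
#' configs, a binary benchmark config, and a bundle of noisy FRAP traces —
#' as YAML/CSV files under `dir`.  Regenerating with the same seed
#' reproduces every file byte-identically.
#'
#' @param dir Output directory (created if needed).
#' @param seed Root seed.
#' @param n_traces Number of synthetic FRAP traces.
#' @return Invisibly, the paths written.
#' @export
write_fixture_set <- function(dir, seed = 1L, n_traces = 10L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pair <- gen_dc_scenario(seed = seed)
  paths <- c(
    nucleated = file.path(dir, "dc_nucleated.yaml"),
    free = file.path(dir, "dc_free.yaml"),
    binary = file.path(dir, "benchmark_binary.yaml"),
    frap = file.path(dir, "frap_traces.csv"))
  write_run_config(pair$nucleated, paths[["nucleated"]])
  write_run_config(pair$free, paths[["free"]])
  write_run_config(gen_benchmark_binary(seed = seed), paths[["binary"]])
  traces <- lapply(seq_len(n_traces), function(i) {
    tr <- gen_frap_trace(a = 0.3 + 0.7 * ((i - 1) %% 5) / 4,
                         b = 0.01 * 10^(((i - 1) %/% 5) / 2),
                         seed = seed + 100L + i)
    cbind(trace_id = i, tr)
  })
  write.csv(do.call(rbind, traces), paths[["frap"]], row.names = FALSE)
  invisible(paths)
}
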