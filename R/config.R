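#' Full simulation run configuration
#'
#' Bundles everything a run needs: grid, physical parameters, interaction
#' matrix (as class values or an explicit matrix), reaction rates,
#' per-component mean fractions, nucleator geometry, solver settings and
#' the root seed.  The defaults are the standard destruction-complex
#' scenario: a 100x100 unit square, kinases and beta-catenin at 5% mean
#' fraction, the default chi classes, the two-step phosphorylation cascade
#' at rates `k1 = k2 = 10`, and a centrosome-like nucleator of radius 0.08.
#'
#' @param grid List `nx, ny, lx, ly`.
#' @param params List `mobility, surface_energy, dt, theta`.
#' @param chi Either a list `binding, neutral, separating` of class values
#'   (expanded through [default_interaction_matrix()]) or an explicit
#'   symmetric matrix matching `components`.
#' @param rates List `k1, k2` for the phosphorylation cascade, or `NULL`
#'   for no reactions.
#' @param means Named mean fractions of the non-cytoplasm components;
#'   unnamed components default to 0 and cytoplasm is the remainder.
#' @param noise_amplitude Relative initialization noise (default 0.05).
#' @param nucleator A [nucleator_spec()] or `NULL` (no nucleator; any
#'   displaced volume returns to the cytoplasm).
#' @param solver List of [solver_config()] fields.
#' @param seed Integer root seed for the noisy initialization.
#' @param components Component names; default [DC_ROLES].
#' @return A validated `run_config` list.
#' @export
run_config <- function(grid = list(nx = 100, ny = 100, lx = 1, ly = 1),
                       params = list(),
                       chi = list(binding = -0.1, neutral = 0, separating = 2),
                       rates = list(k1 = 5, k2 = 5),
                       means = c(GSK3B = 0.05, CK1A = 0.05, BCAT = 0.05,
                                 BCAT_P1 = 0, BCAT_P4 = 0),
                       noise_amplitude = 0.05,
                       nucleator = nucleator_spec(),
                       solver = list(),
                       seed = 1L,
                       components = DC_ROLES) {
  cfg <- list(grid = grid, params = params, chi = chi, rates = rates,
              means = as.list(means), noise_amplitude = noise_amplitude,
              nucleator = nucleator, solver = solver, seed = as.integer(seed),
              components = components)
  validate_run_config(cfg)
}

RUN_CONFIG_KEYS <- list(
  top = c("grid", "params", "chi", "rates", "means", "noise_amplitude",
          "nucleator", "solver", "seed", "components"),
  grid = c("nx", "ny", "lx", "ly"),
  params = c("mobility", "surface_energy", "dt", "theta"),
  chi = c("binding", "neutral", "separating"),
  rates = c("k1", "k2"),
  nucleator = c("center", "radius", "edge_width", "amplitude"),
  solver = c("n_steps", "snapshot_every", "newton_tol", "newton_max_iter",
             "sum_drift_tol", "seed", "evolve_nucleator", "incompressibility"))

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown %s key(s): %s", where, paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  x
}

#' Validate a run configuration
#'
#' Rejects unknown keys and checks cross-field consistency (chi dimensions,
#' mean-fraction names, reaction roles).  Called by every consumer before a
#' run; errors are classed `dcphase_config_error`.
#'
#' @param cfg A `run_config`-shaped list.
#' @return The configuration, classed `run_config`.
#' @export
validate_run_config <- function(cfg) {
  fail <- function(...) {
    stop(structure(class = c("dcphase_config_error", "error", "condition"),
                   list(message = sprintf(...), call = NULL)))
  }
  tryCatch({
    check_keys(cfg, RUN_CONFIG_KEYS$top, "config")
    check_keys(cfg$grid, RUN_CONFIG_KEYS$grid, "grid")
    check_keys(cfg$params, RUN_CONFIG_KEYS$params, "params")
    if (is.list(cfg$chi)) check_keys(cfg$chi, RUN_CONFIG_KEYS$chi, "chi")
    if (!is.null(cfg$rates)) check_keys(cfg$rates, RUN_CONFIG_KEYS$rates, "rates")
    if (!is.null(cfg$nucleator) && !inherits(cfg$nucleator, "nucleator_spec")) {
      check_keys(cfg$nucleator, RUN_CONFIG_KEYS$nucleator, "nucleator")
      cfg$nucleator <- do.call(nucleator_spec, cfg$nucleator)
    }
    check_keys(cfg$solver, RUN_CONFIG_KEYS$solver, "solver")
    comps <- cfg$components
    if (!("CYTOPLASM" %in% comps)) fail("components must include CYTOPLASM")
    if (is.matrix(cfg$chi) || is.data.frame(cfg$chi)) {
      if (nrow(as.matrix(cfg$chi)) != length(comps)) {
        fail("explicit chi matrix must match the component count")
      }
    } else if (!identical(comps, DC_ROLES)) {
      fail("chi class values require the default DC components; supply an explicit matrix")
    }
    bad <- setdiff(names(cfg$means), comps)
    if (length(bad)) fail("means name unknown component(s): %s",
                          paste(bad, collapse = ", "))
    if (!is.null(cfg$rates) && !identical(comps, DC_ROLES)) {
      fail("the phosphorylation cascade requires the default DC components")
    }
    if (!is.null(cfg$nucleator) && !("NUCLEATOR" %in% comps)) {
      fail("a nucleator requires a NUCLEATOR component")
    }
    structure(cfg, class = "run_config")
  }, error = function(e) {
    if (inherits(e, "dcphase_config_error")) stop(e)
    stop(structure(class = c("dcphase_config_error", "error", "condition"),
                   list(message = conditionMessage(e), call = NULL)))
  })
}

config_grid <- function(cfg) do.call(grid_spec, cfg$grid)

config_params <- function(cfg) do.call(physical_params, cfg$params)

config_chi <- function(cfg) {
  if (is.matrix(cfg$chi) || is.data.frame(cfg$chi)) {
    as_chi_matrix(as.matrix(cfg$chi))
  } else {
    do.call(default_interaction_matrix, cfg$chi)
  }
}

config_reactions <- function(cfg) {
  if (is.null(cfg$rates)) list() else do.call(dc_reactions, cfg$rates)
}

config_solver <- function(cfg) do.call(solver_config, cfg$solver)

config_initial_state <- function(cfg, grid = config_grid(cfg)) {
  comps <- cfg$components
  means <- setNames(numeric(length(comps)), comps)
  for (nm in names(cfg$means)) means[[nm]] <- cfg$means[[nm]]
  nf <- NULL
  if (!is.null(cfg$nucleator)) {
    nf <- make_nucleator_field(grid, cfg$nucleator)
  }
  initialize_state(grid, means, noise_amplitude = cfg$noise_amplitude,
                   seed = cfg$seed, nucleator_field = nf)
}

#' Stable hash of a configuration
#'
#' MD5 digest of the canonical serialization; used as provenance in scan
#' tables and run artifacts so any result can be re-run bit-identically.
#'
#' @param cfg Any R object (typically a [run_config()]).
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(cfg, tf, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Execute a run configuration
#'
#' Builds the grid, interaction matrix, reactions and seeded initial state
#' from the configuration and integrates the trajectory with [ch_run()].
#'
#' @param cfg A [run_config()].
#' @return A trajectory (see [ch_run()]) with the configuration and its
#'   hash attached as attributes `config` and `config_hash`.
#' @export
run_sim <- function(cfg) {
  cfg <- validate_run_config(cfg)
  grid <- config_grid(cfg)
  state0 <- config_initial_state(cfg, grid)
  traj <- ch_run(state0, config_chi(cfg), config_params(cfg),
                 config_reactions(cfg), config_solver(cfg))
  attr(traj, "config") <- cfg
  attr(traj, "config_hash") <- config_hash(cfg)
  traj
}

#' Matched nucleated / non-nucleated configurations
#'
#' Returns two fully specified run configurations identical in every
#' respect — same seed, same per-component means, same physics — except
#' that the second has no nucleator (`phi_7 == 0`, the displaced volume
#' returning to the cytoplasm remainder).  Because initialization noise is
#' drawn from per-component substreams, the shared components receive
#' identical noise realizations in both configurations.
#'
#' @param base_config A [run_config()] used as the template.
#' @param spec Nucleator geometry for the nucleated twin; defaults to the
#'   template's own nucleator (or the default spec if it has none).
#' @param seed Root seed applied to both twins; defaults to the template's.
#' @return List with elements `nucleated` and `free`.
#' @export
paired_configs <- function(base_config, spec = NULL, seed = NULL) {
  cfg <- validate_run_config(base_config)
  if (is.null(spec)) {
    spec <- if (!is.null(cfg$nucleator)) cfg$nucleator else nucleator_spec()
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  nucleated <- cfg
  nucleated$nucleator <- spec
  free <- cfg
  free$nucleator <- NULL
  list(nucleated = validate_run_config(nucleated),
       free = validate_run_config(free))
}
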