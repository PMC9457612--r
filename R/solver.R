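#' Solver configuration
#'
#' @param n_steps Number of time steps to take (>= 0 for [ch_run()]).
#' @param snapshot_every Record a full field snapshot every this many steps
#'   (the initial and final states are always recorded).
#' @param newton_tol Convergence tolerance of the iterative implicit solve
#'   (max-norm of the update between successive iterates).
#' @param newton_max_iter Iteration cap; exceeding it is a step failure.
#' @param sum_drift_tol Tolerated pointwise drift of `sum_i phi_i` away
#'   from 1.  Exceeding it is surfaced as a warning and flagged in the
#'   diagnostics, never silently clipped.
#' @param seed Seed recorded for provenance (the stepping itself is
#'   deterministic; randomness enters only at initialization).
#' @param evolve_nucleator If `FALSE` (default) the nucleator field is held
#'   static (mobility factor 0), modelling the centrosome as a fixed region
#'   of increased interaction strength.
#' @param incompressibility `"constrained"` (default) slaves the cytoplasm
#'   to the remainder `1 - sum(others)` and evolves the remaining fields by
#'   their exchange chemical potentials `mu_i - mu_cyto` — the reduced
#'   gradient flow on the incompressibility manifold, which keeps the free
#'   energy a Lyapunov functional and the field sum at 1 to round-off.
#'   `"monitor"` evolves all fields independently by their own potentials
#'   (the literal per-component transport equations) and reports the drift
#'   of their sum as a diagnostic.
#' @return A `solver_config` list.
#' @export
solver_config <- function(n_steps = 100L, snapshot_every = 25L,
                          newton_tol = 1e-6, newton_max_iter = 50L,
                          sum_drift_tol = 0.01, seed = NA_integer_,
                          evolve_nucleator = FALSE,
                          incompressibility = c("constrained", "monitor")) {
  if (newton_tol <= 0) stop("newton_tol must be positive")
  if (n_steps < 0) stop("n_steps must be non-negative")
  if (snapshot_every < 1) stop("snapshot_every must be >= 1")
  if (n_steps > 0 && snapshot_every > n_steps) snapshot_every <- n_steps
  structure(list(n_steps = as.integer(n_steps),
                 snapshot_every = as.integer(snapshot_every),
                 newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 sum_drift_tol = sum_drift_tol,
                 seed = seed,
                 evolve_nucleator = isTRUE(evolve_nucleator),
                 incompressibility = match.arg(incompressibility)),
            class = "solver_config")
}

#' Seeded noisy initial state
#'
#' Each non-cytoplasm field is set to `mean_i * (1 + u_i(x))` with `u_i`
#' uniform on `[-noise_amplitude, +noise_amplitude]`, drawn from a
#' per-component substream of the root seed (so adding a component does not
#' shift the noise of the others).  If a nucleator field is supplied it is
#' used as-is, un-noised.  The cytoplasm is then set pointwise to
#' `1 - sum(others)`, so the fields sum to 1 exactly.
#'
#' @param grid A [grid_spec()].
#' @param mean_fractions Named vector of mean volume fractions, one entry
#'   per component including `"CYTOPLASM"` (whose value is ignored and
#'   replaced by the remainder).  Component order follows the names.
#' @param noise_amplitude Relative noise amplitude (default 0.05, i.e. the
#'   standard +/-5% inhomogeneity used to seed phase separation).
#' @param seed Integer root seed; identical seeds give bit-identical states.
#' @param nucleator_field Optional matrix assigned un-noised to the
#'   `"NUCLEATOR"` component.
#' @return A [field_state()] at time 0.
#' @export
initialize_state <- function(grid, mean_fractions, noise_amplitude = 0.05,
                             seed = 1L, nucleator_field = NULL) {
  comps <- names(mean_fractions)
  if (is.null(comps) || !("CYTOPLASM" %in% comps)) {
    stop("mean_fractions must be named and include a CYTOPLASM component")
  }
  if (any(mean_fractions[comps != "CYTOPLASM"] < 0 |
          mean_fractions[comps != "CYTOPLASM"] > 1)) {
    stop("mean fractions must lie in [0, 1]")
  }
  K <- length(comps)
  phi <- array(0, dim = c(grid$nx, grid$ny, K),
               dimnames = list(NULL, NULL, comps))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  for (i in seq_len(K)) {
    if (comps[i] == "CYTOPLASM") next
    if (comps[i] == "NUCLEATOR" && !is.null(nucleator_field)) {
      phi[, , i] <- nucleator_field
      next
    }
    set.seed(as.integer(seed) + i)   # per-component substream
    u <- matrix(runif(grid$nx * grid$ny, -noise_amplitude, noise_amplitude),
                grid$nx, grid$ny)
    phi[, , i] <- mean_fractions[[i]] * (1 + u)
  }
  ic <- which(comps == "CYTOPLASM")
  others <- matrix(0, grid$nx, grid$ny)
  for (i in seq_len(K)) if (i != ic) others <- others + phi[, , i]
  phi[, , ic] <- 1 - others
  if (any(phi < 0)) {
    stop("initial fractions produce a negative field; reduce means, noise, ",
         "or nucleator amplitude")
  }
  field_state(phi, grid, time = 0, step = 0L, components = comps)
}

# stabilisation shift for the fixed-point iteration: bounds the Jacobian of
# the bulk potential for phi in [0,1]
stabilization_shift <- function(chi) 2 * max(rowSums(abs(chi)))

#' Advance the state by one time step
#'
#' One step of the coupled (phi_i, mu_i) mixed-form system
#' `d phi_i/dt = div(M grad mu_i) + R_i`,
#' `mu_i = dF/dphi_i - lambda lap(phi_i)`,
#' with theta-weighted treatment of the chemical-potential divergence and
#' of the mass-action reaction terms (default theta = 0.5, i.e.
#' Crank-Nicolson / trapezoidal), under no-flux boundaries on both phi and
#' mu.  The
#' nonlinear implicit system is solved by a stabilised fixed-point
#' iteration whose linear part (the fourth-order surface-energy operator
#' plus a convex-splitting shift) is inverted exactly in the grid's cosine
#' eigenbasis; iteration stops when the max-norm update falls below
#' `newton_tol`.
#'
#' @param state Current [field_state()].
#' @param chi Interaction matrix.
#' @param params [physical_params()].
#' @param reactions List of [reaction_spec()] (possibly empty).
#' @param config [solver_config()].
#' @return The advanced [field_state()]; attributes `newton_iters` and
#'   `residual` report the solve.
#' @export
ch_step <- function(state, chi, params, reactions = list(),
                    config = solver_config()) {
  grid <- state$grid
  K <- dim(state$phi)[3]
  evolved <- seq_len(K)
  if (!config$evolve_nucleator) {
    evolved <- setdiff(evolved, which(state$components == "NUCLEATOR"))
  }
  constrained <- config$incompressibility == "constrained"
  ic <- which(state$components == "CYTOPLASM")
  if (constrained && length(ic) == 1L) {
    # cytoplasm is slaved to the remainder, not transported
    evolved <- setdiff(evolved, ic)
  }
  lam <- params$surface_energy
  th <- params$theta
  dt <- params$dt
  dtM <- dt * params$mobility
  L2 <- grid$L2
  L2sq <- L2 * L2
  S <- stabilization_shift(chi)
  denom <- 1 + th * dtM * (lam * L2sq - S * L2)

  phi <- state$phi
  R <- if (length(reactions)) reaction_rates(state, reactions) else NULL

  # In constrained mode the evolved components follow the reduced gradient
  # flow on the manifold sum(phi) = 1: exchange potentials
  # mu_i - mu_cyto with phi_cyto = 1 - sum(others), so the free energy
  # remains a Lyapunov functional.  The surface-energy term then couples
  # the evolved fields linearly ( -lap(phi_cyto) = sum_j lap(phi_j) ),
  # which the mode-wise solve handles by Sherman-Morrison.
  reduced <- constrained && length(ic) == 1L
  eff_g <- function(phi_arr) {
    g <- bulk_potential(phi_arr, chi)
    if (reduced) {
      for (k in evolved) g[, , k] <- g[, , k] - g[, , ic]
    }
    g
  }
  g0 <- eff_g(phi)

  # transform of the static (non-evolved, non-cytoplasm) fields entering
  # the coupled surface-energy term
  static_h <- NULL
  if (reduced) {
    static_idx <- setdiff(seq_len(K), c(evolved, ic))
    if (length(static_idx)) {
      static_h <- matrix(0, grid$nx, grid$ny)
      for (k in static_idx) static_h <- static_h + dct_fwd(phi[, , k], grid)
    }
  }

  m_ev <- length(evolved)
  phih <- vector("list", K)
  for (k in evolved) phih[[k]] <- dct_fwd(phi[, , k], grid)
  sum_h <- NULL
  if (reduced) {
    sum_h <- if (is.null(static_h)) 0 else static_h
    for (k in evolved) sum_h <- sum_h + phih[[k]]
  }
  bh <- vector("list", K)
  for (k in evolved) {
    lap4 <- if (reduced) L2sq * (phih[[k]] + sum_h) else L2sq * phih[[k]]
    rhs <- phih[[k]] +
      dtM * (1 - th) * (L2 * dct_fwd(g0[, , k], grid) - lam * lap4)
    if (!is.null(R)) rhs <- rhs + dt * (1 - th) * dct_fwd(R[, , k], grid)
    if (reduced && !is.null(static_h)) {
      rhs <- rhs - th * dtM * lam * L2sq * static_h   # static part, implicit side
    }
    bh[[k]] <- rhs
  }
  if (reduced) {
    coup <- th * dtM * lam * L2sq
    sm_denom <- denom + m_ev * coup
  }

  cur_phi <- phi
  cur_h <- phih
  cur_g <- g0
  cur_R <- R
  iters <- 0L
  residual <- Inf
  while (iters < config$newton_max_iter) {
    iters <- iters + 1L
    res <- 0
    if (reduced) {
      rhs_list <- vector("list", K)
      rhs_sum <- 0
      for (k in evolved) {
        r_k <- bh[[k]] +
          th * dtM * (L2 * dct_fwd(cur_g[, , k], grid) - S * L2 * cur_h[[k]])
        if (!is.null(cur_R)) r_k <- r_k + th * dt * dct_fwd(cur_R[, , k], grid)
        rhs_list[[k]] <- r_k
        rhs_sum <- rhs_sum + r_k
      }
      x_sum <- rhs_sum / sm_denom
      for (k in evolved) {
        newh <- (rhs_list[[k]] - coup * x_sum) / denom
        new <- dct_inv(newh, grid)
        res <- max(res, max(abs(new - cur_phi[, , k])))
        cur_phi[, , k] <- new
        cur_h[[k]] <- newh
      }
    } else {
      for (k in evolved) {
        rhs <- bh[[k]] +
          th * dtM * (L2 * dct_fwd(cur_g[, , k], grid) - S * L2 * cur_h[[k]])
        if (!is.null(cur_R)) rhs <- rhs + th * dt * dct_fwd(cur_R[, , k], grid)
        newh <- rhs / denom
        new <- dct_inv(newh, grid)
        res <- max(res, max(abs(new - cur_phi[, , k])))
        cur_phi[, , k] <- new
        cur_h[[k]] <- newh
      }
    }
    if (reduced) {
      others <- matrix(0, grid$nx, grid$ny)
      for (k in seq_len(K)) if (k != ic) others <- others + cur_phi[, , k]
      cur_phi[, , ic] <- 1 - others
    }
    residual <- res
    if (res < config$newton_tol) break
    cur_g <- eff_g(cur_phi)
    if (!is.null(cur_R)) cur_R <- reaction_rates_phi(cur_phi, reactions)
  }
  if (residual >= config$newton_tol) {
    stop(structure(class = c("dcphase_step_failure", "error", "condition"),
                   list(message = sprintf(
                     "implicit solve did not converge in %d iterations (residual %.3e)",
                     config$newton_max_iter, residual),
                     call = sys.call(), residual = residual)))
  }
  if (!all(is.finite(cur_phi))) {
    stop(structure(class = c("dcphase_step_failure", "error", "condition"),
                   list(message = "non-finite volume fraction encountered",
                        call = sys.call(), residual = residual)))
  }
  if (min(cur_phi) < -0.05) {
    stop(structure(class = c("dcphase_step_failure", "error", "condition"),
                   list(message = sprintf(
                     "volume fraction undershoot below -0.05 (min %.4f)",
                     min(cur_phi)),
                     call = sys.call(), residual = residual)))
  }
  if (constrained && length(ic) == 1L) {
    others <- matrix(0, grid$nx, grid$ny)
    for (k in seq_len(K)) if (k != ic) others <- others + cur_phi[, , k]
    cur_phi[, , ic] <- 1 - others
  }
  out <- field_state(cur_phi, grid, time = state$time + dt,
                     step = state$step + 1L, components = state$components)
  attr(out, "newton_iters") <- iters
  attr(out, "residual") <- residual
  out
}

#' Run a trajectory
#'
#' Applies [ch_step()] `n_steps` times, recording one diagnostics row per
#' step (component integrals, total free energy, incompressibility drift,
#' solver iterations) and field snapshots every `snapshot_every` steps.
#' Deterministic given the initial state and configuration.
#'
#' @inheritParams ch_step
#' @param initial Initial [field_state()].
#' @return A `trajectory` with elements `snapshots` (list of field states)
#'   and `diagnostics` (data frame).
#' @export
ch_run <- function(initial, chi, params, reactions = list(),
                   config = solver_config()) {
  state <- initial
  n <- config$n_steps
  comps <- state$components
  diag_rows <- vector("list", n + 1L)
  snaps <- list()
  record <- function(state, iters, residual) {
    tot <- component_totals(state)
    drift <- sum_drift(state)
    row <- data.frame(step = state$step, time = state$time,
                      free_energy = total_free_energy(state, chi, params),
                      sum_drift = drift,
                      drift_exceeded = drift > config$sum_drift_tol,
                      newton_iters = iters, residual = residual)
    for (cn in comps) row[[paste0("total_", cn)]] <- tot[[cn]]
    row
  }
  diag_rows[[1]] <- record(state, NA_integer_, NA_real_)
  snaps[["0"]] <- state
  for (s in seq_len(n)) {
    state <- tryCatch(
      ch_step(state, chi, params, reactions, config),
      dcphase_step_failure = function(e) {
        stop(sprintf("step %d failed: %s", s, conditionMessage(e)),
             call. = FALSE)
      })
    diag_rows[[s + 1L]] <- record(state, attr(state, "newton_iters"),
                                  attr(state, "residual"))
    if (s %% config$snapshot_every == 0L || s == n) {
      snaps[[as.character(s)]] <- state
    }
  }
  diagnostics <- do.call(rbind, diag_rows)
  max_drift <- max(diagnostics$sum_drift)
  if (max_drift > config$sum_drift_tol) {
    warning(sprintf(
      "incompressibility drift max |sum(phi) - 1| = %.4g exceeded tolerance %g",
      max_drift, config$sum_drift_tol))
  }
  structure(list(snapshots = snaps, diagnostics = diagnostics,
                 components = comps, config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<trajectory> %d steps, %d snapshots, %d components\n",
              max(d$step), length(x$snapshots), length(x$components)))
  cat(sprintf("  free energy %.6g -> %.6g; max drift %.3g; max iters %s\n",
              d$free_energy[1], d$free_energy[nrow(d)], max(d$sum_drift),
              if (nrow(d) > 1) max(d$newton_iters, na.rm = TRUE) else "NA"))
  invisible(x)
}

#' Extract a recorded snapshot by step
#'
#' @param traj A trajectory from [ch_run()].
#' @param step Step number; default the final recorded step.
#' @return A [field_state()].
#' @export
snapshot_at <- function(traj, step = NULL) {
  steps <- as.integer(names(traj$snapshots))
  if (is.null(step)) step <- max(steps)
  i <- match(as.integer(step), steps)
  if (is.na(i)) stop("no snapshot recorded at step ", step)
  traj$snapshots[[i]]
}
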