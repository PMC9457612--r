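dc_means <- c(GSK3B = 0.05, CK1A = 0.05, BCAT = 0.05, BCAT_P1 = 0,
              BCAT_P4 = 0, CYTOPLASM = NA, NUCLEATOR = 0)

test_that("initialization is exact, seeded and mass-closing", {
  g <- grid_spec(20, 20)
  # zero noise: exactly uniform at the means, cytoplasm the exact remainder
  st <- initialize_state(g, dc_means, noise_amplitude = 0, seed = 1)
  expect_true(all(st$phi[, , "GSK3B"] == 0.05))
  expect_true(all(st$phi[, , "CYTOPLASM"] == 1 - 0.15))
  # with noise the pointwise sum is still exactly one
  st <- initialize_state(g, dc_means, noise_amplitude = 0.05, seed = 1)
  expect_lte(max(abs(apply(st$phi, c(1, 2), sum) - 1)), 1e-9)
  expect_true(all(st$phi[, , "GSK3B"] >= 0.05 * 0.95 &
                    st$phi[, , "GSK3B"] <= 0.05 * 1.05))
  # same seed twice -> bit-identical fields
  st2 <- initialize_state(g, dc_means, noise_amplitude = 0.05, seed = 1)
  expect_identical(st$phi, st2$phi)
  st3 <- initialize_state(g, dc_means, noise_amplitude = 0.05, seed = 2)
  expect_false(identical(st$phi, st3$phi))
})

test_that("spatial mean of a noisy field stays within 0.5% of its target", {
  g <- grid_spec(100, 100)
  st <- initialize_state(g, dc_means, noise_amplitude = 0.05, seed = 42)
  for (cn in c("GSK3B", "CK1A", "BCAT")) {
    expect_lt(abs(mean(st$phi[, , cn]) / 0.05 - 1), 0.005)
  }
})

test_that("per-component noise substreams do not shift when another mean changes", {
  g <- grid_spec(12, 12)
  a <- initialize_state(g, dc_means, seed = 5)
  m2 <- dc_means
  m2[["BCAT_P1"]] <- 0.02
  b <- initialize_state(g, m2, seed = 5)
  expect_identical(a$phi[, , "GSK3B"], b$phi[, , "GSK3B"])
  expect_identical(a$phi[, , "BCAT"], b$phi[, , "BCAT"])
})

test_that("initialization rejects negative fields", {
  g <- grid_spec(10, 10)
  bad <- c(A = 0.9, CYTOPLASM = NA)
  expect_error(initialize_state(g, bad, noise_amplitude = 0.5, seed = 1),
               "negative")
  expect_error(initialize_state(g, c(A = 1.2, CYTOPLASM = NA),
                                noise_amplitude = 0, seed = 1), "\\[0, 1\\]")
})

test_that("a uniform interaction-free state is a fixed point of the step", {
  g <- grid_spec(16, 16)
  st <- initialize_state(g, dc_means, noise_amplitude = 0, seed = 1)
  chi0 <- as_chi_matrix(matrix(0, 7, 7))
  out <- ch_step(st, chi0, physical_params(), list(), solver_config())
  expect_lt(max(abs(out$phi - st$phi)), 1e-12)
})

test_that("transport conserves every component integral without reactions", {
  chi <- default_interaction_matrix()
  pp <- physical_params()
  g <- grid_spec(24, 24)
  nf <- make_nucleator_field(g, nucleator_spec())
  for (mode in c("constrained", "monitor")) {
    cfg <- solver_config(n_steps = 10, incompressibility = mode)
    st <- initialize_state(g, dc_means, seed = 3, nucleator_field = nf)
    traj <- suppressWarnings(ch_run(st, chi, pp, list(), cfg))
    d <- traj$diagnostics
    for (cn in paste0("total_", DC_ROLES)) {
      expect_lt(max_rel_step_drift(d[[cn]]), 1e-8, label = paste(mode, cn))
    }
  }
})

test_that("separating vs binding chi reproduce spinodal vs stable regimes", {
  grow <- run_sim(gen_benchmark_binary(grid = list(nx = 32, ny = 32),
                                       chi12 = 2, seed = 9, n_steps = 30))
  decay <- run_sim(gen_benchmark_binary(grid = list(nx = 32, ny = 32),
                                        chi12 = -0.1, seed = 9, n_steps = 30))
  v <- function(tr, s) var(as.vector(snapshot_at(tr, s)$phi[, , 1]))
  expect_gt(v(grow, 30) / v(grow, 0), 2)
  expect_lt(v(decay, 30) / v(decay, 0), 1)
})

test_that("a zero-step run returns only the initial snapshot", {
  g <- grid_spec(10, 10)
  st <- initialize_state(g, dc_means, seed = 1)
  traj <- ch_run(st, default_interaction_matrix(), physical_params(),
                 list(), solver_config(n_steps = 0))
  expect_length(traj$snapshots, 1L)
  expect_identical(traj$diagnostics$step, 0L)
  expect_identical(snapshot_at(traj, 0)$phi, st$phi)
})

test_that("free energy decreases along reaction-free trajectories", {
  pair <- gen_dc_scenario(overrides = c(tiny_dc_overrides(nx = 32, n_steps = 25),
                                        list(rates = NULL)), seed = 2)
  traj <- run_sim(pair$nucleated)
  expect_true(all(diff(traj$diagnostics$free_energy) <= 1e-9))
})

test_that("trajectories are deterministic given config and seed", {
  pair <- gen_dc_scenario(tiny_dc_overrides(), seed = 4)
  a <- run_sim(pair$nucleated)
  b <- run_sim(pair$nucleated)
  expect_identical(a$diagnostics, b$diagnostics)
  expect_identical(snapshot_at(a)$phi, snapshot_at(b)$phi)
})

test_that("non-convergence raises a classed step failure with the residual", {
  cfg <- gen_benchmark_binary(grid = list(nx = 24, ny = 24), chi12 = 2,
                              seed = 1)
  st <- dcphase:::config_initial_state(cfg)
  err <- tryCatch(
    ch_step(st, dcphase:::config_chi(cfg), physical_params(),
            list(), solver_config(newton_tol = 1e-14, newton_max_iter = 2L)),
    dcphase_step_failure = function(e) e)
  expect_s3_class(err, "dcphase_step_failure")
  expect_true(is.finite(err$residual))
  # and ch_run tags the failing step index
  expect_error(
    ch_run(st, dcphase:::config_chi(cfg), physical_params(), list(),
           solver_config(n_steps = 3, newton_tol = 1e-14,
                         newton_max_iter = 2L)),
    "step 1 failed")
})

test_that("monitor mode reports incompressibility drift instead of hiding it", {
  ov <- c(tiny_dc_overrides(nx = 32, n_steps = 15))
  ov$solver$incompressibility <- "monitor"
  ov$solver$sum_drift_tol <- 1e-4
  pair <- gen_dc_scenario(ov, seed = 1)
  expect_warning(traj <- run_sim(pair$nucleated), "drift")
  expect_true(any(traj$diagnostics$drift_exceeded))
  # constrained mode keeps the sum at one to round-off
  pair2 <- gen_dc_scenario(tiny_dc_overrides(nx = 32, n_steps = 15), seed = 1)
  traj2 <- run_sim(pair2$nucleated)
  expect_lt(max(traj2$diagnostics$sum_drift), 1e-12)
})

test_that("uniform interaction-free runs match the mean-field cascade ODE", {
  ov <- list(chi = matrix(0, 7, 7, dimnames = list(DC_ROLES, DC_ROLES)),
             noise_amplitude = 0, nucleator = NULL,
             grid = list(nx = 16, ny = 16))
  pair <- gen_dc_scenario(overrides = ov, seed = 1)
  d <- run_sim(pair$free)$diagnostics
  ref <- cascade_ode_oracle(k1 = 5, k2 = 5, phi_ck1 = 0.05, phi_gsk3 = 0.05,
                            bcat0 = 0.05, t_end = 0.05)
  got <- unlist(d[nrow(d), c("total_BCAT", "total_BCAT_P1", "total_BCAT_P4")])
  expect_lt(max(abs(got - ref) / ref), 1e-3)
})
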