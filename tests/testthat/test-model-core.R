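test_that("component table is a bijection between indices 1..7 and roles", {
  comp <- dc_components()
  expect_identical(comp$index, 1:7)
  expect_identical(comp$role, DC_ROLES)
  expect_identical(component_index("BCAT_P4"), 5L)
  expect_identical(component_index(c("GSK3B", "CYTOPLASM")), c(1L, 6L))
  expect_error(component_index("AXIN"), "unknown component")
  expect_error(component_index(9), "out of range")
})

test_that("default interaction matrix realises the scaffold-binding map", {
  chi <- default_interaction_matrix()
  expect_identical(chi["BCAT", "CYTOPLASM"], 2)      # separating
  expect_identical(chi["BCAT_P4", "NUCLEATOR"], 0)   # P4 released, neutral
  expect_identical(chi["GSK3B", "GSK3B"], 0)         # no self-interaction
  # scaffold-binding species are pairwise binding with one another
  binders <- c("GSK3B", "CK1A", "BCAT", "BCAT_P1", "NUCLEATOR")
  off <- chi[binders, binders][upper.tri(diag(5))]
  expect_true(all(off == -0.1))
  # each binder separates from cytoplasm; P4 is neutral to everything
  expect_true(all(chi[binders, "CYTOPLASM"] == 2))
  expect_true(all(chi["BCAT_P4", ] == 0))
  # structural invariants
  expect_identical(unclass(chi), t(unclass(chi)))
  expect_true(all(diag(chi) == 0))
})

test_that("interaction-class ordering is enforced", {
  expect_error(default_interaction_matrix(binding = 3, separating = 2),
               "ordering violated")
  expect_error(interaction_classes(binding = 0.5, neutral = 0, separating = 2),
               "ordered")
  cl <- interaction_classes()
  expect_true(cl[["BINDING"]] < cl[["NEUTRAL"]] &&
                cl[["NEUTRAL"]] < cl[["SEPARATING"]])
})

test_that("chi matrices must be symmetric with zero diagonal", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(as_chi_matrix(m), "symmetric")
  m2 <- diag(2) * 0.5
  expect_error(as_chi_matrix(m2), "zero diagonal")
})

two_comp_state <- function(phi1, phi2, nx = 8) {
  g <- grid_spec(nx, nx)
  phi <- array(0, c(nx, nx, 2), dimnames = list(NULL, NULL, c("A", "CYTOPLASM")))
  phi[, , 1] <- phi1
  phi[, , 2] <- phi2
  field_state(phi, g)
}

test_that("free-energy density matches the quartic pair formula", {
  chi0 <- matrix(0, 2, 2)
  st <- two_comp_state(0.2, 0.5)
  expect_true(all(free_energy_density(st, chi0) == 0))
  chi <- matrix(c(0, 2, 2, 0), 2, 2)
  f <- free_energy_density(st, chi)
  expect_equal(max(abs(f - 2 * 0.04 * 0.25)), 0, tolerance = 1e-14)
  expect_equal(f[1, 1], 0.02)
})

test_that("free-energy density is invariant under joint relabelling", {
  set.seed(7)
  nx <- 6
  phi <- array(runif(nx * nx * 3, 0, 0.4), c(nx, nx, 3))
  g <- grid_spec(nx, nx)
  chi <- matrix(c(0, -0.1, 2, -0.1, 0, 0.5, 2, 0.5, 0), 3, 3)
  st <- field_state(phi, g, components = c("A", "B", "CYTOPLASM"))
  perm <- c(3, 1, 2)
  stp <- field_state(phi[, , perm], g, components = c("CYTOPLASM", "A", "B"))
  expect_equal(free_energy_density(st, chi),
               free_energy_density(stp, chi[perm, perm]), tolerance = 1e-14)
})

test_that("chemical potential is the variational derivative of F", {
  pp <- physical_params()
  # uniform fields, all chi zero -> mu identically zero
  st <- two_comp_state(0.3, 0.7)
  mu <- chemical_potential(st, matrix(0, 2, 2), pp)
  expect_equal(max(abs(mu)), 0, tolerance = 1e-12)
  # uniform pair: mu_i = 2 chi phi_i phi_j^2
  st <- two_comp_state(0.2, 0.5)
  chi <- matrix(c(0, 2, 2, 0), 2, 2)
  mu <- chemical_potential(st, chi, pp)
  expect_equal(max(abs(mu[, , 1] - 0.2)), 0, tolerance = 1e-12)
  expect_equal(max(abs(mu[, , 2] - 2 * 2 * 0.5 * 0.04)), 0, tolerance = 1e-12)
})

test_that("surface-energy part of mu matches an independent stencil oracle", {
  nx <- 16
  g <- grid_spec(nx, nx)
  set.seed(11)
  u <- matrix(runif(nx * nx, 0.2, 0.8), nx, nx)
  phi <- array(0, c(nx, nx, 2))
  phi[, , 1] <- u
  phi[, , 2] <- 1 - u
  st <- field_state(phi, g, components = c("A", "CYTOPLASM"))
  lam <- 1e-3
  pp <- physical_params(surface_energy = lam)
  mu <- chemical_potential(st, matrix(0, 2, 2), pp)
  expect_lt(max(abs(mu[, , 1] + lam * lap_stencil_oracle(u, g$h))), 1e-10)
})

test_that("total free energy integrates bulk and gradient terms", {
  # uniform fields: gradient term exactly zero, total = f * area
  st <- two_comp_state(0.2, 0.5, nx = 10)
  chi <- matrix(c(0, 2, 2, 0), 2, 2)
  pp <- physical_params()
  expect_equal(total_free_energy(st, chi, pp), 0.02, tolerance = 1e-12)
  # single sinusoidal perturbation, chi = 0: (lambda/2) int |grad phi|^2,
  # analytically eps^2 pi^2 / 4 for phi = 0.5 + eps cos(pi x)
  nx <- 64
  g <- grid_spec(nx, nx)
  eps <- 0.05
  u <- matrix(0.5 + eps * cos(pi * g$x), nx, nx)
  phi <- array(0, c(nx, nx, 2))
  phi[, , 1] <- u
  phi[, , 2] <- 1 - u   # mirrored field doubles the gradient energy
  st <- field_state(phi, g, components = c("A", "CYTOPLASM"))
  got <- total_free_energy(st, matrix(0, 2, 2), pp)
  expect_equal(got, 2 * pp$surface_energy / 2 * eps^2 * pi^2 / 2,
               tolerance = 1e-2)
})

test_that("reaction rates implement catalytic conversion with conservation", {
  g <- grid_spec(8, 8)
  phi <- array(0, c(8, 8, 7), dimnames = list(NULL, NULL, DC_ROLES))
  phi[, , "GSK3B"] <- 0.1
  phi[, , "BCAT_P1"] <- 0.2
  phi[, , "CYTOPLASM"] <- 0.7
  st <- field_state(phi, g)
  rx <- dc_reactions(k1 = 1, k2 = 1)
  R <- reaction_rates(st, rx)
  # no CK1a anywhere: the priming step is silent
  expect_true(all(R[, , "BCAT"] == 0))
  # completion step: P4 gains k * phi1 * phi4, P1 loses the same
  expect_equal(max(abs(R[, , "BCAT_P4"] - 0.02)), 0, tolerance = 1e-14)
  expect_equal(max(abs(R[, , "BCAT_P1"] + 0.02)), 0, tolerance = 1e-14)
  # stoichiometric conservation and untouched species
  set.seed(3)
  phi[] <- runif(length(phi), 0, 0.2)
  st <- field_state(phi, g)
  R <- reaction_rates(st, dc_reactions())
  chain <- R[, , "BCAT"] + R[, , "BCAT_P1"] + R[, , "BCAT_P4"]
  expect_lt(max(abs(chain)), 1e-15)
  for (cn in c("GSK3B", "CK1A", "CYTOPLASM", "NUCLEATOR")) {
    expect_true(all(R[, , cn] == 0))
  }
})

test_that("reaction specifications are validated", {
  expect_error(reaction_spec("BCAT", "CK1A", "BCAT_P1", -1), "non-negative")
  expect_error(reaction_spec("BCAT", "CK1A", "BCAT", 1), "must differ")
  expect_error(reaction_spec("BCAT", "BCAT", "BCAT_P1", 1), "catalyst")
})
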