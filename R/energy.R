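#' Physical parameters of the transport model
#'
#' @param mobility Mobility constant M (> 0), shared by all components —
#'   every DC species diffuses at the same rate.
#' @param surface_energy Surface-energy parameter lambda (> 0) setting the
#'   width of the transition regions between domains.
#' @param dt Time-step of the simulation (dimensionless time).
#' @param theta Implicitness weight in `[0, 1]` for the chemical-potential
#'   divergence term (0 = explicit, 1 = backward Euler, 0.5 =
#'   Crank-Nicolson, the default).
#' @return A `physical_params` list.
#' @export
physical_params <- function(mobility = 1, surface_energy = 1e-3,
                            dt = 5e-4, theta = 0.5) {
  if (mobility <= 0) stop("mobility must be positive")
  if (surface_energy <= 0) stop("surface_energy must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  structure(list(mobility = mobility, surface_energy = surface_energy,
                 dt = dt, theta = theta),
            class = "physical_params")
}

#' Bulk free-energy density
#'
#' Pointwise quartic (double-well style) mixing energy
#' `f(x) = sum_{i<j} chi_ij phi_i(x)^2 phi_j(x)^2`, each unordered pair
#' counted once.
#'
#' @param state A [field_state()].
#' @param chi Interaction matrix matching the state's component count.
#' @return Matrix `nx x ny` of energy densities.
#' @export
free_energy_density <- function(state, chi) {
  K <- dim(state$phi)[3]
  if (nrow(chi) != K) stop("chi does not match the state's component count")
  phi2 <- state$phi^2
  f <- matrix(0, state$grid$nx, state$grid$ny)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      if (chi[i, j] != 0) f <- f + chi[i, j] * (phi2[, , i] * phi2[, , j])
    }
  }
  f
}

#' Total free energy (diagnostic Lyapunov functional)
#'
#' Grid quadrature of the bulk energy plus the interfacial gradient energy
#' `(lambda/2) sum_i |grad phi_i|^2`.  The gradient term is accumulated
#' over cell edges, which is the exact discrete energy whose gradient flow
#' the solver's 5-point Laplacian realises; with reactions switched off the
#' value is non-increasing along a trajectory.
#'
#' @inheritParams free_energy_density
#' @param params A [physical_params()] (supplies lambda).
#' @return Scalar total energy.
#' @export
total_free_energy <- function(state, chi, params) {
  h <- state$grid$h
  bulk <- sum(free_energy_density(state, chi)) * h^2
  lam <- params$surface_energy
  grad <- 0
  for (k in seq_len(dim(state$phi)[3])) {
    u <- state$phi[, , k]
    dx <- u[-1, , drop = FALSE] - u[-nrow(u), , drop = FALSE]
    dy <- u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE]
    grad <- grad + sum(dx^2) + sum(dy^2)   # (d/h)^2 * h^2 = d^2
  }
  bulk + 0.5 * lam * grad
}

# pointwise derivative of the bulk energy wrt phi_i for all components:
# g_i = sum_{j != i} 2 chi_ij phi_i phi_j^2  (returns nx x ny x K array)
bulk_potential <- function(phi, chi) {
  K <- dim(phi)[3]
  phi2 <- phi^2
  g <- array(0, dim = dim(phi))
  for (i in seq_len(K)) {
    acc <- NULL
    for (j in seq_len(K)) {
      if (j == i || chi[i, j] == 0) next
      term <- chi[i, j] * phi2[, , j]
      acc <- if (is.null(acc)) term else acc + term
    }
    if (!is.null(acc)) g[, , i] <- 2 * phi[, , i] * acc
  }
  g
}

#' Chemical potential fields
#'
#' `mu_i(x) = sum_{j != i} 2 chi_ij phi_i(x) phi_j(x)^2 - lambda lap(phi_i)`,
#' the variational derivative of the total free energy, with the Laplacian
#' taken under no-flux boundary conditions.
#'
#' @inheritParams total_free_energy
#' @return Array `nx x ny x K` of chemical potentials.
#' @export
chemical_potential <- function(state, chi, params) {
  mu <- bulk_potential(state$phi, chi)
  lam <- params$surface_energy
  for (k in seq_len(dim(mu)[3])) {
    mu[, , k] <- mu[, , k] - lam * laplacian_field(state$phi[, , k], state$grid)
  }
  dimnames(mu) <- dimnames(state$phi)
  mu
}
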