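#' Simulation grid
#'
#' Cell-centred uniform grid on a rectangular domain with closed (no-flux /
#' Neumann) boundaries, mimicking the closed cytoplasmic volume of a cell.
#' Cells must be square (`lx/nx == ly/ny`).  The object caches the
#' orthonormal cosine eigenbasis of the 5-point Neumann Laplacian in each
#' direction, which the solver uses for exact linear solves.
#'
#' @param nx,ny Number of cells in x and y.
#' @param lx,ly Domain lengths (dimensionless; default unit square).
#' @return A `grid_spec` list with fields `nx, ny, lx, ly, h, x, y`
#'   (cell-centre coordinates), the eigenbases `Vx, Vy`, and the 2-D
#'   Laplacian eigenvalue table `L2` (all eigenvalues are <= 0).
#' @export
grid_spec <- function(nx, ny = nx, lx = 1, ly = lx * ny / nx) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("grid must have at least 2 cells per side")
  hx <- lx / nx; hy <- ly / ny
  if (abs(hx - hy) > 1e-12 * max(hx, hy)) {
    stop("grid cells must be square: lx/nx must equal ly/ny")
  }
  bx <- neumann_cosine_basis(nx, hx)
  by <- neumann_cosine_basis(ny, hy)
  g <- list(
    nx = nx, ny = ny, lx = lx, ly = ly, h = hx,
    x = (seq_len(nx) - 0.5) * hx,
    y = (seq_len(ny) - 0.5) * hy,
    Vx = bx$V, Vy = by$V,
    L2 = outer(bx$ev, by$ev, `+`)
  )
  class(g) <- "grid_spec"
  g
}

# Orthonormal eigenbasis of the 1-D cell-centred Neumann (ghost-reflection)
# finite-difference Laplacian: V[j,k] ~ cos(pi*(k-1)*(j-1/2)/n),
# eigenvalues -(4/h^2) sin^2(pi*(k-1)/(2n)).
neumann_cosine_basis <- function(n, h) {
  j <- seq_len(n) - 0.5
  k <- seq_len(n) - 1
  V <- cos(pi * outer(j, k) / n)
  V <- sweep(V, 2, c(sqrt(n), rep(sqrt(n / 2), n - 1)), `/`)
  list(V = V, ev = -(4 / h^2) * sin(pi * k / (2 * n))^2)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells on %g x %g domain (h = %g)\n",
              x$nx, x$ny, x$lx, x$ly, x$h))
  invisible(x)
}

# forward / inverse cosine transform of a single field (matrix)
dct_fwd <- function(u, grid) crossprod(grid$Vx, u) %*% grid$Vy
dct_inv <- function(uh, grid) grid$Vx %*% tcrossprod(uh, grid$Vy)

#' Discrete Laplacian of a field under no-flux boundaries
#'
#' Applies the standard 5-point finite-difference Laplacian with
#' ghost-cell reflection at the closed boundaries, evaluated exactly
#' through the grid's cosine eigenbasis.
#'
#' @param u Matrix of values on the grid (`nx` x `ny`).
#' @param grid A [grid_spec()].
#' @return Matrix of the same shape.
#' @export
laplacian_field <- function(u, grid) {
  dct_inv(grid$L2 * dct_fwd(u, grid), grid)
}

#' Per-component field state
#'
#' Holds the volume-fraction fields of all components at one instant.
#'
#' @param phi Numeric array `nx x ny x n_components`; third dimension may
#'   carry role names as dimnames.
#' @param grid A [grid_spec()].
#' @param time Simulation time (dt * step).
#' @param step Integer step counter.
#' @param components Character vector of component names; defaults to the
#'   dimnames of `phi` or [DC_ROLES] when the count matches.
#' @return A `field_state` object.
#' @export
field_state <- function(phi, grid, time = 0, step = 0L, components = NULL) {
  if (length(dim(phi)) != 3L) stop("phi must be an nx x ny x K array")
  if (dim(phi)[1] != grid$nx || dim(phi)[2] != grid$ny) {
    stop("phi does not match the grid dimensions")
  }
  if (is.null(components)) {
    components <- dimnames(phi)[[3]]
    if (is.null(components)) {
      components <- if (dim(phi)[3] == length(DC_ROLES)) DC_ROLES else
        paste0("C", seq_len(dim(phi)[3]))
    }
  }
  if (length(components) != dim(phi)[3]) {
    stop("components must name every field in phi")
  }
  if (!all(is.finite(phi))) stop("phi must be finite everywhere")
  dimnames(phi) <- list(NULL, NULL, components)
  structure(list(phi = phi, grid = grid, time = time, step = as.integer(step),
                 components = components),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  tot <- apply(x$phi, 3, sum) * x$grid$h^2
  cat(sprintf("<field_state> step %d (t = %g), %d x %d grid, %d components\n",
              x$step, x$time, x$grid$nx, x$grid$ny, length(x$components)))
  cat("  integrals:", paste(sprintf("%s=%.4g", x$components, tot),
                            collapse = " "), "\n")
  cat(sprintf("  max |sum(phi) - 1| = %.3g\n",
              max(abs(apply(x$phi, c(1, 2), sum) - 1))))
  invisible(x)
}

# domain integral of every component: vector named by component
component_totals <- function(state) {
  apply(state$phi, 3, sum) * state$grid$h^2
}

# pointwise incompressibility drift max |sum_i phi_i - 1|
sum_drift <- function(state) {
  s <- state$phi[, , 1]
  for (k in seq_len(dim(state$phi)[3])[-1]) s <- s + state$phi[, , k]
  max(abs(s - 1))
}
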