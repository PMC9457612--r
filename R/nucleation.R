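#' Centrosome-like nucleator geometry
#'
#' The centrosome is modelled as a static disk of nucleator material whose
#' binding interactions with the DC clients create a region of increased
#' interaction strength where condensation can nucleate.
#'
#' @param center Disk centre as fractions of the domain lengths.
#' @param radius Disk radius as a fraction of the domain length `lx`
#'   (0 < radius < 0.5).
#' @param edge_width Interface smoothing length (same units as the domain).
#' @param amplitude Peak nucleator volume fraction in (0, 1].
#' @return A `nucleator_spec` list.
#' @export
nucleator_spec <- function(center = c(0.5, 0.5), radius = 0.08,
                           edge_width = 0.01, amplitude = 0.12) {
  if (radius <= 0 || radius >= 0.5) stop("radius must lie in (0, 0.5)")
  if (edge_width <= 0) stop("edge_width must be positive")
  if (amplitude <= 0 || amplitude > 1) stop("amplitude must lie in (0, 1]")
  structure(list(center = center, radius = radius,
                 edge_width = edge_width, amplitude = amplitude),
            class = "nucleator_spec")
}

#' Smooth nucleator disk field
#'
#' Returns `phi_7(x) = amplitude * 0.5 * (1 - tanh((r - R)/edge_width))`, a
#' radially symmetric disk with a hyperbolic-tangent edge, values in
#' `[0, amplitude]`.
#'
#' @param grid A [grid_spec()].
#' @param spec A [nucleator_spec()].
#' @return Matrix `nx x ny`.
#' @export
make_nucleator_field <- function(grid, spec) {
  R <- spec$radius * grid$lx
  cx <- spec$center[1] * grid$lx
  cy <- spec$center[2] * grid$ly
  reach <- R + 3 * spec$edge_width
  if (cx - reach < 0 || cx + reach > grid$lx ||
      cy - reach < 0 || cy + reach > grid$ly) {
    stop("nucleator disk (radius + 3 * edge_width) exceeds the domain")
  }
  r <- sqrt(outer((grid$x - cx)^2, (grid$y - cy)^2, `+`))
  spec$amplitude * 0.5 * (1 - tanh((r - R) / spec$edge_width))
}

#' Boolean mask of the nucleator support
#'
#' Cells within the disk radius (where the smooth profile exceeds half its
#' amplitude).
#'
#' @inheritParams make_nucleator_field
#' @return Logical matrix `nx x ny`.
#' @export
nucleator_mask <- function(grid, spec) {
  make_nucleator_field(grid, spec) > spec$amplitude / 2
}
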