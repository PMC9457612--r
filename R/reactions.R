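#' Catalytic conversion reaction
#'
#' One second-order mass-action conversion: the substrate is consumed and
#' the product created at rate `k * phi_catalyst * phi_substrate`; the
#' catalyst itself is unchanged.  This is the spatially resolved analogue
#' of a well-mixed kinase reaction.
#'
#' @param substrate,catalyst,product Component roles or indices.
#' @param rate Rate constant k >= 0 (per unit simulation time).
#' @return A `reaction_spec` list of integer indices plus the rate.
#' @export
reaction_spec <- function(substrate, catalyst, product, rate) {
  if (rate < 0) stop("reaction rate must be non-negative")
  s <- component_index(substrate)
  c_ <- component_index(catalyst)
  p <- component_index(product)
  if (s == p) stop("substrate and product must differ")
  if (c_ == s || c_ == p) stop("catalyst must differ from substrate and product")
  structure(list(substrate = s, catalyst = c_, product = p, rate = rate),
            class = "reaction_spec")
}

#' The two-step beta-catenin phosphorylation cascade
#'
#' CK1alpha phosphorylates beta-catenin at S45 (rate `k1`), priming it for
#' GSK3beta, which completes phosphorylation to the quadruply
#' phosphorylated form (rate `k2`):
#' `BCAT --(CK1A, k1)--> BCAT_P1 --(GSK3B, k2)--> BCAT_P4`.
#'
#' @param k1 Rate of the CK1alpha priming step (k_2,3 in the field notation).
#' @param k2 Rate of the GSK3beta completion step (k_1,4).
#' @return List of two [reaction_spec()] objects.
#' @export
dc_reactions <- function(k1 = 5, k2 = 5) {
  list(reaction_spec("BCAT", "CK1A", "BCAT_P1", k1),
       reaction_spec("BCAT_P1", "GSK3B", "BCAT_P4", k2))
}

#' Pointwise reaction-rate fields
#'
#' For every reaction the substrate loses `k * phi_catalyst * phi_substrate`
#' pointwise and the product gains the same amount, so the fields sum to
#' zero over each conversion chain (stoichiometric conservation).
#'
#' @param state A [field_state()].
#' @param reactions List of [reaction_spec()] objects (may be empty).
#' @return Array `nx x ny x K` of net rates `R_i(x)`.
#' @export
reaction_rates <- function(state, reactions) {
  reaction_rates_phi(state$phi, reactions)
}

reaction_rates_phi <- function(phi, reactions) {
  R <- array(0, dim = dim(phi), dimnames = dimnames(phi))
  for (rx in reactions) {
    if (!inherits(rx, "reaction_spec")) stop("reactions must be reaction_spec objects")
    flux <- rx$rate * phi[, , rx$catalyst] * phi[, , rx$substrate]
    R[, , rx$substrate] <- R[, , rx$substrate] - flux
    R[, , rx$product] <- R[, , rx$product] + flux
  }
  R
}
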