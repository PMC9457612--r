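#' Interaction-class values
#'
#' Pairwise interactions are limited to three classes: binding (chi < 0,
#' components tend to mix), neutral (chi = 0, interactionless) and
#' separating (chi > 0, components tend to demix).  With the quartic free
#' energy `F = sum_{i<j} chi_ij phi_i^2 phi_j^2`, a positive chi penalises
#' co-localisation, so binding pairs carry the negative value.
#'
#' @param binding,neutral,separating Class values; defaults -0.1, 0, +2.
#' @return Named numeric vector `c(BINDING=, NEUTRAL=, SEPARATING=)`.
#' @export
interaction_classes <- function(binding = -0.1, neutral = 0, separating = 2) {
  if (!(binding < neutral && neutral < separating)) {
    stop("interaction classes must be ordered binding < neutral < separating")
  }
  c(BINDING = binding, NEUTRAL = neutral, SEPARATING = separating)
}

#' Default destruction-complex interaction matrix
#'
#' Builds the symmetric 7x7 chi matrix realised from the scaffold-binding
#' map under the implicit-scaffold convention: every scaffold-binding
#' species (GSK3beta, CK1alpha, beta-catenin, P1-beta-catenin, nucleator)
#' is pairwise BINDING with every other one; each of them is SEPARATING
#' against cytoplasm; P4-beta-catenin (which no longer binds the scaffold)
#' is NEUTRAL to everything; diagonals are zero.
#'
#' @inheritParams interaction_classes
#' @return A `chi_matrix`: symmetric 7x7 numeric matrix with role dimnames.
#' @examples
#' chi <- default_interaction_matrix()
#' chi["BCAT", "CYTOPLASM"]   # separating, +2
#' chi["BCAT_P4", "NUCLEATOR"] # neutral, 0
#' @export
default_interaction_matrix <- function(binding = -0.1, neutral = 0,
                                       separating = 2) {
  if (binding >= separating) {
    stop("interaction class ordering violated: binding must be < separating")
  }
  n <- length(DC_ROLES)
  chi <- matrix(neutral, n, n, dimnames = list(DC_ROLES, DC_ROLES))
  chi[SCAFFOLD_BINDERS, SCAFFOLD_BINDERS] <- binding
  chi[SCAFFOLD_BINDERS, "CYTOPLASM"] <- separating
  chi["CYTOPLASM", SCAFFOLD_BINDERS] <- separating
  chi["BCAT_P4", ] <- neutral
  chi[, "BCAT_P4"] <- neutral
  diag(chi) <- 0
  as_chi_matrix(chi)
}

#' Coerce and validate an interaction matrix
#'
#' @param chi Square numeric matrix; must be symmetric with zero diagonal.
#' @return The matrix with class `chi_matrix`.
#' @export
as_chi_matrix <- function(chi) {
  chi <- as.matrix(chi)
  if (nrow(chi) != ncol(chi)) stop("chi must be square")
  if (!isTRUE(all.equal(chi, t(chi), tolerance = 1e-12))) {
    stop("chi must be symmetric")
  }
  if (any(abs(diag(chi)) > 1e-12)) {
    stop("chi must have a zero diagonal (no self-interaction)")
  }
  structure(chi, class = c("chi_matrix", "matrix", "array"))
}

#' Set the interaction between one client and the cytoplasm
#'
#' Helper used by the client-chi parameter scan: returns a copy of `chi`
#' with the symmetric `client`-`CYTOPLASM` entry replaced.
#'
#' @param chi A `chi_matrix`.
#' @param client Component role or index (must not be the cytoplasm itself).
#' @param value New chi value.
#' @export
set_client_cytoplasm_chi <- function(chi, client, value) {
  comps <- rownames(chi)
  if (is.null(comps)) comps <- DC_ROLES[seq_len(nrow(chi))]
  i <- component_index(client, comps)
  j <- component_index("CYTOPLASM", comps)
  if (i == j) stop("client must differ from the cytoplasm component")
  chi[i, j] <- value
  chi[j, i] <- value
  as_chi_matrix(unclass(chi))
}
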