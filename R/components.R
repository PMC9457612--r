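#' Destruction-complex model components
#'
#' The model tracks seven incompressible volume-fraction fields: the two
#' kinases GSK3beta and CK1alpha, beta-catenin in three phosphorylation
#' states (unphosphorylated `BCAT`, phospho-S45 `BCAT_P1`, quadruply
#' phosphorylated `BCAT_P4`), the bulk `CYTOPLASM`, and a centrosome-like
#' `NUCLEATOR` region.  The scaffolds Axin/APC are represented implicitly
#' through the pairwise interaction parameters, not as fields.
#'
#' @return A data frame with columns `index` (1..7) and `role`.
#' @examples
#' dc_components()
#' @export
dc_components <- function() {
  data.frame(index = seq_along(DC_ROLES), role = DC_ROLES,
             stringsAsFactors = FALSE)
}

#' @rdname dc_components
#' @format `DC_ROLES` is the ordered character vector of the seven roles.
#' @export
DC_ROLES <- c("GSK3B", "CK1A", "BCAT", "BCAT_P1", "BCAT_P4",
              "CYTOPLASM", "NUCLEATOR")

# roles that bind the implicit Axin/APC scaffold (Table-style binding map)
SCAFFOLD_BINDERS <- c("GSK3B", "CK1A", "BCAT", "BCAT_P1", "NUCLEATOR")

#' Resolve a component role to its field index
#'
#' @param role Character role name or an integer index, which is validated
#'   and returned as-is.
#' @param components Component name table to resolve against (default
#'   [DC_ROLES]).
#' @return Integer index.
#' @export
component_index <- function(role, components = DC_ROLES) {
  if (is.numeric(role)) {
    idx <- as.integer(role)
    if (any(idx < 1L | idx > length(components))) {
      stop("component index out of range 1..", length(components))
    }
    return(idx)
  }
  idx <- match(role, components)
  if (anyNA(idx)) {
    stop("unknown component role: ", paste(role[is.na(idx)], collapse = ", "))
  }
  idx
}
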