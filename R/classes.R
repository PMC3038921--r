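#' The four nucleolar-association classes
#'
#' Proteins are classified by their degree of association with the nucleolus:
#' `ENRICHED` (predominantly nucleolar in all conditions), `NUCLEOPLASMIC`
#' (nucleolar and other nuclear regions), `CYTOPLASMIC` (nucleolar and
#' cytoplasmic), and `NON_NUCLEOLAR` (never nucleolar). The order of the
#' returned vector is the fixed precedence order used for deterministic
#' tie-breaking throughout the package: when two classes score identically,
#' the earlier one wins.
#'
#' @return Character vector of the four class labels, in precedence order.
#' @export
#' @examples
#' nucleolar_classes()
nucleolar_classes <- function() {
  c("ENRICHED", "NUCLEOPLASMIC", "CYTOPLASMIC", "NON_NUCLEOLAR")
}

#' Coerce labels to the nucleolar-class factor
#'
#' @param x Character vector (or factor) of class labels.
#' @return Factor with levels in precedence order.
#' @export
as_nucleolar_class <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), nucleolar_classes())
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown nucleolar class label(s): ", paste(bad, collapse = ", "),
      ". Valid labels: ", paste(nucleolar_classes(), collapse = ", ")
    ))
  }
  factor(x, levels = nucleolar_classes())
}

# The three classes that can associate with the nucleolus; GO scores and the
# GO feature bins are defined over these only.
nucleolar_groups <- function() nucleolar_classes()[1:3]
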