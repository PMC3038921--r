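#' Compartment vocabulary and nucleolar proximity distances
#'
#' Subcellular-localisation annotations are grouped into four cellular
#' regions, each assigned a unitless nucleolar proximity distance:
#' 0.0 for the nucleolus; 1.2 for the nucleoplasm, nuclear speckles, nuclear
#' pore and nuclear envelope; 3.0 for the cytosol, cytoplasm, cytoplasmic
#' organelles, plasma membrane and extracellular region; and 0.8 for a bare
#' "nuclear" annotation, which does not distinguish nucleolar from
#' non-nucleolar nuclear proteins.
#'
#' The vocabulary is an editable table: pass a modified copy wherever a
#' `distances` argument is accepted to extend or re-map compartment labels.
#'
#' @return A tibble with columns `label` (compartment annotation as found in
#'   localisation files), `group` (one of `nucleolus`, `nuclear_other`,
#'   `cytoplasmic`, `nuclear_unspecified`) and `distance` (numeric, >= 0).
#' @export
#' @examples
#' localisation_distances()
localisation_distances <- function() {
  tibble(
    label = c(
      "nucleolus",
      "nucleoplasm", "nuclear_speckles", "nuclear_pore", "nuclear_envelope",
      "cytosol", "cytoplasm", "mitochondrion", "endoplasmic_reticulum",
      "golgi", "lysosome", "endosome", "peroxisome", "plasma_membrane",
      "extracellular",
      "nuclear"
    ),
    group = c(
      "nucleolus",
      rep("nuclear_other", 4),
      rep("cytoplasmic", 10),
      "nuclear_unspecified"
    ),
    distance = c(0.0, rep(1.2, 4), rep(3.0, 10), 0.8)
  )
}

# Validate a distance map and return a named numeric lookup label -> distance.
distance_lookup <- function(distances) {
  stopifnot(is.data.frame(distances))
  if (!all(c("label", "distance") %in% names(distances))) {
    abort("`distances` must have columns `label` and `distance`.")
  }
  if (any(distances$distance < 0)) abort("Distances must be >= 0.")
  if (anyDuplicated(distances$label)) {
    abort("Duplicate compartment labels in distance map.")
  }
  setNames(distances$distance, distances$label)
}
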