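#' Rectangular SILAC classification regions
#'
#' Each nucleolar class owns an axis-aligned rectangle in
#' (log2 nucleolar/cytoplasmic ratio, log2 nucleoplasmic/cytoplasmic ratio)
#' space; infinite bounds are allowed and all edges are closed. Rectangles
#' must be pairwise disjoint; points outside every rectangle map to
#' `UNDEFINED`.
#'
#' @param regions Tibble with columns `group` (the four class labels),
#'   `x_min`, `x_max`, `y_min`, `y_max` (log2 units; `-Inf`/`Inf` allowed).
#' @return Validated tibble of class `nucleo_silac_regions`.
#' @export
silac_regions <- function(regions) {
  stopifnot(is.data.frame(regions))
  need <- c("group", "x_min", "x_max", "y_min", "y_max")
  if (!all(need %in% names(regions))) {
    abort(paste0("Regions need columns: ", paste(need, collapse = ", ")))
  }
  regions$group <- as.character(regions$group)
  bad <- setdiff(regions$group, nucleolar_classes())
  if (length(bad) > 0) abort(paste0("Unknown region group(s): ", paste(bad, collapse = ", ")))
  if (anyDuplicated(regions$group)) abort("Each class may own at most one rectangle.")
  if (any(regions$x_min > regions$x_max) || any(regions$y_min > regions$y_max)) {
    abort("Rectangle bounds must satisfy min <= max.")
  }
  n <- nrow(regions)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        # closed rectangles: touching edges already count as overlap
        x_overlap <- max(regions$x_min[i], regions$x_min[j]) <=
          min(regions$x_max[i], regions$x_max[j])
        y_overlap <- max(regions$y_min[i], regions$y_min[j]) <=
          min(regions$y_max[i], regions$y_max[j])
        if (x_overlap && y_overlap) {
          abort(paste0("Overlapping SILAC rectangles: ", regions$group[i],
                       " and ", regions$group[j], "."))
        }
      }
    }
  }
  out <- as_tibble(as.data.frame(regions)[need])
  class(out) <- unique(c("nucleo_silac_regions", class(out)))
  out
}

#' Map dual SILAC abundance ratios onto the nucleolar classes
#'
#' Each protein's two positive abundance ratios are log2-transformed and
#' located among the class rectangles; a protein outside every rectangle is
#' assigned `UNDEFINED` (its ratios are too unlike those of the proteins
#' used to set the thresholds).
#'
#' @param silac Tibble with columns `id`, `nuc_cyto_ratio`,
#'   `nucpl_cyto_ratio` (both > 0).
#' @param regions A `nucleo_silac_regions` configuration.
#' @return `silac` with an added `silac_group` column (`character`: a class
#'   label or `"UNDEFINED"`).
#' @export
classify_silac <- function(silac, regions) {
  regions <- silac_regions(regions)  # idempotent validation
  stopifnot(all(c("id", "nuc_cyto_ratio", "nucpl_cyto_ratio") %in% names(silac)))
  if (any(silac$nuc_cyto_ratio <= 0) || any(silac$nucpl_cyto_ratio <= 0)) {
    abort("SILAC ratios must be > 0.")
  }
  x <- log2(silac$nuc_cyto_ratio)
  y <- log2(silac$nucpl_cyto_ratio)
  group <- rep("UNDEFINED", nrow(silac))
  for (r in seq_len(nrow(regions))) {
    inside <- x >= regions$x_min[r] & x <= regions$x_max[r] &
      y >= regions$y_min[r] & y <= regions$y_max[r]
    group[inside] <- regions$group[r]
  }
  mutate(silac, silac_group = group)
}

#' Calibrate SILAC regions from labelled overlap proteins
#'
#' Stands in for the manual threshold selection on the proteins shared by
#' the literature test set and the SILAC data: each class receives the
#' axis-aligned bounding box of its points in log2 ratio space, expanded by
#' `margin` log2 units; any two overlapping boxes are shrunk to the midline
#' between their nearest conflicting edges (cutting along the axis with the
#' smaller overlap). Proteins used for calibration are flagged so they can
#' be excluded from downstream agreement scoring.
#'
#' @param overlap Tibble with columns `id`, `nuc_cyto_ratio`,
#'   `nucpl_cyto_ratio`, `class`; at least one protein per class present in
#'   the table.
#' @param margin Non-negative log2 expansion of each bounding box
#'   (default 0.5).
#' @return A `nucleo_silac_regions` with attribute `calibration_ids` (the
#'   protein ids consumed).
#' @export
calibrate_regions <- function(overlap, margin = 0.5) {
  stopifnot(is.data.frame(overlap), margin >= 0)
  overlap <- mutate(overlap, class = as_nucleolar_class(.data$class))
  present <- unique(as.character(overlap$class))
  x <- log2(overlap$nuc_cyto_ratio)
  y <- log2(overlap$nucpl_cyto_ratio)

  # identical points in two classes can never be separated by rectangles
  key <- paste(x, y)
  clash <- tapply(as.character(overlap$class), key, function(cl) length(unique(cl)) > 1)
  if (any(clash)) {
    abort("Inseparable calibration data: identical ratio points in more than one class.")
  }

  boxes <- tibble(
    group = present,
    x_min = vapply(present, function(cl) min(x[overlap$class == cl]) - margin, numeric(1)),
    x_max = vapply(present, function(cl) max(x[overlap$class == cl]) + margin, numeric(1)),
    y_min = vapply(present, function(cl) min(y[overlap$class == cl]) - margin, numeric(1)),
    y_max = vapply(present, function(cl) max(y[overlap$class == cl]) + margin, numeric(1))
  )

  eps <- 1e-9
  repeat {
    conflict <- NULL
    n <- nrow(boxes)
    for (i in seq_len(max(0, n - 1))) {
      for (j in (i + 1):n) {
        xo <- min(boxes$x_max[i], boxes$x_max[j]) - max(boxes$x_min[i], boxes$x_min[j])
        yo <- min(boxes$y_max[i], boxes$y_max[j]) - max(boxes$y_min[i], boxes$y_min[j])
        if (xo >= 0 && yo >= 0) {
          conflict <- list(i = i, j = j, xo = xo, yo = yo)
          break
        }
      }
      if (!is.null(conflict)) break
    }
    if (is.null(conflict)) break
    i <- conflict$i; j <- conflict$j
    if (conflict$xo <= conflict$yo) {
      # cut along x at the midline of the overlapping interval
      if (boxes$x_min[i] <= boxes$x_min[j]) { lo <- i; hi <- j } else { lo <- j; hi <- i }
      mid <- (max(boxes$x_min[lo], boxes$x_min[hi]) +
                min(boxes$x_max[lo], boxes$x_max[hi])) / 2
      boxes$x_max[lo] <- mid - eps
      boxes$x_min[hi] <- mid + eps
      if (boxes$x_max[lo] < boxes$x_min[lo] || boxes$x_max[hi] < boxes$x_min[hi]) {
        abort("Inseparable calibration data: rectangle collapsed while resolving overlap.")
      }
    } else {
      if (boxes$y_min[i] <= boxes$y_min[j]) { lo <- i; hi <- j } else { lo <- j; hi <- i }
      mid <- (max(boxes$y_min[lo], boxes$y_min[hi]) +
                min(boxes$y_max[lo], boxes$y_max[hi])) / 2
      boxes$y_max[lo] <- mid - eps
      boxes$y_min[hi] <- mid + eps
      if (boxes$y_max[lo] < boxes$y_min[lo] || boxes$y_max[hi] < boxes$y_min[hi]) {
        abort("Inseparable calibration data: rectangle collapsed while resolving overlap.")
      }
    }
  }

  out <- silac_regions(boxes)
  attr(out, "calibration_ids") <- unique(overlap$id)
  out
}

#' Agreement between classifier predictions and SILAC groups
#'
#' Cross-tabulates predicted labels against SILAC-derived groups, omitting
#' proteins in the `UNDEFINED` group and any explicitly excluded ids (e.g.
#' proteins trained on or used to calibrate the SILAC thresholds). The
#' disagreement list carries both labels per protein for triage.
#'
#' @param predictions Prediction tibble (`id`, `label`, ...).
#' @param silac_groups Tibble `id`, `silac_group` as from
#'   [classify_silac()].
#' @param excluded_ids Ids omitted from scoring.
#' @return List with `confusion` (SILAC group as truth), `report`
#'   (a `nucleo_eval`), `disagreements` (tibble id, silac_group, label),
#'   and `n_undefined`.
#' @export
agreement_report <- function(predictions, silac_groups, excluded_ids = character(0)) {
  joined <- inner_join(select(predictions, "id", "label"),
                       select(silac_groups, "id", "silac_group"), by = "id")
  n_undefined <- sum(joined$silac_group == "UNDEFINED")
  scored <- filter(joined, .data$silac_group != "UNDEFINED",
                   !.data$id %in% excluded_ids)
  if (nrow(scored) == 0) {
    return(list(confusion = NULL, report = NULL,
                disagreements = tibble(id = character(0),
                                       silac_group = character(0),
                                       label = character(0)),
                n_undefined = n_undefined))
  }
  confusion <- confusion_matrix(scored$silac_group, scored$label)
  report <- class_metrics(confusion)
  disagreements <- scored |>
    filter(as.character(.data$silac_group) != as.character(.data$label)) |>
    mutate(label = as.character(.data$label)) |>
    select("id", "silac_group", "label")
  list(confusion = confusion, report = report,
       disagreements = disagreements, n_undefined = n_undefined)
}
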