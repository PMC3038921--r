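#' Discretize a value against an ordered threshold list
#'
#' Bins are half-open intervals `[t_i, t_{i+1})` with the first bin open
#' below and the last bin closed above: values below the first threshold
#' fall in bin 0, values at or above the last threshold fall in the last
#' bin, and a value exactly equal to a threshold resolves upward.
#'
#' @param value Numeric vector.
#' @param thresholds Strictly increasing numeric vector; `k` thresholds
#'   define `k + 1` bins.
#' @return Integer bin indices (0-based); `NA` in maps to `NA` out.
#' @export
#' @examples
#' discretize(c(0, 0.12, 0.2), c(0.05, 0.10, 0.15, 0.20))
discretize <- function(value, thresholds) {
  if (length(thresholds) < 1 || any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be a strictly increasing numeric vector.")
  }
  out <- findInterval(value, thresholds)
  out[is.na(value)] <- NA_integer_
  as.integer(out)
}

#' Equal-frequency bin thresholds
#'
#' Places `n_bins - 1` thresholds at the `k / n_bins` quantiles of the
#' supplied values so that each bin holds roughly (within 20 percent) the same
#' number of observations on the input itself.
#'
#' @param values Numeric vector (NAs dropped); needs at least `n_bins`
#'   distinct values.
#' @param n_bins Number of bins (>= 2).
#' @return Strictly increasing numeric vector of `n_bins - 1` thresholds.
#' @export
equal_frequency_thresholds <- function(values, n_bins) {
  stopifnot(n_bins >= 2)
  values <- values[!is.na(values)]
  if (length(unique(values)) < n_bins) {
    abort(paste0("Need at least ", n_bins, " distinct values for ",
                 n_bins, "-bin equal-frequency thresholds."))
  }
  thr <- unname(quantile(values, probs = seq_len(n_bins - 1) / n_bins, type = 7))
  if (any(diff(thr) <= 0)) {
    abort("Values too concentrated: equal-frequency thresholds are not strictly increasing.")
  }
  thr
}

#' Binning configuration for the five feature channels
#'
#' Holds the threshold lists used to discretize each continuous channel:
#' per-residue amino-acid frequency thresholds (5 bins for S/L/I, 4 for K),
#' co-expression thresholds (4 bins), the GO score threshold (a single value,
#' default 0.003, below which all class GO scores map to the "uninformative"
#' bin), and nucleolar-proximity (NPI) thresholds (5 bins). The shipped
#' defaults were calibrated once by equal-frequency binning on the default
#' synthetic reference cohort; [calibrate_binning()] re-derives thresholds
#' for any cohort.
#'
#' @param aa_thresholds Named list with elements `S`, `L`, `I`, `K`, each a
#'   strictly increasing numeric vector.
#' @param coexpr_thresholds,npi_thresholds Strictly increasing numeric
#'   vectors.
#' @param go_threshold Single positive numeric.
#' @return Object of class `nucleo_binning`.
#' @export
binning_config <- function(
    aa_thresholds = list(
      S = c(0.058317, 0.064459, 0.110374, 0.134838),
      L = c(0.056757, 0.066398, 0.071429, 0.126429),
      I = c(0.019395, 0.024581, 0.028254, 0.064045),
      K = c(0.038898, 0.044111, 0.084104)
    ),
    coexpr_thresholds = c(-0.042504, 0.004285, 0.049615),
    go_threshold = 0.003,
    npi_thresholds = c(0.779412, 1.030065, 1.293277, 2.45086)) {
  for (aa in c("S", "L", "I", "K")) {
    thr <- aa_thresholds[[aa]]
    if (is.null(thr) || any(diff(thr) <= 0)) {
      abort(paste0("aa_thresholds$", aa, " must be strictly increasing."))
    }
  }
  if (any(diff(coexpr_thresholds) <= 0)) abort("coexpr_thresholds must be strictly increasing.")
  if (any(diff(npi_thresholds) <= 0)) abort("npi_thresholds must be strictly increasing.")
  stopifnot(length(go_threshold) == 1, go_threshold > 0)
  structure(
    list(
      aa_thresholds = aa_thresholds[c("S", "L", "I", "K")],
      coexpr_thresholds = coexpr_thresholds,
      go_threshold = go_threshold,
      npi_thresholds = npi_thresholds
    ),
    class = "nucleo_binning"
  )
}

#' @export
print.nucleo_binning <- function(x, ...) {
  cat("<nucleo_binning>\n")
  for (aa in names(x$aa_thresholds)) {
    cat("  aa ", aa, ": ", paste(signif(x$aa_thresholds[[aa]], 4), collapse = ", "), "\n", sep = "")
  }
  cat("  coexpr: ", paste(signif(x$coexpr_thresholds, 4), collapse = ", "), "\n", sep = "")
  cat("  go threshold: ", x$go_threshold, "\n", sep = "")
  cat("  npi: ", paste(signif(x$npi_thresholds, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# number of bins per channel implied by a config
binning_sizes <- function(config) {
  c(
    aa_S = length(config$aa_thresholds$S) + 1L,
    aa_L = length(config$aa_thresholds$L) + 1L,
    aa_I = length(config$aa_thresholds$I) + 1L,
    aa_K = length(config$aa_thresholds$K) + 1L,
    targeting = 9L,
    coexpr = length(config$coexpr_thresholds) + 1L,
    go = 4L,
    npi = length(config$npi_thresholds) + 1L
  )
}

#' Choose discretization thresholds that minimise balanced class error
#'
#' Evaluates every combination of `n_bins - 1` thresholds drawn from a
#' candidate grid (quantiles of the observed values) and keeps the one
#' whose single-channel bin classifier — each bin predicts its
#' pseudocounted majority class — attains the smallest average per-class
#' error. This mirrors how operating thresholds for the interactor-
#' proximity channel are chosen in practice: by minimising the average
#' class error on the training corpus rather than by equal-frequency
#' quantiles, which would let the majority class dilute every bin.
#'
#' @param values Numeric channel values (NA allowed, dropped with their
#'   classes).
#' @param classes Class labels aligned with `values`.
#' @param n_bins Number of bins to produce.
#' @param n_candidates Size of the candidate quantile grid (default 16).
#' @param alpha Pseudocount used when scoring candidate tables.
#' @return Strictly increasing numeric vector of `n_bins - 1` thresholds.
#' @export
class_error_thresholds <- function(values, classes, n_bins = 5,
                                   n_candidates = 16, alpha = 0.1) {
  keep <- !is.na(values)
  values <- values[keep]
  classes <- as_nucleolar_class(classes[keep])
  if (length(unique(values)) < n_bins) {
    abort("Too few distinct values to place class-error thresholds.")
  }
  cand <- unique(unname(quantile(values, probs = seq_len(n_candidates) /
                                   (n_candidates + 1), type = 7)))
  if (length(cand) < n_bins - 1) {
    abort("Too few distinct candidate thresholds.")
  }
  combos <- utils::combn(length(cand), n_bins - 1)
  lev <- levels(classes)
  cls_idx <- as.integer(classes)
  n_true <- tabulate(cls_idx, nbins = length(lev))
  best <- NULL
  best_err <- Inf
  for (k in seq_len(ncol(combos))) {
    thr <- cand[combos[, k]]
    bins <- findInterval(values, thr)
    counts <- matrix(0, n_bins, length(lev))
    for (b in 0:(n_bins - 1)) {
      counts[b + 1, ] <- tabulate(cls_idx[bins == b], nbins = length(lev))
    }
    prop <- (counts + alpha) / rowSums(counts + alpha)
    pred_class <- max.col(prop, ties.method = "first")
    tp <- vapply(seq_along(lev), function(ci) {
      sum(counts[pred_class == ci, ci])
    }, numeric(1))
    sens <- ifelse(n_true > 0, tp / n_true, NA_real_)
    err <- mean(1 - sens, na.rm = TRUE)
    if (err < best_err) {
      best_err <- err
      best <- thr
    }
  }
  best
}

#' Calibrate binning thresholds on a cohort
#'
#' Derives thresholds for the continuous channels from the observed feature
#' values of a labelled cohort: equal-frequency quantiles for the
#' co-expression channel (its bins are defined to hold roughly equal
#' numbers of proteins), and balanced-class-error optimisation
#' ([class_error_thresholds()]) for the amino-acid and NPI channels, whose
#' operating thresholds are picked empirically to minimise the average
#' class error — quantile bins would let the majority class dilute every
#' bin. Co-expression and NPI values are computed with the cohort's own
#' training groups as reference (no protein excluded); the GO threshold is
#' kept at its configured value, which is a published operating point
#' rather than a quantile.
#'
#' @param cohort A `nucleo_cohort` with a `labels` table.
#' @param n_bins_aa,n_bins_aa_K,n_bins_coexpr,n_bins_npi Bin counts per
#'   channel (defaults 5/4/4/5).
#' @param go_threshold GO score threshold carried into the result.
#' @return A `nucleo_binning` configuration.
#' @export
calibrate_binning <- function(cohort, n_bins_aa = 5, n_bins_aa_K = 4,
                              n_bins_coexpr = 4, n_bins_npi = 5,
                              go_threshold = 0.003) {
  stopifnot(inherits(cohort, "nucleo_cohort"))
  if (is.null(cohort$labels)) abort("Calibration requires a labelled cohort.")
  groups <- training_groups(cohort$labels)
  state <- feature_state(cohort)
  raw <- raw_channel_values(state, groups, exclude = character(0))
  labelled <- state$ids %in% cohort$labels$id
  cls <- cohort$labels$class[match(state$ids[labelled], cohort$labels$id)]
  freqs <- aa_frequencies(cohort$proteins$sequence)[labelled, , drop = FALSE]
  aa_thr <- list(
    S = class_error_thresholds(freqs$S, cls, n_bins_aa),
    L = class_error_thresholds(freqs$L, cls, n_bins_aa),
    I = class_error_thresholds(freqs$I, cls, n_bins_aa),
    K = class_error_thresholds(freqs$K, cls, n_bins_aa_K)
  )
  coexpr_thr <- equal_frequency_thresholds(raw$coexpr, n_bins_coexpr)
  npi_thr <- class_error_thresholds(unname(raw$npi[labelled]), cls, n_bins_npi)
  binning_config(
    aa_thresholds = aa_thr,
    coexpr_thresholds = coexpr_thr,
    go_threshold = go_threshold,
    npi_thresholds = npi_thr
  )
}
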