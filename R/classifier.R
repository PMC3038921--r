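#' Train the semi-naive Bayes nucleolar-association model
#'
#' For every feature channel, proteins of each class are counted per bin;
#' a pseudocount `alpha` (default 0.1) is added to every (bin, class) cell,
#' and each bin's counts are divided by the pseudocounted total over all
#' four classes in that bin. Each channel therefore yields a table of
#' per-bin class proportions; rows (bins) sum to one and all entries are
#' strictly positive. Channels with a missing bin for a protein simply do
#' not count that protein.
#'
#' @param features Feature tibble as from [extract_features()] (column `id`
#'   plus bin columns).
#' @param labels Tibble with columns `id`, `class`; every labelled protein
#'   must appear in `features`.
#' @param priors Named numeric vector of class priors (strictly positive,
#'   summing to 1). Defaults to the published operating point 0.2 / 0.15 /
#'   0.15 / 0.5.
#' @param alpha Pseudocount, > 0; default 0.1.
#' @param config The `nucleo_binning` configuration used to build
#'   `features` (fixes the bin count per channel).
#' @return Object of class `nucleo_model`.
#' @export
train_model <- function(features, labels,
                        priors = default_priors(), alpha = 0.1,
                        config = binning_config()) {
  stopifnot(is.data.frame(features), is.data.frame(labels))
  if (alpha <= 0) abort("Pseudocount `alpha` must be > 0.")
  if (nrow(labels) == 0) abort("Training corpus is empty.")
  validate_priors(priors)
  labels <- mutate(labels, class = as_nucleolar_class(.data$class))
  missing_ids <- setdiff(labels$id, features$id)
  if (length(missing_ids) > 0) {
    abort(paste0("No feature vector for labelled protein(s): ",
                 paste(missing_ids, collapse = ", ")))
  }
  dat <- inner_join(labels, features, by = "id") |> arrange(.data$id)
  sizes <- binning_sizes(config)
  tables <- lapply(names(sizes), function(ch) {
    cpt_from_counts(channel_counts(dat[[ch]], dat$class, sizes[[ch]]), alpha)
  })
  names(tables) <- names(sizes)
  structure(
    list(
      priors = priors[nucleolar_classes()],
      alpha = alpha,
      tables = tables,
      binning = config,
      manifest = tibble(id = dat$id, class = dat$class)
    ),
    class = "nucleo_model"
  )
}

default_priors <- function() {
  setNames(c(0.2, 0.15, 0.15, 0.5), nucleolar_classes())
}

validate_priors <- function(priors) {
  if (!all(nucleolar_classes() %in% names(priors))) {
    abort("`priors` must be named with all four nucleolar classes.")
  }
  priors <- priors[nucleolar_classes()]
  if (any(priors <= 0)) abort("Priors must be strictly positive.")
  if (abs(sum(priors) - 1) > 1e-9) abort("Priors must sum to 1 (within 1e-9).")
  invisible(priors)
}

channel_counts <- function(bins, class, n_bins) {
  keep <- !is.na(bins)
  tab <- table(
    factor(bins[keep], levels = 0:(n_bins - 1L)),
    factor(class[keep], levels = nucleolar_classes())
  )
  m <- matrix(as.numeric(tab), nrow = n_bins,
              dimnames = list(bin = 0:(n_bins - 1L), class = nucleolar_classes()))
  m
}

cpt_from_counts <- function(counts, alpha) {
  num <- counts + alpha
  num / rowSums(num)
}

#' @export
print.nucleo_model <- function(x, ...) {
  cat("<nucleo_model> semi-naive Bayes, ", length(x$tables), " feature channels, ",
      nrow(x$manifest), " training proteins\n", sep = "")
  cat("  priors: ", paste(names(x$priors), x$priors, sep = "=", collapse = ", "),
      "; alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Per-class scores for feature vectors
#'
#' The score of class `c` is the class prior multiplied by the product,
#' over the channels whose bin is observed, of the class-`c` entry of that
#' channel's conditional probability table at the observed bin. Computed in
#' log space and exponentiated, so scores are strictly positive.
#'
#' @param model A `nucleo_model`.
#' @param features Feature tibble (column `id` plus bin columns).
#' @return Tibble with `id`, one score column per class (named
#'   `score_<CLASS>`), and `channels_used`.
#' @export
score_classes <- function(model, features) {
  stopifnot(inherits(model, "nucleo_model"))
  classes <- nucleolar_classes()
  n <- nrow(features)
  logs <- matrix(rep(log(model$priors), each = n), nrow = n,
                 dimnames = list(NULL, classes))
  used <- integer(n)
  for (ch in names(model$tables)) {
    tab <- model$tables[[ch]]
    bins <- features[[ch]]
    if (is.null(bins)) abort(paste0("Feature table lacks channel `", ch, "`."))
    ok <- !is.na(bins)
    if (any(bins[ok] < 0 | bins[ok] > nrow(tab) - 1L)) {
      abort(paste0("Bin index out of range for channel `", ch, "`."))
    }
    logs[ok, ] <- logs[ok, , drop = FALSE] + log(tab[bins[ok] + 1L, , drop = FALSE])
    used <- used + as.integer(ok)
  }
  out <- as_tibble(exp(logs))
  names(out) <- paste0("score_", classes)
  bind_cols(tibble(id = features$id), out, tibble(channels_used = used))
}

#' Classify feature vectors
#'
#' Labels each protein with its highest-scoring class (ties broken by the
#' fixed class precedence) and reports the reliability index: the ratio of
#' the highest to the second-highest class score (1 under an exact tie;
#' always finite because pseudocounts keep every score positive).
#'
#' @inheritParams score_classes
#' @return Prediction tibble: `id`, the four `score_*` columns, `label`
#'   (factor), `reliability_index`, `channels_used`.
#' @export
classify <- function(model, features) {
  scored <- score_classes(model, features)
  sm <- as.matrix(scored[paste0("score_", nucleolar_classes())])
  top_idx <- apply(sm, 1, which.max)  # first max = precedence winner
  top <- sm[cbind(seq_len(nrow(sm)), top_idx)]
  second <- vapply(seq_len(nrow(sm)), function(i) {
    max(sm[i, -top_idx[i]])
  }, numeric(1))
  mutate(
    scored,
    label = factor(nucleolar_classes()[top_idx], levels = nucleolar_classes()),
    reliability_index = top / second
  ) |>
    select("id", dplyr::starts_with("score_"), "label",
           "reliability_index", "channels_used")
}

#' @rdname classify
#' @param object A `nucleo_model`.
#' @param ... Unused.
#' @export
predict.nucleo_model <- function(object, features, ...) {
  classify(object, features)
}

#' Write / read a model as diffable JSON
#'
#' The model file carries priors, pseudocount, binning thresholds, all
#' conditional probability tables and the training manifest. Loading
#' re-validates every invariant (priors positive summing to 1, strictly
#' positive table entries, per-bin sums of 1).
#'
#' @param model A `nucleo_model`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "nucleo_model"))
  payload <- list(
    format = "nucleoclass-model",
    version = 1L,
    priors = as.list(model$priors),
    alpha = model$alpha,
    binning = list(
      aa_thresholds = model$binning$aa_thresholds,
      coexpr_thresholds = model$binning$coexpr_thresholds,
      go_threshold = model$binning$go_threshold,
      npi_thresholds = model$binning$npi_thresholds
    ),
    tables = lapply(model$tables, function(m) {
      list(bins = rownames(m), classes = colnames(m), values = unclass(m))
    }),
    manifest = list(id = model$manifest$id, class = as.character(model$manifest$class))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$format) || payload$format != "nucleoclass-model") {
    abort("Not a nucleoclass model file.")
  }
  priors <- unlist(payload$priors)
  validate_priors(priors)
  config <- binning_config(
    aa_thresholds = lapply(payload$binning$aa_thresholds, as.numeric),
    coexpr_thresholds = as.numeric(payload$binning$coexpr_thresholds),
    go_threshold = as.numeric(payload$binning$go_threshold),
    npi_thresholds = as.numeric(payload$binning$npi_thresholds)
  )
  tables <- lapply(payload$tables, function(t) {
    m <- as.matrix(t$values)
    dimnames(m) <- list(bin = t$bins, class = t$classes)
    if (any(m <= 0)) abort("Model file invalid: non-positive table entry.")
    if (any(abs(rowSums(m) - 1) > 1e-9)) {
      abort("Model file invalid: bin proportions do not sum to 1.")
    }
    m
  })
  expected <- names(binning_sizes(config))
  if (!identical(sort(names(tables)), sort(expected))) {
    abort("Model file invalid: unexpected feature channel set.")
  }
  structure(
    list(
      priors = priors[nucleolar_classes()],
      alpha = as.numeric(payload$alpha),
      tables = tables[expected],
      binning = config,
      manifest = tibble(
        id = payload$manifest$id,
        class = as_nucleolar_class(payload$manifest$class)
      )
    ),
    class = "nucleo_model"
  )
}

#' Tidy a fitted model into one row per (channel, bin, class)
#'
#' @param x A `nucleo_model`.
#' @param ... Unused.
#' @return Tibble with columns `channel`, `bin`, `class`, `proportion`.
#' @export
tidy.nucleo_model <- function(x, ...) {
  purrr::imap(x$tables, function(m, ch) {
    as_tibble(as.data.frame.table(m, responseName = "proportion")) |>
      mutate(channel = ch,
             bin = as.integer(as.character(.data$bin)),
             class = as.character(.data$class))
  }) |>
    bind_rows() |>
    select("channel", "bin", "class", "proportion")
}

#' One-row model summary
#'
#' @param x A `nucleo_model`.
#' @param ... Unused.
#' @return Tibble with training size, channel count and hyperparameters.
#' @export
glance.nucleo_model <- function(x, ...) {
  tibble(
    n_train = nrow(x$manifest),
    n_channels = length(x$tables),
    alpha = x$alpha,
    prior_enriched = unname(x$priors["ENRICHED"]),
    prior_nucleoplasmic = unname(x$priors["NUCLEOPLASMIC"]),
    prior_cytoplasmic = unname(x$priors["CYTOPLASMIC"]),
    prior_non_nucleolar = unname(x$priors["NON_NUCLEOLAR"])
  )
}
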