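#' Frequencies of the four discriminative residues
#'
#' Serine, leucine, isoleucine and lysine frequencies differ between the
#' nucleolar-association classes; each is measured as residue count divided
#' by sequence length.
#'
#' @param sequence Character vector of amino-acid sequences (non-empty).
#' @return Tibble with one row per sequence and columns `S`, `L`, `I`, `K`.
#' @export
#' @examples
#' aa_frequencies(c("SLIK", "SSSS"))
aa_frequencies <- function(sequence) {
  if (any(!nzchar(sequence))) abort("Sequences must be non-empty.")
  len <- nchar(sequence)
  tibble(
    S = stringr::str_count(sequence, stringr::fixed("S")) / len,
    L = stringr::str_count(sequence, stringr::fixed("L")) / len,
    I = stringr::str_count(sequence, stringr::fixed("I")) / len,
    K = stringr::str_count(sequence, stringr::fixed("K")) / len
  )
}

#' Targeting-motif scores from upstream predictor outputs
#'
#' Combines signal-peptide and transmembrane-domain predictions (Phobius),
#' mitochondrial targeting-peptide predictions (TargetP) and the maximum
#' nucleolar-localisation-sequence score (NoD) into four discrete scores:
#' the secretory-membrane score `s_S` (1 if a signal peptide or at least one
#' TMD is predicted), the mitochondrial score `s_M`, the NoLS score `s_N`
#' (2 if the NoLS maximum is >= 0.9, 1 if in \[0.8, 0.9), 0 otherwise; a
#' missing NoLS score means no predicted NoLS, so 0), and the derived cyto
#' score `s_C` (2 if `s_S` = 1 regardless of `s_M`; 1 if `s_M` = 1 and
#' `s_S` = 0; 0 otherwise).
#'
#' @param signal_peptide Logical (or 0/1) vector.
#' @param tmd_count Non-negative integer vector.
#' @param mito_peptide Logical (or 0/1) vector.
#' @param nols_max Numeric vector in \[0, 1\], NA allowed.
#' @return Tibble with integer columns `s_M`, `s_S`, `s_N`, `s_C`.
#' @export
#' @examples
#' targeting_scores(FALSE, 0, TRUE, 0.5)
targeting_scores <- function(signal_peptide, tmd_count, mito_peptide, nols_max) {
  if (any(tmd_count < 0, na.rm = TRUE)) abort("tmd_count must be >= 0.")
  if (any(!is.na(nols_max) & (nols_max < 0 | nols_max > 1))) {
    abort("nols_max must lie in [0, 1].")
  }
  s_S <- as.integer(as.logical(signal_peptide) | tmd_count >= 1)
  s_M <- as.integer(as.logical(mito_peptide))
  s_N <- dplyr::case_when(
    is.na(nols_max) ~ 0L,
    nols_max >= 0.9 ~ 2L,
    nols_max >= 0.8 ~ 1L,
    TRUE ~ 0L
  )
  s_C <- dplyr::case_when(s_S == 1L ~ 2L, s_M == 1L ~ 1L, TRUE ~ 0L)
  tibble(s_M = s_M, s_S = s_S, s_N = s_N, s_C = s_C)
}

#' Targeting feature bin
#'
#' Maps the (cyto score, NoLS score) pair bijectively onto the nine bins
#' `3 * s_C + s_N`.
#'
#' @param scores Tibble from [targeting_scores()], or missing if `s_C`/`s_N`
#'   are given directly.
#' @param s_C,s_N Integer vectors in `{0, 1, 2}`.
#' @return Integer bin index in 0..8.
#' @export
targeting_bin <- function(scores = NULL, s_C = scores$s_C, s_N = scores$s_N) {
  stopifnot(all(s_C %in% 0:2), all(s_N %in% 0:2))
  as.integer(3L * s_C + s_N)
}

#' Mean co-expression with a reference group
#'
#' The average Pearson correlation between a query expression profile and a
#' set of reference profiles (in practice, the nucleolar-cytoplasmic training
#' group). References with zero variance are skipped; the result is `NA` if
#' the query has zero variance or no usable reference remains.
#'
#' @param query Numeric expression vector (length >= 3).
#' @param references A list of numeric vectors, or a matrix with one
#'   reference per row, all the same length as `query`.
#' @return Mean correlation in \[-1, 1\], or `NA`.
#' @export
coexpression_score <- function(query, references) {
  if (is.matrix(references)) {
    references <- asplit(references, 1)
  }
  if (length(references) == 0) return(NA_real_)
  lens <- vapply(references, length, integer(1))
  if (any(lens != length(query))) {
    abort("All expression profiles must share the query's length.")
  }
  if (length(query) < 3) abort("Expression profiles need length >= 3.")
  if (sd(query) == 0) return(NA_real_)
  rs <- vapply(references, function(r) {
    if (sd(r) == 0) NA_real_ else cor(query, r)
  }, numeric(1))
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0) return(NA_real_)
  mean(rs)
}

#' Per-class GO scores for a protein
#'
#' For each nucleolar-association class `c`, the GO score is the mean over
#' the protein's annotating terms `t` of the ratio `n_ct / n_t`, where
#' `n_ct` is the number of class-`c` proteins annotated with `t` and `n_t`
#' the number of proteome proteins annotated with `t`. Terms absent from
#' the proteome count table are dropped with a warning.
#'
#' @param terms Character vector of term ids annotating the protein.
#' @param class_term_counts Named list (one element per nucleolar class
#'   `ENRICHED`, `NUCLEOPLASMIC`, `CYTOPLASMIC`), each a named numeric
#'   vector of per-term class counts.
#' @param proteome_term_counts Named numeric vector of per-term proteome
#'   counts (all >= 1).
#' @return List with `g` (named numeric over the three nucleolar classes;
#'   all `NA` when no usable term remains) and `n_terms` (number of usable
#'   terms).
#' @export
go_scores <- function(terms, class_term_counts, proteome_term_counts) {
  classes <- nucleolar_groups()
  terms <- unique(terms)
  usable <- terms[terms %in% names(proteome_term_counts)]
  dropped <- setdiff(terms, usable)
  if (length(dropped) > 0) {
    warn(paste0("Dropping term(s) absent from the proteome table: ",
                paste(dropped, collapse = ", ")))
  }
  if (length(usable) == 0) {
    return(list(g = setNames(rep(NA_real_, 3), classes), n_terms = 0L))
  }
  n_t <- proteome_term_counts[usable]
  if (any(n_t < 1)) abort("Proteome term counts must be >= 1.")
  g <- vapply(classes, function(cl) {
    n_ct <- class_term_counts[[cl]][usable]
    n_ct[is.na(n_ct)] <- 0
    mean(n_ct / n_t)
  }, numeric(1))
  list(g = g, n_terms = length(usable))
}

#' GO feature bin
#'
#' Bin 0/1/2 for whichever of the enriched / nucleoplasmic / cytoplasmic GO
#' scores is highest (ties broken by class precedence), or bin 3 when the
#' score vector is undefined or all scores fall below the threshold
#' (default 0.003).
#'
#' @param g Numeric vector of the three class GO scores (in precedence
#'   order), or a 3-column matrix with one protein per row.
#' @param go_threshold Threshold below which all scores are uninformative.
#' @return Integer bin in 0..3.
#' @export
go_bin <- function(g, go_threshold = 0.003) {
  if (!is.matrix(g)) g <- matrix(g, nrow = 1)
  stopifnot(ncol(g) == 3)
  unname(apply(g, 1, function(row) {
    if (all(is.na(row)) || max(row, na.rm = TRUE) < go_threshold) {
      3L
    } else {
      as.integer(which.max(row) - 1L)
    }
  }))
}

#' Nucleolar proximity of one interactor
#'
#' The mean nucleolar proximity distance over the compartments annotated to
#' an interactor.
#'
#' @param labels Non-empty character vector of compartment labels.
#' @param distances Distance map, see [localisation_distances()].
#' @return Mean distance (numeric scalar).
#' @export
#' @examples
#' interactor_np(c("nucleolus", "cytosol"))
interactor_np <- function(labels, distances = localisation_distances()) {
  if (length(labels) == 0) abort("Interactor has no localisation annotation.")
  lookup <- distance_lookup(distances)
  bad <- setdiff(labels, names(lookup))
  if (length(bad) > 0) {
    abort(paste0("Unresolvable compartment label(s): ", paste(bad, collapse = ", ")))
  }
  mean(lookup[labels])
}

#' Nucleolar proximity of a protein's interactors (NPI)
#'
#' The mean, over a protein's interaction partners, of each partner's mean
#' compartment distance. Partners listed in `excluded_ids`, self-loops, and
#' partners without localisation annotation are ignored; the score is `NA`
#' when no usable partner remains.
#'
#' @param protein_id Query protein id.
#' @param ppi Tibble of undirected edges with columns `id_a`, `id_b`.
#' @param localisation Tibble with columns `id`, `label`.
#' @param excluded_ids Ids removed from the partner set (e.g. the held-out
#'   test protein during cross-validation).
#' @param distances Distance map.
#' @return NPI score or `NA`.
#' @export
npi_score <- function(protein_id, ppi, localisation, excluded_ids = character(0),
                      distances = localisation_distances()) {
  partners <- unique(c(
    ppi$id_b[ppi$id_a == protein_id],
    ppi$id_a[ppi$id_b == protein_id]
  ))
  partners <- setdiff(partners, c(protein_id, excluded_ids))
  if (length(partners) == 0) return(NA_real_)
  labs <- split(localisation$label, localisation$id)
  partners <- partners[partners %in% names(labs)]
  if (length(partners) == 0) return(NA_real_)
  nps <- vapply(partners, function(i) interactor_np(labs[[i]], distances), numeric(1))
  mean(nps)
}

# ---------------------------------------------------------------------------
# Internal feature state: everything about a cohort that does not depend on
# the training groups or on which protein is held out. Computing it once
# makes leave-one-out evaluation cheap.

feature_state <- function(cohort) {
  stopifnot(inherits(cohort, "nucleo_cohort"))
  ids <- cohort$proteins$id
  freqs <- aa_frequencies(cohort$proteins$sequence)

  # targeting: proteins without a predictor record get all-zero scores
  tg <- tibble(id = ids)
  if (!is.null(cohort$targeting)) {
    tg <- left_join(tg, cohort$targeting, by = "id")
  } else {
    tg$signal_peptide <- NA_integer_; tg$tmd_count <- NA_integer_
    tg$mito_peptide <- NA_integer_; tg$nols_max <- NA_real_
  }
  sc <- targeting_scores(
    signal_peptide = dplyr::coalesce(tg$signal_peptide, 0L),
    tmd_count = dplyr::coalesce(tg$tmd_count, 0L),
    mito_peptide = dplyr::coalesce(tg$mito_peptide, 0L),
    nols_max = tg$nols_max
  )
  targeting_bins <- targeting_bin(sc)

  # expression correlation matrix (proteins x proteins), NA where undefined
  corr <- NULL
  if (!is.null(cohort$expression)) {
    em <- as.matrix(cohort$expression[, -1, drop = FALSE])
    rownames(em) <- cohort$expression$id
    em <- em[rownames(em) %in% ids, , drop = FALSE]
    corr <- suppressWarnings(cor(t(em)))
  }

  # GO: per-protein term list plus proteome term counts over the cohort
  terms_by_id <- list()
  n_t <- numeric(0)
  if (!is.null(cohort$go)) {
    go_tbl <- distinct(cohort$go[cohort$go$id %in% ids, ], .data$id, .data$term_id)
    terms_by_id <- split(go_tbl$term_id, go_tbl$id)
    n_t <- table(go_tbl$term_id)
    n_t <- setNames(as.numeric(n_t), names(n_t))
  }

  # interactors: adjacency list and per-protein mean compartment distance
  adjacency <- list()
  np <- setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(cohort$ppi)) {
    edges <- cohort$ppi[cohort$ppi$id_a != cohort$ppi$id_b, , drop = FALSE]
    both <- tibble(
      id = c(edges$id_a, edges$id_b),
      partner = c(edges$id_b, edges$id_a)
    )
    both <- distinct(both)
    adjacency <- split(both$partner, both$id)
  }
  if (!is.null(cohort$localisation)) {
    lookup <- distance_lookup(cohort$distances)
    d <- lookup[cohort$localisation$label]
    means <- tapply(d, cohort$localisation$id, mean)
    np[names(means)[names(means) %in% ids]] <-
      means[names(means) %in% ids]
  }

  list(
    ids = ids, freqs = freqs, targeting_bins = targeting_bins,
    corr = corr, terms_by_id = terms_by_id, n_t = n_t,
    adjacency = adjacency, np = np
  )
}

#' Split a labelled corpus into per-class id groups
#'
#' @param labels Tibble with columns `id`, `class`.
#' @return Named list of id vectors, one element per nucleolar class.
#' @export
training_groups <- function(labels) {
  labels$class <- as_nucleolar_class(labels$class)
  split(labels$id, labels$class)
}

# Continuous channel values (coexpr, go score matrix, npi) for every cohort
# protein, given reference groups and an exclusion set.
raw_channel_values <- function(state, groups, exclude = character(0)) {
  ids <- state$ids
  n <- length(ids)

  # co-expression with the nucleolar-cytoplasmic group (self excluded)
  coexpr <- setNames(rep(NA_real_, n), ids)
  if (!is.null(state$corr)) {
    refs <- setdiff(groups$CYTOPLASMIC, exclude)
    refs <- refs[refs %in% rownames(state$corr)]
    if (length(refs) > 0) {
      sub <- state$corr[, refs, drop = FALSE]
      have <- rownames(sub)
      row_sum <- rowSums(sub, na.rm = TRUE)
      row_cnt <- rowSums(!is.na(sub))
      is_self <- have %in% refs
      row_sum[is_self] <- row_sum[is_self] - 1
      row_cnt[is_self] <- row_cnt[is_self] - 1L
      vals <- ifelse(row_cnt > 0, row_sum / row_cnt, NA_real_)
      # proteins whose own profile has zero variance have an all-NA row
      vals[rowSums(!is.na(state$corr[have, , drop = FALSE])) == 0] <- NA_real_
      coexpr[have] <- vals
    }
  }

  # GO scores: class term counts over the (exclusion-filtered) groups
  gmat <- matrix(NA_real_, n, 3, dimnames = list(ids, nucleolar_groups()))
  n_terms <- setNames(rep(0L, n), ids)
  if (length(state$n_t) > 0) {
    have <- names(state$terms_by_id)
    tl <- state$terms_by_id[have]
    lens <- lengths(tl)
    flat_id <- rep(have, lens)
    flat_term <- unlist(tl, use.names = FALSE)
    keep <- flat_term %in% names(state$n_t)
    flat_id <- flat_id[keep]; flat_term <- flat_term[keep]
    nt <- state$n_t[flat_term]
    n_terms[have] <- vapply(tl, function(t) sum(t %in% names(state$n_t)), integer(1))
    for (cl in nucleolar_groups()) {
      members <- setdiff(groups[[cl]], exclude)
      cnt <- table(unlist(state$terms_by_id[intersect(members, names(state$terms_by_id))],
                          use.names = FALSE))
      n_ct <- setNames(as.numeric(cnt), names(cnt))[flat_term]
      n_ct[is.na(n_ct)] <- 0
      sums <- rowsum(n_ct / nt, group = flat_id)
      gmat[rownames(sums), cl] <- sums[, 1] / n_terms[rownames(sums)]
    }
  }

  # NPI: mean partner distance, held-out ids excluded from partner sets
  npi <- setNames(rep(NA_real_, n), ids)
  if (length(state$adjacency) > 0) {
    annotated <- names(state$np)[!is.na(state$np)]
    for (i in intersect(ids, names(state$adjacency))) {
      partners <- setdiff(state$adjacency[[i]], c(i, exclude))
      partners <- partners[partners %in% annotated]
      if (length(partners) > 0) npi[i] <- mean(state$np[partners])
    }
  }

  list(coexpr = coexpr, g = gmat, n_terms = n_terms, npi = npi)
}

# Assemble the per-protein bin table from precomputed state.
features_from_state <- function(state, groups, config, exclude = character(0)) {
  raw <- raw_channel_values(state, groups, exclude)
  g_for_bin <- raw$g
  g_for_bin[raw$n_terms == 0, ] <- NA_real_
  tibble(
    id = state$ids,
    aa_S = discretize(state$freqs$S, config$aa_thresholds$S),
    aa_L = discretize(state$freqs$L, config$aa_thresholds$L),
    aa_I = discretize(state$freqs$I, config$aa_thresholds$I),
    aa_K = discretize(state$freqs$K, config$aa_thresholds$K),
    targeting = state$targeting_bins,
    coexpr = discretize(unname(raw$coexpr), config$coexpr_thresholds),
    go = go_bin(g_for_bin, config$go_threshold),
    npi = discretize(unname(raw$npi), config$npi_thresholds)
  )
}

#' Extract the discretized feature table for a cohort
#'
#' Computes all eight feature bins (four amino-acid channels, the targeting
#' channel, co-expression, GO, and NPI) for every protein in the cohort.
#' The amino-acid and targeting bins depend only on the protein itself and
#' are never missing (absent targeting-predictor records are treated as
#' all-negative predictions); co-expression and NPI are `NA` when no usable
#' expression profile or annotated interactor exists; proteins without
#' usable GO terms fall in GO bin 3.
#'
#' @param cohort A `nucleo_cohort`.
#' @param groups Named list of training-group id vectors (elements
#'   `ENRICHED`, `NUCLEOPLASMIC`, `CYTOPLASMIC`); defaults to the cohort's
#'   own labels.
#' @param config A `nucleo_binning` configuration.
#' @param exclude Ids excluded from all reference structures (GO class
#'   counts, co-expression references, interactor sets) — used to hold a
#'   test protein out.
#' @return Tibble with column `id` plus one integer bin column per channel.
#' @export
extract_features <- function(cohort, groups = NULL, config = binning_config(),
                             exclude = character(0)) {
  stopifnot(inherits(cohort, "nucleo_cohort"), inherits(config, "nucleo_binning"))
  if (is.null(groups)) {
    if (is.null(cohort$labels)) abort("Provide `groups` or a labelled cohort.")
    groups <- training_groups(cohort$labels)
  }
  state <- feature_state(cohort)
  features_from_state(state, groups, config, exclude)
}
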