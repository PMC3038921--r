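#' Specification of a synthetic nucleolar cohort
#'
#' Describes the class-conditional structure of a simulated cohort:
#' class sizes (default 30 / 22 / 24 / 200, the sizes of the curated
#' training groups plus the resampled negative set), per-class amino-acid
#' compositions, targeting-predictor output distributions, GO term pools,
#' expression templates, interaction densities, localisation vocabularies
#' with a corruption rate, SILAC log2 ratio distributions and per-organism
#' orthologue probabilities. The `separation` preset scales every
#' between-class contrast: `"high"` keeps the full contrasts (disjoint GO
#' pools, strongly biased compositions, dense within-class interactions),
#' `"medium"` and `"low"` shrink them toward the pooled average by factors
#' 0.6 and 0.25.
#'
#' @param separation One of `"high"`, `"medium"`, `"low"`.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the spec.
#' @param class_sizes Named integer vector over the four classes (each
#'   >= 2).
#' @param n_tissues Number of expression tissues (default 79).
#' @param corruption_rate Probability that a localisation label is replaced
#'   by a random vocabulary label (default 0.1).
#' @param expression_missing_rate Fraction of proteins without an
#'   expression profile (default 0.05).
#' @param localisation_missing_rate Fraction of proteins without
#'   localisation annotation (default 0.1).
#' @return Object of class `nucleo_cohort_spec`.
#' @export
cohort_spec <- function(separation = c("high", "medium", "low"), seed = 42,
                        class_sizes = c(ENRICHED = 30L, NUCLEOPLASMIC = 22L,
                                        CYTOPLASMIC = 24L, NON_NUCLEOLAR = 200L),
                        n_tissues = 79L, corruption_rate = 0.1,
                        expression_missing_rate = 0.05,
                        localisation_missing_rate = 0.1) {
  separation <- match.arg(separation)
  if (!all(nucleolar_classes() %in% names(class_sizes))) {
    abort("`class_sizes` must name all four classes.")
  }
  class_sizes <- class_sizes[nucleolar_classes()]
  if (any(class_sizes < 2)) abort("Each class size must be >= 2.")
  stopifnot(n_tissues >= 3, corruption_rate >= 0, corruption_rate <= 1)
  f <- c(high = 1, medium = 0.6, low = 0.25)[[separation]]

  baseline <- c(
    A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, E = 0.071,
    Q = 0.048, G = 0.066, H = 0.026, I = 0.043, L = 0.100, K = 0.058,
    M = 0.021, F = 0.037, P = 0.063, S = 0.083, T = 0.053, W = 0.012,
    Y = 0.027, V = 0.060
  )
  baseline <- baseline / sum(baseline)
  # full-separation shifts on the four discriminative residues
  deltas <- list(
    ENRICHED      = c(S = 0.015, L = -0.030, I = -0.018, K = 0.060),
    NUCLEOPLASMIC = c(S = 0.060, L = -0.028, I = -0.016, K = 0.018),
    CYTOPLASMIC   = c(S = -0.040, L = 0.045, I = 0.035, K = -0.025),
    NON_NUCLEOLAR = c(S = 0.000, L = 0.000, I = 0.000, K = 0.000)
  )
  compositions <- lapply(deltas, function(d) {
    comp <- baseline
    comp[names(d)] <- comp[names(d)] + f * d
    rest <- setdiff(names(comp), names(d))
    comp[rest] <- comp[rest] * (1 - sum(comp[names(d)])) / sum(comp[rest])
    comp / sum(comp)
  })

  blend <- function(full, base) base + f * (full - base)
  # targeting rates: full-separation per class, blended toward pooled means
  tg_full <- list(
    ENRICHED      = list(signal = 0.02, tmd_lambda = 0.03, mito = 0.01, nols_mean = 0.85, nols_conc = 9),
    NUCLEOPLASMIC = list(signal = 0.03, tmd_lambda = 0.05, mito = 0.02, nols_mean = 0.60, nols_conc = 8),
    CYTOPLASMIC   = list(signal = 0.06, tmd_lambda = 0.10, mito = 0.06, nols_mean = 0.60, nols_conc = 8),
    NON_NUCLEOLAR = list(signal = 0.45, tmd_lambda = 0.85, mito = 0.18, nols_mean = 0.12, nols_conc = 9)
  )
  pooled <- list(
    signal = mean(vapply(tg_full, `[[`, numeric(1), "signal")),
    tmd_lambda = mean(vapply(tg_full, `[[`, numeric(1), "tmd_lambda")),
    mito = mean(vapply(tg_full, `[[`, numeric(1), "mito")),
    nols_mean = mean(vapply(tg_full, `[[`, numeric(1), "nols_mean"))
  )
  targeting <- lapply(tg_full, function(p) {
    list(
      signal = blend(p$signal, pooled$signal),
      tmd_lambda = blend(p$tmd_lambda, pooled$tmd_lambda),
      mito = blend(p$mito, pooled$mito),
      nols_mean = blend(p$nols_mean, pooled$nols_mean),
      nols_conc = p$nols_conc
    )
  })

  silac_full <- list(
    ENRICHED      = c(x = 3.5, y = 1.2),
    NUCLEOPLASMIC = c(x = 1.2, y = 2.5),
    CYTOPLASMIC   = c(x = 0.5, y = -1.0),
    NON_NUCLEOLAR = c(x = -2.5, y = -0.5)
  )
  silac_mean <- Reduce(`+`, silac_full) / 4
  silac <- lapply(silac_full, function(m) blend(m, silac_mean))

  organisms <- c("Pan_troglodytes", "Mus_musculus", "Rattus_norvegicus",
                 "Danio_rerio", "Drosophila_melanogaster",
                 "Caenorhabditis_elegans", "Saccharomyces_cerevisiae",
                 "Giardia_lamblia")
  orthology <- rbind(
    ENRICHED      = c(0.95, 0.93, 0.92, 0.75, 0.60, 0.50, 0.45, 0.30),
    NUCLEOPLASMIC = c(0.93, 0.90, 0.88, 0.70, 0.55, 0.45, 0.35, 0.20),
    CYTOPLASMIC   = c(0.95, 0.92, 0.91, 0.80, 0.69, 0.60, 0.55, 0.42),
    NON_NUCLEOLAR = c(0.80, 0.76, 0.74, 0.55, 0.30, 0.22, 0.15, 0.08)
  )
  colnames(orthology) <- organisms

  structure(
    list(
      separation = separation, sep_factor = f, seed = as.integer(seed),
      class_sizes = class_sizes, compositions = compositions,
      length_range = c(150L, 500L), targeting = targeting,
      go_pool_size = 12L, go_shared_size = 12L,
      go_own_pool_prob = 0.4 + 0.6 * f, go_terms_range = c(2L, 6L),
      n_tissues = as.integer(n_tissues),
      expression_amplitude = 0.3 + 1.5 * f, expression_noise_sd = 1,
      expression_missing_rate = expression_missing_rate,
      ppi_within = 0.05 + 0.25 * f, ppi_between = 0.03 - 0.025 * f,
      localisation_missing_rate = localisation_missing_rate,
      corruption_rate = corruption_rate,
      silac_means = silac, silac_sd = 0.6,
      organisms = organisms, orthology_probs = orthology
    ),
    class = "nucleo_cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_spec <- function(separation = "high", seed = 42) {
  cohort_spec(separation = separation, seed = seed)
}

#' @export
print.nucleo_cohort_spec <- function(x, ...) {
  cat("<nucleo_cohort_spec> separation = ", x$separation,
      " (factor ", x$sep_factor, "), seed = ", x$seed, "\n", sep = "")
  cat("  class sizes: ", paste(names(x$class_sizes), x$class_sizes,
                               sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# localisation label pools per class (drawn from the default vocabulary)
localisation_pools <- function() {
  list(
    ENRICHED      = c("nucleolus", "nucleolus", "nuclear"),
    NUCLEOPLASMIC = c("nucleoplasm", "nuclear_speckles", "nuclear", "nucleolus"),
    CYTOPLASMIC   = c("cytosol", "cytoplasm", "nucleolus", "nucleolus"),
    NON_NUCLEOLAR = c("cytosol", "cytoplasm", "plasma_membrane",
                      "extracellular", "mitochondrion", "nuclear")
  )
}

#' Simulate a synthetic cohort in memory
#'
#' Draws a complete cohort (sequences plus every annotation table) from a
#' [cohort_spec()]. The same spec always yields the same cohort.
#'
#' @param spec A `nucleo_cohort_spec`.
#' @return A labelled `nucleo_cohort`.
#' @export
simulate_cohort <- function(spec = default_spec()) {
  stopifnot(inherits(spec, "nucleo_cohort_spec"))
  classes <- nucleolar_classes()
  sizes <- spec$class_sizes
  n <- sum(sizes)
  cls <- rep(classes, times = sizes)
  ids <- sprintf("SYN%04d", seq_len(n))

  withr::with_seed(spec$seed, {
    # sequences
    lengths <- sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
    sequences <- vapply(seq_len(n), function(i) {
      comp <- spec$compositions[[cls[i]]]
      paste(sample(names(comp), lengths[i], replace = TRUE, prob = comp),
            collapse = "")
    }, character(1))

    # targeting predictor outputs
    tg <- bind_rows(lapply(seq_len(n), function(i) {
      p <- spec$targeting[[cls[i]]]
      a <- p$nols_mean * p$nols_conc
      b <- (1 - p$nols_mean) * p$nols_conc
      tibble(
        id = ids[i],
        signal_peptide = rbinom(1, 1, p$signal),
        tmd_count = rpois(1, p$tmd_lambda),
        mito_peptide = rbinom(1, 1, p$mito),
        nols_max = round(rbeta(1, a, b), 6)
      )
    }))

    # GO annotations: per-class pools plus a shared pool
    pools <- lapply(classes, function(cl) {
      sprintf("GO:%s%03d", substr(cl, 1, 2), seq_len(spec$go_pool_size))
    })
    names(pools) <- classes
    shared <- sprintf("GO:SH%03d", seq_len(spec$go_shared_size))
    go <- bind_rows(lapply(seq_len(n), function(i) {
      k <- sample(spec$go_terms_range[1]:spec$go_terms_range[2], 1)
      own <- rbinom(k, 1, spec$go_own_pool_prob) == 1
      terms <- character(k)
      terms[own] <- sample(pools[[cls[i]]], sum(own), replace = TRUE)
      terms[!own] <- sample(shared, sum(!own), replace = TRUE)
      tibble(id = ids[i], term_id = unique(terms))
    }))

    # expression: class template + independent Gaussian noise
    templates <- lapply(classes, function(cl) rnorm(spec$n_tissues))
    names(templates) <- classes
    expr_mat <- t(vapply(seq_len(n), function(i) {
      spec$expression_amplitude * templates[[cls[i]]] +
        rnorm(spec$n_tissues, sd = spec$expression_noise_sd)
    }, numeric(spec$n_tissues)))
    expr_keep <- runif(n) >= spec$expression_missing_rate
    expression <- bind_cols(
      tibble(id = ids[expr_keep]),
      as_tibble(round(expr_mat[expr_keep, , drop = FALSE], 6),
                .name_repair = ~ sprintf("tissue_%02d", seq_len(spec$n_tissues)))
    )

    # interactions: Bernoulli edges, denser within classes
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    p_edge <- ifelse(cls[pairs[, 1]] == cls[pairs[, 2]],
                     spec$ppi_within, spec$ppi_between)
    keep_edge <- runif(nrow(pairs)) < p_edge
    ppi <- tibble(id_a = ids[pairs[keep_edge, 1]],
                  id_b = ids[pairs[keep_edge, 2]])

    # localisation annotations with corruption
    loc_pools <- localisation_pools()
    vocab <- localisation_distances()$label
    loc_keep <- runif(n) >= spec$localisation_missing_rate
    localisation <- bind_rows(lapply(which(loc_keep), function(i) {
      k <- sample(1:2, 1)
      labs <- sample(loc_pools[[cls[i]]], k, replace = TRUE)
      corrupt <- runif(k) < spec$corruption_rate
      labs[corrupt] <- sample(vocab, sum(corrupt), replace = TRUE)
      tibble(id = ids[i], label = unique(labs))
    }))

    # SILAC dual ratios (log-normal in log2 space)
    silac <- bind_rows(lapply(seq_len(n), function(i) {
      m <- spec$silac_means[[cls[i]]]
      tibble(
        id = ids[i],
        nuc_cyto_ratio = round(2^rnorm(1, m[["x"]], spec$silac_sd), 6),
        nucpl_cyto_ratio = round(2^rnorm(1, m[["y"]], spec$silac_sd), 6)
      )
    }))

    # orthology
    orthology <- bind_rows(lapply(seq_len(n), function(i) {
      probs <- spec$orthology_probs[cls[i], ]
      has <- runif(length(probs)) < probs
      if (!any(has)) return(NULL)
      tibble(id = ids[i], organism = spec$organisms[has])
    }))

    new_cohort(
      proteins = tibble(id = ids, sequence = sequences),
      targeting = tg, go = go, expression = expression, ppi = ppi,
      localisation = localisation, silac = silac, orthology = orthology,
      labels = tibble(id = ids, class = as_nucleolar_class(cls))
    )
  })
}

#' Write a synthetic cohort to disk
#'
#' Simulates a cohort from the spec and writes it as the plain-text files
#' [load_cohort()] consumes: `proteins.fasta`, `targeting.tsv`, `go.tsv`,
#' `expression.tsv`, `ppi.tsv`, `localisation.tsv`, `silac.tsv`,
#' `orthology.tsv`, `labels.tsv`. Identical specs yield byte-identical
#' files.
#'
#' @param spec A `nucleo_cohort_spec`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
generate_cohort <- function(spec = default_spec(), dir) {
  cohort <- simulate_cohort(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "proteins.fasta"),
    targeting = file.path(dir, "targeting.tsv"),
    go = file.path(dir, "go.tsv"),
    expression = file.path(dir, "expression.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    localisation = file.path(dir, "localisation.tsv"),
    silac = file.path(dir, "silac.tsv"),
    orthology = file.path(dir, "orthology.tsv"),
    labels = file.path(dir, "labels.tsv")
  )
  writeLines(
    paste0(">", cohort$proteins$id, "\n", cohort$proteins$sequence),
    paths[["fasta"]]
  )
  readr::write_tsv(cohort$targeting, paths[["targeting"]], progress = FALSE)
  readr::write_tsv(cohort$go, paths[["go"]], progress = FALSE)
  readr::write_tsv(cohort$expression, paths[["expression"]], progress = FALSE)
  readr::write_tsv(cohort$ppi, paths[["ppi"]], progress = FALSE)
  readr::write_tsv(cohort$localisation, paths[["localisation"]], progress = FALSE)
  readr::write_tsv(cohort$silac, paths[["silac"]], progress = FALSE)
  readr::write_tsv(cohort$orthology, paths[["orthology"]], progress = FALSE)
  labels_out <- mutate(cohort$labels, class = as.character(.data$class))
  readr::write_tsv(labels_out, paths[["labels"]], progress = FALSE)
  invisible(paths)
}
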