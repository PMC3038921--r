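# Small cohorts built in code.

# Every protein shares one amino-acid composition (a scrambled copy of the
# same residue multiset), so the sequence channels are uninformative and the
# GO channel — one private term per class — separates the classes exactly.
# Balanced class sizes keep the uninformative channels neutral: per-bin class
# proportions carry the class frequencies, so a constant channel would
# otherwise vote for the largest class.
go_separable_cohort <- function(n_per_class = c(ENRICHED = 6, NUCLEOPLASMIC = 6,
                                                CYTOPLASMIC = 6, NON_NUCLEOLAR = 6),
                                seed = 1) {
  classes <- rep(names(n_per_class), times = n_per_class)
  n <- length(classes)
  ids <- sprintf("P%03d", seq_len(n))
  base <- strsplit(strrep("ACDEFGHIKLMNPQRSTVWY", 10), "")[[1]]
  seqs <- withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(base), collapse = "")
  }, character(1)))
  terms <- c(ENRICHED = "GO:E001", NUCLEOPLASMIC = "GO:N001",
             CYTOPLASMIC = "GO:C001", NON_NUCLEOLAR = "GO:X001")
  as_cohort(
    proteins = tibble::tibble(id = ids, sequence = seqs),
    go = tibble::tibble(id = ids, term_id = unname(terms[classes])),
    labels = tibble::tibble(id = ids, class = classes)
  )
}

# random conditional-probability-table stack for score oracles
random_model_like <- function(n_channels, n_bins, seed) {
  withr::with_seed(seed, {
    priors <- runif(4, 0.05, 1)
    priors <- priors / sum(priors)
    names(priors) <- nucleolar_classes()
    tables <- lapply(seq_len(n_channels), function(i) {
      m <- matrix(runif(n_bins * 4, 0.01, 1), nrow = n_bins,
                  dimnames = list(0:(n_bins - 1), nucleolar_classes()))
      m / rowSums(m)
    })
    names(tables) <- paste0("ch", seq_len(n_channels))
    structure(list(priors = priors, alpha = 0.1, tables = tables),
              class = "nucleo_model")
  })
}
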