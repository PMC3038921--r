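#' Orthologue-conservation fractions with bootstrap uncertainty
#'
#' For each predicted class and each organism, the fraction of class
#' members with an orthologue in that organism, with a standard deviation
#' estimated by bootstrap resampling of the class members (with
#' replacement, class size preserved; one shared set of resamples per
#' class so organism fractions within a class are computed on the same
#' bootstrap cohorts).
#'
#' @param groups Named list of protein-id vectors, one per class (all
#'   non-empty).
#' @param orthology Tibble `id`, `organism`: one row per (protein,
#'   organism) orthologue relationship.
#' @param organisms Character vector of organisms to report.
#' @param n_boot Number of bootstrap datasets (default 10000).
#' @param seed Integer seed for the bootstrap.
#' @return Tibble `class`, `organism`, `n`, `fraction`, `sd`.
#' @export
conservation_fractions <- function(groups, orthology, organisms,
                                   n_boot = 10000, seed = 1) {
  stopifnot(is.list(groups), length(groups) > 0, n_boot >= 1)
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty) > 0) {
    abort(paste0("Empty class group(s): ", paste(empty, collapse = ", ")))
  }
  orth_by_org <- split(orthology$id, orthology$organism)
  withr::with_seed(as.integer(seed), {
    out <- imap(groups, function(ids, cl) {
      n <- length(ids)
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
      per_org <- lapply(organisms, function(org) {
        has <- ids %in% (orth_by_org[[org]] %||% character(0))
        frac <- mean(has)
        boots <- rowMeans(matrix(has[idx], nrow = n_boot))
        tibble(class = cl, organism = org, n = n, fraction = frac,
               sd = if (n_boot > 1) sd(boots) else 0)
      })
      bind_rows(per_org)
    })
    bind_rows(out)
  })
}
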