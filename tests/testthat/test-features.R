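test_that("amino-acid frequencies are plain residue proportions", {
  f <- aa_frequencies(c("SSSS", "SLIK", "SLIKAAAA"))
  expect_equal(unlist(f[1, ]), c(S = 1, L = 0, I = 0, K = 0))
  expect_equal(unlist(f[2, ]), c(S = 0.25, L = 0.25, I = 0.25, K = 0.25))
  expect_equal(unlist(f[3, ]), c(S = 0.125, L = 0.125, I = 0.125, K = 0.125))
  expect_error(aa_frequencies(""), "non-empty")

  # tracked residues plus complement account for the whole sequence
  withr::with_seed(3, {
    seqs <- vapply(1:10, function(i) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 50,
                   replace = TRUE), collapse = "")
    }, character(1))
  })
  f <- aa_frequencies(seqs)
  other <- vapply(seqs, function(s) {
    mean(!strsplit(s, "")[[1]] %in% c("S", "L", "I", "K"))
  }, numeric(1))
  expect_equal(unname(rowSums(f) + other), rep(1, 10))
})

test_that("discretize uses half-open bins closed above, ties upward", {
  thr <- c(0.05, 0.10, 0.15, 0.20)
  expect_equal(discretize(0.12, thr), 2L)
  expect_equal(discretize(0.0, thr), 0L)
  expect_equal(discretize(0.20, thr), 4L)
  expect_equal(discretize(0.10, thr), 2L)  # tie resolves upward
  expect_equal(discretize(c(NA, 0.3), thr), c(NA_integer_, 4L))
  expect_error(discretize(0.1, c(0.2, 0.1)), "increasing")
})

test_that("equal-frequency thresholds hit quantiles and balance occupancy", {
  thr <- equal_frequency_thresholds(1:100, 4)
  expect_equal(thr, c(25.75, 50.5, 75.25))
  occ <- table(discretize(1:100, thr))
  expect_true(all(abs(occ - 25) <= 5))  # within 20% of uniform

  expect_error(equal_frequency_thresholds(rep(1, 10), 2), "distinct")
  thr2 <- equal_frequency_thresholds(c(1, 2, 3, 4), 2)
  expect_length(thr2, 1)
  expect_equal(as.integer(table(discretize(c(1, 2, 3, 4), thr2))), c(2L, 2L))

  withr::with_seed(11, {
    vals <- rexp(200)
    for (nb in c(3, 4, 5)) {
      th <- equal_frequency_thresholds(vals, nb)
      occ <- tabulate(discretize(vals, th) + 1L, nbins = nb)
      expect_true(all(abs(occ - 200 / nb) <= 0.2 * 200 / nb))
    }
  })
})

test_that("class-error thresholds separate well-clustered channels", {
  withr::with_seed(5, {
    cls <- rep(nucleolar_classes(), times = c(10, 10, 10, 40))
    centers <- c(ENRICHED = 1, NUCLEOPLASMIC = 2, CYTOPLASMIC = 3,
                 NON_NUCLEOLAR = 4.5)
    vals <- rnorm(length(cls), centers[cls], 0.1)
  })
  thr <- class_error_thresholds(vals, cls, n_bins = 5)
  bins <- discretize(vals, thr)
  # each class should sit in bins it dominates
  for (cl in nucleolar_classes()) {
    b <- bins[cls == cl]
    dominant <- as.integer(names(which.max(table(b))))
    others <- bins[cls != cl]
    expect_lt(mean(others == dominant), 0.2)
  }
})

test_that("targeting scores implement the s_M/s_S/s_N/s_C rules", {
  s <- targeting_scores(FALSE, 0, TRUE, 0.5)
  expect_equal(unlist(s), c(s_M = 1L, s_S = 0L, s_N = 0L, s_C = 1L))
  s <- targeting_scores(TRUE, 0, TRUE, 0.95)
  expect_equal(s$s_S, 1L); expect_equal(s$s_N, 2L); expect_equal(s$s_C, 2L)
  s <- targeting_scores(FALSE, 0, FALSE, 0.85)
  expect_equal(s$s_C, 0L); expect_equal(s$s_N, 1L)
  # missing NoLS score means no predicted NoLS
  expect_equal(targeting_scores(FALSE, 0, FALSE, NA)$s_N, 0L)
  expect_error(targeting_scores(FALSE, 0, FALSE, 1.2), "\\[0, 1\\]")

  # s_C invariant over all predictor combinations
  grid <- expand.grid(sp = c(TRUE, FALSE), tmd = 0:2, mito = c(TRUE, FALSE))
  s <- targeting_scores(grid$sp, grid$tmd, grid$mito, rep(0.1, nrow(grid)))
  expect_equal(s$s_C == 2L, s$s_S == 1L)
  expect_equal(s$s_C == 1L, s$s_S == 0L & s$s_M == 1L)
  expect_equal(s$s_C == 0L, s$s_S == 0L & s$s_M == 0L)
})

test_that("targeting bin is a bijection over the 3x3 score grid", {
  grid <- expand.grid(s_C = 0:2, s_N = 0:2)
  bins <- targeting_bin(s_C = grid$s_C, s_N = grid$s_N)
  expect_setequal(bins, 0:8)
  expect_equal(targeting_bin(s_C = 0, s_N = 0), 0L)
  expect_equal(targeting_bin(s_C = 2, s_N = 2), 8L)
})

test_that("co-expression score averages Pearson correlations", {
  q <- c(1, 2, 3, 5, 4)
  expect_equal(coexpression_score(q, list(q)), 1.0)
  expect_equal(coexpression_score(q, list(-q)), -1.0)
  expect_equal(coexpression_score(q, list(q, -q)), 0.0)
  # zero-variance reference skipped; zero-variance query undefined
  expect_equal(coexpression_score(q, list(rep(1, 5), q)), 1.0)
  expect_true(is.na(coexpression_score(rep(2, 5), list(q))))
  expect_error(coexpression_score(q, list(c(1, 2))), "length")
})

test_that("GO scores match the ratio-averaging formula", {
  counts <- list(
    ENRICHED = c("t1" = 2, "t2" = 1),
    NUCLEOPLASMIC = c("t1" = 0),
    CYTOPLASMIC = c("t2" = 5)
  )
  nt <- c("t1" = 10, "t2" = 5)
  one <- go_scores("t1", counts, nt)
  expect_equal(unname(one$g["ENRICHED"]), 0.2)
  two <- go_scores(c("t1", "t2"), counts, nt)
  expect_equal(unname(two$g["ENRICHED"]), (2 / 10 + 1 / 5) / 2)
  expect_equal(two$n_terms, 2L)
  none <- suppressWarnings(go_scores("t9", counts, nt))
  expect_equal(none$n_terms, 0L)
  expect_true(all(is.na(none$g)))
})

test_that("GO bin picks the top class, falls back below threshold, breaks ties", {
  expect_equal(go_bin(c(0.5, 0.1, 0.1)), 0L)
  expect_equal(go_bin(c(0.001, 0.002, 0.0025), go_threshold = 0.003), 3L)
  expect_equal(go_bin(c(0.2, 0.2, 0.1)), 0L)  # precedence tie-break
  expect_equal(go_bin(c(NA, NA, NA)), 3L)
  expect_equal(go_bin(c(0.001, 0.3, 0.2)), 1L)
})

test_that("interactor proximity is the mean compartment distance", {
  expect_equal(interactor_np("nucleolus"), 0.0)
  expect_equal(interactor_np("nuclear"), 0.8)
  expect_equal(interactor_np(c("nucleolus", "cytosol")), 1.5)
  expect_error(interactor_np("atlantis"), "atlantis")
  expect_error(interactor_np(character(0)), "no localisation")
})

test_that("NPI averages partner proximities with exclusions", {
  ppi <- tibble::tibble(id_a = c("P", "P", "P"), id_b = c("A", "B", "P"))
  loc <- tibble::tibble(
    id = c("A", "A", "B"),
    label = c("nucleolus", "nucleolus", "cytosol")
  )
  expect_equal(npi_score("P", ppi, loc), 1.5)  # (0 + 3) / 2, self-loop dropped
  expect_true(is.na(npi_score("P", ppi, loc, excluded_ids = c("A", "B"))))
  expect_true(is.na(npi_score("Q", ppi, loc)))

  one <- tibble::tibble(id_a = "P", id_b = "A")
  expect_true(is.na(npi_score("P", one, loc, excluded_ids = "A")))
})

test_that("NPI equals the brute-force oracle on random graphs", {
  dist_tbl <- localisation_distances()
  withr::with_seed(99, {
    for (k in 1:25) {
      n <- sample(5:30, 1)
      ids <- paste0("N", seq_len(n))
      m <- sample(1:40, 1)
      edges <- tibble::tibble(id_a = sample(ids, m, replace = TRUE),
                              id_b = sample(ids, m, replace = TRUE))
      kk <- sample(2:n, 1)
      loc <- tibble::tibble(
        id = sample(ids, kk, replace = TRUE),
        label = sample(dist_tbl$label, kk, replace = TRUE)
      )
      excl <- sample(ids, sample(0:2, 1))
      q <- sample(ids, 1)
      got <- npi_score(q, edges, loc, excluded_ids = excl)
      want <- oracle_npi(q, edges, loc, excl, dist_tbl)
      if (is.na(want)) expect_true(is.na(got))
      else expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("feature extraction composes channels and flags missing ones", {
  cfg <- binning_config(npi_thresholds = c(0.4, 0.8, 1.6, 2.4))
  bare <- as_cohort(
    proteins = tibble::tibble(id = "P1", sequence = "SLIKSLIKAA"),
    labels = tibble::tibble(id = "P1", class = "ENRICHED")
  )
  f <- extract_features(bare, config = cfg)
  expect_false(anyNA(f[c("aa_S", "aa_L", "aa_I", "aa_K", "targeting")]))
  expect_true(is.na(f$coexpr))
  expect_true(is.na(f$npi))
  expect_equal(f$go, 3L)

  withnpi <- as_cohort(
    proteins = tibble::tibble(id = c("P1", "P2"), sequence = c("SLIK", "MMMM")),
    ppi = tibble::tibble(id_a = "P1", id_b = "P2"),
    localisation = tibble::tibble(id = "P2", label = "nucleolus"),
    labels = tibble::tibble(id = c("P1", "P2"),
                            class = c("ENRICHED", "NON_NUCLEOLAR"))
  )
  f2 <- extract_features(withnpi, config = cfg)
  expect_equal(f2$npi[f2$id == "P1"], 0L)

  f2b <- extract_features(withnpi, config = cfg)
  expect_identical(f2, f2b)
})
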