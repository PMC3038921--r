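write_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}

test_that("load_cohort reads a minimal FASTA-only cohort", {
  fa <- write_lines(c(">P1 some description", "MKKL", ">P2", "ACDE"),
                    withr::local_tempfile(fileext = ".fasta"))
  co <- load_cohort(fa)
  expect_s3_class(co, "nucleo_cohort")
  expect_equal(co$proteins$id, c("P1", "P2"))
  expect_equal(co$proteins$sequence, c("MKKL", "ACDE"))
  expect_null(co$targeting)
  expect_null(co$go)
})

test_that("load_cohort rejects duplicate ids, naming the offender", {
  fa <- write_lines(c(">P1", "MKKL", ">P1", "ACDE"),
                    withr::local_tempfile(fileext = ".fasta"))
  expect_error(load_cohort(fa), "P1")
})

test_that("load_cohort resolves vocabulary labels and rejects unknown ones", {
  fa <- write_lines(c(">P1", "MKKL", ">P2", "ACDE"),
                    withr::local_tempfile(fileext = ".fasta"))
  loc <- write_lines(c("id\tlabel", "P1\tgolgi"),
                     withr::local_tempfile(fileext = ".tsv"))
  co <- load_cohort(fa, localisation = loc)
  # golgi maps to the cytoplasmic group, distance 3.0
  expect_equal(interactor_np(co$localisation$label, co$distances), 3.0)

  bad <- write_lines(c("id\tlabel", "P1\tnot_a_place"),
                     withr::local_tempfile(fileext = ".tsv"))
  expect_error(load_cohort(fa, localisation = bad), "not_a_place")
})

test_that("labelled proteins must be present in the FASTA", {
  fa <- write_lines(c(">P1", "MKKL"), withr::local_tempfile(fileext = ".fasta"))
  lab <- write_lines(c("id\tclass", "P9\tENRICHED"),
                     withr::local_tempfile(fileext = ".tsv"))
  expect_error(load_cohort(fa, labels = lab), "P9")
})

test_that("negative-set sampling is seeded, disjoint and size-checked", {
  pool <- tibble::tibble(id = sprintf("P%03d", 1:300))
  nucleolar <- sprintf("P%03d", 1:50)
  s1 <- sample_non_nucleolar(pool, nucleolar, 200, seed = 1)
  expect_equal(nrow(s1), 200)
  expect_length(intersect(s1$id, nucleolar), 0)
  expect_true(all(s1$class == "NON_NUCLEOLAR"))

  s7a <- sample_non_nucleolar(pool, nucleolar, 200, seed = 7)
  s7b <- sample_non_nucleolar(pool, nucleolar, 200, seed = 7)
  expect_identical(s7a$id, s7b$id)
  expect_false(identical(s1$id, s7a$id))

  small <- tibble::tibble(id = sprintf("P%d", 1:10))
  expect_error(sample_non_nucleolar(small, character(0), 20, seed = 1), "10")
})

test_that("pairwise identity matches hand cases and the alignment oracle", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AATT"), 0.5)
  expect_equal(pairwise_identity("AAAA", "WWWW"), 0.0)

  # enumeration oracle: identity must be achievable by an optimal alignment
  withr::with_seed(42, {
    for (k in 1:20) {
      a <- paste(sample(c("A", "C", "G", "T", "W"), sample(2:5, 1), replace = TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "G", "T", "W"), sample(2:5, 1), replace = TRUE),
                 collapse = "")
      rng <- oracle_identity_range(a, b)
      got <- pairwise_identity(a, b)
      expect_gte(got, rng[1] - 1e-12)
      expect_lte(got, rng[2] + 1e-12)
      expect_equal(got, pairwise_identity(b, a))
    }
  })
})

test_that("non-standard residues never count as identical", {
  expect_equal(pairwise_identity("XXXX", "XXXX"), 0.0)
  expect_equal(pairwise_identity("AXAX", "AXAX"), 0.5)
})

test_that("redundancy filtering is greedy, order-preserving and safe", {
  prot <- tibble::tibble(
    id = c("A", "B", "C"),
    sequence = c("AAAA", "AATT", "TTTT")
  )
  # B matches A at 0.5 (removed); C matches A at 0 (kept despite matching B)
  kept <- redundancy_filter(prot, threshold = 0.25)
  expect_equal(kept$id, c("A", "C"))

  dup <- tibble::tibble(id = c("X", "Y"), sequence = c("MKKL", "MKKL"))
  expect_equal(redundancy_filter(dup)$id, "X")

  # exhaustive recheck: no kept pair at or above threshold
  withr::with_seed(7, {
    seqs <- vapply(1:12, function(i) {
      paste(sample(c("A", "C", "D", "E", "F", "G"), 12, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  tbl <- tibble::tibble(id = paste0("S", 1:12), sequence = seqs)
  out <- redundancy_filter(tbl, threshold = 0.5)
  if (nrow(out) > 1) {
    combs <- utils::combn(nrow(out), 2)
    for (k in seq_len(ncol(combs))) {
      expect_lt(pairwise_identity(out$sequence[combs[1, k]],
                                  out$sequence[combs[2, k]]), 0.5)
    }
  }
  expect_identical(out$id, tbl$id[tbl$id %in% out$id])
})

test_that("GAF input is recognised and reduced to id/term pairs", {
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.1",
    paste("UniProtKB", "P1", "SYM1", "", "GO:0001", "PMID:1", "IDA", "", "P",
          sep = "\t"),
    paste("UniProtKB", "P1", "SYM1", "", "GO:0002", "PMID:1", "IDA", "", "P",
          sep = "\t"),
    paste("UniProtKB", "P2", "SYM2", "", "GO:0001", "PMID:1", "IDA", "", "P",
          sep = "\t")
  ), gaf)
  tbl <- read_go_annotations(gaf)
  expect_equal(nrow(tbl), 3)
  expect_setequal(tbl$term_id[tbl$id == "P1"], c("GO:0001", "GO:0002"))
})
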