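test_that("descendant closure handles leaves, chains and diamonds", {
  chain <- ontology_graph(tibble::tibble(child = c("c", "b"), parent = c("b", "a")))
  expect_equal(descendant_closure(chain, "c"), "c")
  expect_equal(descendant_closure(chain, "a"), c("a", "b", "c"))

  diamond <- ontology_graph(tibble::tibble(
    child = c("c", "c", "b1", "b2"),
    parent = c("b1", "b2", "a", "a")
  ))
  expect_equal(descendant_closure(diamond, "a"), c("a", "b1", "b2", "c"))

  expect_error(descendant_closure(chain, "zz"), "zz")
  expect_error(ontology_graph(tibble::tibble(child = c("a", "b"),
                                             parent = c("b", "a"))), "cyclic")
})

test_that("closure matches a breadth-first oracle on random DAGs", {
  withr::with_seed(31, {
    for (k in 1:20) {
      n <- sample(5:25, 1)
      nodes <- paste0("t", seq_len(n))
      m <- sample(n:(3 * n), 1)
      ii <- sample(n - 1, m, replace = TRUE)
      jj <- ii + vapply(n - ii, function(r) sample(r, 1), integer(1))
      edges <- unique(tibble::tibble(child = nodes[jj], parent = nodes[ii]))
      g <- ontology_graph(edges)
      in_graph <- unique(c(edges$child, edges$parent))
      for (t in sample(in_graph, 3)) {
        expect_equal(descendant_closure(g, t), oracle_closure(edges, t))
      }
    }
  })
})

test_that("the OBO reader follows is_a (and optionally part_of) edges", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0001", "name: root", "",
    "[Term]", "id: GO:0002", "name: mid", "is_a: GO:0001 ! root", "",
    "[Term]", "id: GO:0003", "name: leaf", "is_a: GO:0002 ! mid",
    "relationship: part_of GO:0001 ! root", "",
    "[Term]", "id: GO:0004", "name: gone", "is_obsolete: true",
    "is_a: GO:0001", "",
    "[Typedef]", "id: part_of"
  ), obo)
  g <- ontology_graph(obo)
  expect_setequal(descendant_closure(g, "GO:0001"),
                  c("GO:0001", "GO:0002", "GO:0003"))
  g2 <- ontology_graph(obo, relationships = c("is_a", "part_of"))
  expect_true(igraph::are_adjacent(g2, "GO:0003", "GO:0001"))
})

test_that("term census rolls annotations up and respects the RI cut-off", {
  g <- ontology_graph(tibble::tibble(
    child = c("GO:rrna", "GO:trna", "GO:rna"),
    parent = c("GO:rna", "GO:rna", "GO:meta")
  ))
  preds <- tibble::tibble(
    id = paste0("p", 1:4),
    label = factor(c("ENRICHED", "ENRICHED", "ENRICHED", "CYTOPLASMIC"),
                   levels = nucleolar_classes()),
    reliability_index = c(50, 5, 10, 50)
  )
  ann <- tibble::tibble(
    id = c("p1", "p1", "p2", "p3", "p4"),
    term_id = c("GO:rrna", "GO:trna", "GO:rna", "GO:rna", "GO:rrna")
  )
  cen <- term_census(preds, ann, g, c("GO:rna", "GO:rrna"), min_ri = 10)
  get <- function(cl, t) cen$count[cen$class == cl & cen$term == t]
  # p1 counts once for GO:rna despite two child annotations; p2 fails the
  # cut-off; p3 sits exactly at 10 and is excluded under strict inequality
  expect_equal(get("ENRICHED", "GO:rna"), 1L)
  expect_equal(get("ENRICHED", "GO:rrna"), 1L)
  expect_equal(get("CYTOPLASMIC", "GO:rna"), 1L)

  lax <- term_census(preds, ann, g, "GO:rna", min_ri = 10, strict = FALSE)
  expect_equal(lax$count[lax$class == "ENRICHED"], 2L)

  # invariant to prediction order and duplicated annotation rows
  cen2 <- term_census(preds[4:1, ], dplyr::bind_rows(ann, ann), g,
                      c("GO:rna", "GO:rrna"), min_ri = 10)
  expect_equal(dplyr::arrange(cen, class, term), dplyr::arrange(cen2, class, term))

  expect_error(term_census(preds, ann, g, "GO:nope"), "GO:nope")
})

test_that("conservation fractions and bootstrap dispersion behave", {
  orth <- tibble::tibble(
    id = c("a", "b", "c"),
    organism = rep("Mus_musculus", 3)
  )
  out <- conservation_fractions(list(X = c("a", "b", "c", "d")), orth,
                                "Mus_musculus", n_boot = 200, seed = 4)
  expect_equal(out$fraction, 0.75)
  expect_gt(out$sd, 0)

  full <- conservation_fractions(list(X = c("a", "b", "c")), orth,
                                 "Mus_musculus", n_boot = 200, seed = 4)
  expect_equal(full$fraction, 1.0)
  expect_equal(full$sd, 0)

  expect_error(conservation_fractions(list(X = character(0)), orth,
                                      "Mus_musculus"), "Empty")

  # seeded: identical runs agree
  again <- conservation_fractions(list(X = c("a", "b", "c", "d")), orth,
                                  "Mus_musculus", n_boot = 200, seed = 4)
  expect_identical(out, again)
})

test_that("doubling the bootstrap depth barely moves the estimate", {
  ids <- sprintf("q%03d", 1:100)
  orth <- tibble::tibble(id = ids[1:60], organism = "Danio_rerio")
  a <- conservation_fractions(list(X = ids), orth, "Danio_rerio",
                              n_boot = 4000, seed = 9)
  b <- conservation_fractions(list(X = ids), orth, "Danio_rerio",
                              n_boot = 8000, seed = 10)
  expect_lt(abs(a$sd - b$sd) / b$sd, 0.05)
})
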