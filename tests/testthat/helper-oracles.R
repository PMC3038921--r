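# Independent brute-force oracles, deliberately written without reusing any
# package internals.

# Enumerate every global alignment of a and b; return a data frame of
# (score, identical columns, alignment length) under match 1 / mismatch 0 /
# gap -1. Feasible for short strings only.
oracle_alignments <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  res <- list()
  recurse <- function(i, j, score, ident, len) {
    if (i > length(a) && j > length(b)) {
      res[[length(res) + 1]] <<- c(score = score, ident = ident, len = len)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      m <- a[i] == b[j] && !a[i] %in% c("X", "U", "B")
      recurse(i + 1, j + 1, score + as.numeric(a[i] == b[j]),
              ident + as.numeric(m), len + 1)
    }
    if (i <= length(a)) recurse(i + 1, j, score - 1, ident, len + 1)
    if (j <= length(b)) recurse(i, j + 1, score - 1, ident, len + 1)
  }
  recurse(1, 1, 0, 0, 0)
  do.call(rbind, res)
}

# identities achievable by score-optimal alignments
oracle_identity_range <- function(a, b) {
  al <- oracle_alignments(a, b)
  best <- al[al[, "score"] == max(al[, "score"]), , drop = FALSE]
  range(best[, "ident"] / best[, "len"])
}

# GO score by explicit double loop over terms and classes
oracle_go_scores <- function(terms, class_term_counts, proteome_term_counts) {
  terms <- unique(terms)
  terms <- terms[terms %in% names(proteome_term_counts)]
  out <- c(ENRICHED = NA_real_, NUCLEOPLASMIC = NA_real_, CYTOPLASMIC = NA_real_)
  if (length(terms) == 0) return(list(g = out, n_terms = 0L))
  for (cl in names(out)) {
    total <- 0
    for (t in terms) {
      n_ct <- class_term_counts[[cl]][t]
      if (is.na(n_ct) || is.null(n_ct)) n_ct <- 0
      total <- total + n_ct / proteome_term_counts[[t]]
    }
    out[cl] <- total / length(terms)
  }
  list(g = out, n_terms = length(terms))
}

# NPI by explicit partner/region enumeration
oracle_npi <- function(protein_id, edges, loc_tbl, excluded, dist_tbl) {
  partners <- character(0)
  for (k in seq_len(nrow(edges))) {
    if (edges$id_a[k] == protein_id) partners <- c(partners, edges$id_b[k])
    if (edges$id_b[k] == protein_id) partners <- c(partners, edges$id_a[k])
  }
  partners <- setdiff(unique(partners), c(protein_id, excluded))
  nps <- c()
  for (p in partners) {
    labs <- loc_tbl$label[loc_tbl$id == p]
    if (length(labs) == 0) next
    ds <- vapply(labs, function(l) dist_tbl$distance[dist_tbl$label == l], numeric(1))
    nps <- c(nps, sum(ds) / length(ds))
  }
  if (length(nps) == 0) return(NA_real_)
  sum(nps) / length(nps)
}

# per-class product score by direct loop
oracle_score <- function(priors, tables, bins) {
  classes <- names(priors)
  out <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    s <- priors[[cl]]
    for (ch in names(tables)) {
      b <- bins[[ch]]
      if (!is.na(b)) s <- s * tables[[ch]][b + 1, cl]
    }
    out[cl] <- s
  }
  out
}

# one-vs-rest sensitivity/PPV recomputed from raw label vectors
oracle_class_metrics <- function(truth, predicted) {
  classes <- c("ENRICHED", "NUCLEOPLASMIC", "CYTOPLASMIC", "NON_NUCLEOLAR")
  out <- list()
  for (cl in classes) {
    tp <- sum(truth == cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    fp <- sum(truth != cl & predicted == cl)
    out[[cl]] <- c(
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_
    )
  }
  out
}

# descendant closure by breadth-first search over reversed edges
oracle_closure <- function(edges, term) {
  frontier <- term
  seen <- term
  while (length(frontier) > 0) {
    nxt <- edges$child[edges$parent %in% frontier]
    nxt <- setdiff(unique(nxt), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}
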