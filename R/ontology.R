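#' Build an ontology graph from edges or an OBO file
#'
#' The graph holds directed `child -> parent` edges (`is_a` by default when
#' parsing OBO; `part_of` relationships can be included via
#' `relationships`). Cyclic inputs are rejected.
#'
#' @param x Either a data frame with columns `child`, `parent`, or the path
#'   to an OBO file (minimal parser: `[Term]` stanzas with `id:`, `is_a:`
#'   and `relationship:` lines; obsolete terms skipped).
#' @param relationships Relationship types followed when parsing OBO
#'   (default `"is_a"`; add `"part_of"` to follow part-of edges).
#' @return An `igraph` object (directed, child -> parent).
#' @export
ontology_graph <- function(x, relationships = "is_a") {
  if (is.character(x) && length(x) == 1) {
    edges <- parse_obo_edges(x, relationships)
  } else if (is.data.frame(x)) {
    if (!all(c("child", "parent") %in% names(x))) {
      abort("Edge table needs columns `child` and `parent`.")
    }
    edges <- tibble(child = as.character(x$child), parent = as.character(x$parent))
  } else {
    abort("`x` must be an edge data frame or an OBO file path.")
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) abort("Ontology graph is cyclic; refusing to load.")
  g
}

parse_obo_edges <- function(path, relationships) {
  lines <- readLines(path)
  child <- character(0); parent <- character(0)
  current <- NA_character_
  in_term <- FALSE
  obsolete <- FALSE
  flushable <- list()
  pend_parents <- character(0)
  flush <- function() {
    if (in_term && !obsolete && !is.na(current) && length(pend_parents) > 0) {
      child <<- c(child, rep(current, length(pend_parents)))
      parent <<- c(parent, pend_parents)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE; current <- NA_character_; obsolete <- FALSE
      pend_parents <- character(0)
    } else if (startsWith(ln, "[")) {
      flush(); in_term <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id:")) {
        current <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "is_obsolete: true")) {
        obsolete <- TRUE
      } else if (startsWith(ln, "is_a:") && "is_a" %in% relationships) {
        tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        pend_parents <- c(pend_parents, tgt)
      } else if (startsWith(ln, "relationship:")) {
        parts <- strsplit(trimws(sub("!.*$", "", sub("^relationship:", "", ln))), "\\s+")[[1]]
        if (length(parts) >= 2 && parts[1] %in% relationships) {
          pend_parents <- c(pend_parents, parts[2])
        }
      }
    }
  }
  flush()
  if (length(child) == 0) abort(paste0("No ontology edges parsed from ", path))
  tibble(child = child, parent = parent)
}

#' Descendant closure of an ontology term
#'
#' Returns the term itself plus every term from which it can be reached by
#' following child-to-parent edges, i.e. all of its descendants.
#'
#' @param graph Graph from [ontology_graph()].
#' @param term Term identifier present in the graph.
#' @return Character vector of term ids (the closure; order unspecified).
#' @export
descendant_closure <- function(graph, term) {
  if (!term %in% igraph::V(graph)$name) {
    abort(paste0("Unknown ontology term: ", term))
  }
  reach <- igraph::subcomponent(graph, term, mode = "in")
  sort(igraph::V(graph)$name[reach])
}

#' Census of predicted classes over ontology terms
#'
#' Counts, for each (class, query term) pair, the proteins predicted into
#' that class with a reliability index above `min_ri` that carry at least
#' one annotation in the descendant closure of the term. A protein can
#' count toward several query terms but at most once per term.
#'
#' @param predictions Prediction tibble (`id`, `label`,
#'   `reliability_index`).
#' @param annotations Tibble `id`, `term_id`.
#' @param graph Ontology graph.
#' @param query_terms Character vector of term ids to census.
#' @param min_ri Reliability cut-off (default 10); `strict = TRUE` keeps
#'   RI > min_ri, so proteins at exactly the cut-off are excluded.
#' @param strict Use strict inequality (default `TRUE`).
#' @return Tibble `class`, `term`, `count`.
#' @export
term_census <- function(predictions, annotations, graph, query_terms,
                        min_ri = 10, strict = TRUE) {
  unknown <- setdiff(query_terms, igraph::V(graph)$name)
  if (length(unknown) > 0) {
    abort(paste0("Unknown query term(s): ", paste(unknown, collapse = ", ")))
  }
  keep <- if (strict) predictions$reliability_index > min_ri
          else predictions$reliability_index >= min_ri
  preds <- predictions[keep, , drop = FALSE]
  ann <- distinct(annotations, .data$id, .data$term_id)
  terms_by_id <- split(ann$term_id, ann$id)
  rows <- list()
  for (t in query_terms) {
    closure <- descendant_closure(graph, t)
    hit_ids <- names(terms_by_id)[vapply(terms_by_id, function(tt) any(tt %in% closure), logical(1))]
    hit <- preds[preds$id %in% hit_ids, , drop = FALSE]
    counts <- table(factor(as.character(hit$label), levels = nucleolar_classes()))
    rows[[t]] <- tibble(class = nucleolar_classes(), term = t,
                        count = as.integer(counts))
  }
  bind_rows(rows)
}
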