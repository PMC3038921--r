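#' @title Cohort container and input readers
#' @description A cohort bundles protein sequences with every annotation
#'   table the classifier consumes. All on-disk formats are plain text:
#'   FASTA for sequences and tab-separated tables (header row, `#` comments)
#'   for annotations.
#' @name cohort-io
NULL

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, comment = "#", col_types = col_types, progress = FALSE)
}

#' Read protein sequences from FASTA
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return Tibble with columns `id` and `sequence` (upper case).
#' @export
read_fasta_proteins <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) abort(paste0("Malformed FASTA header (empty id) in ", path))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate protein id(s) in FASTA: ", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) < 1)) {
    abort(paste0("Empty sequence for id(s): ",
                 paste(ids[nchar(seqs) < 1], collapse = ", ")))
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXUB]", seqs)
  if (any(bad)) {
    abort(paste0("Invalid residue letters in sequence(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  tibble(id = ids, sequence = unname(seqs))
}

#' Assemble a cohort from on-disk files
#'
#' Reads a FASTA plus any subset of the annotation tables and bundles them.
#' Annotation rows for proteins absent from the FASTA are retained but
#' reported via a message. Labelled proteins must appear in the FASTA.
#'
#' @param fasta Path to the protein FASTA file.
#' @param targeting,go,expression,ppi,localisation,silac,orthology,labels
#'   Optional paths to the corresponding TSV tables (`NULL` to omit):
#'   `targeting` (id, signal_peptide 0/1, tmd_count, mito_peptide 0/1,
#'   nols_max in \[0,1\] or NA); `go` (id, term_id); `expression` (id, one
#'   column per tissue); `ppi` (id_a, id_b); `localisation` (id, label);
#'   `silac` (id, nuc_cyto_ratio, nucpl_cyto_ratio); `orthology`
#'   (id, organism); `labels` (id, class).
#' @param distances Compartment distance map, see [localisation_distances()].
#' @return An object of class `nucleo_cohort`: a list of tibbles
#'   (`proteins`, `targeting`, `go`, `expression`, `ppi`, `localisation`,
#'   `silac`, `orthology`, `labels`) with `NULL` for absent tables.
#' @export
load_cohort <- function(fasta, targeting = NULL, go = NULL, expression = NULL,
                        ppi = NULL, localisation = NULL, silac = NULL,
                        orthology = NULL, labels = NULL,
                        distances = localisation_distances()) {
  proteins <- read_fasta_proteins(fasta)
  ids <- proteins$id

  flag_unknown <- function(tbl, what, id_cols = "id") {
    unknown <- setdiff(unique(unlist(tbl[id_cols])), ids)
    if (length(unknown) > 0) {
      inform(paste0(what, ": ", length(unknown),
                    " annotation id(s) not in FASTA (retained): ",
                    paste(head(unknown, 5), collapse = ", "),
                    if (length(unknown) > 5) ", ..." else ""))
    }
    tbl
  }

  targeting_tbl <- NULL
  if (!is.null(targeting)) {
    targeting_tbl <- read_tsv_quiet(targeting, readr::cols(
      id = readr::col_character(), signal_peptide = readr::col_integer(),
      tmd_count = readr::col_integer(), mito_peptide = readr::col_integer(),
      nols_max = readr::col_double()
    ))
    if (any(!targeting_tbl$signal_peptide %in% c(0L, 1L)) ||
        any(!targeting_tbl$mito_peptide %in% c(0L, 1L)) ||
        any(targeting_tbl$tmd_count < 0L)) {
      abort("targeting table: signal_peptide/mito_peptide must be 0/1 and tmd_count >= 0.")
    }
    nm <- targeting_tbl$nols_max
    if (any(!is.na(nm) & (nm < 0 | nm > 1))) {
      abort("targeting table: nols_max must lie in [0, 1].")
    }
    if (anyDuplicated(targeting_tbl$id)) abort("targeting table: duplicate protein id.")
    targeting_tbl <- flag_unknown(targeting_tbl, "targeting")
  }

  go_tbl <- NULL
  if (!is.null(go)) {
    go_tbl <- read_go_annotations(go)
    go_tbl <- flag_unknown(go_tbl, "go")
  }

  expr_tbl <- NULL
  if (!is.null(expression)) {
    expr_tbl <- read_tsv_quiet(expression, readr::cols(
      id = readr::col_character(), .default = readr::col_double()
    ))
    if (ncol(expr_tbl) < 4) {
      abort("expression table needs at least 3 tissue columns.")
    }
    if (anyDuplicated(expr_tbl$id)) abort("expression table: duplicate protein id.")
    expr_tbl <- flag_unknown(expr_tbl, "expression")
  }

  ppi_tbl <- NULL
  if (!is.null(ppi)) {
    ppi_tbl <- read_tsv_quiet(ppi, readr::cols(
      id_a = readr::col_character(), id_b = readr::col_character()
    ))
    ppi_tbl <- flag_unknown(ppi_tbl, "ppi", c("id_a", "id_b"))
  }

  loc_tbl <- NULL
  if (!is.null(localisation)) {
    loc_tbl <- read_tsv_quiet(localisation, readr::cols(
      id = readr::col_character(), label = readr::col_character()
    ))
    lookup <- distance_lookup(distances)
    bad <- setdiff(unique(loc_tbl$label), names(lookup))
    if (length(bad) > 0) {
      abort(paste0("Unknown compartment label(s) in localisation table: ",
                   paste(bad, collapse = ", ")))
    }
    loc_tbl <- flag_unknown(loc_tbl, "localisation")
  }

  silac_tbl <- NULL
  if (!is.null(silac)) {
    silac_tbl <- read_tsv_quiet(silac, readr::cols(
      id = readr::col_character(), nuc_cyto_ratio = readr::col_double(),
      nucpl_cyto_ratio = readr::col_double()
    ))
    if (any(silac_tbl$nuc_cyto_ratio <= 0) || any(silac_tbl$nucpl_cyto_ratio <= 0)) {
      abort("silac table: abundance ratios must be > 0.")
    }
    silac_tbl <- flag_unknown(silac_tbl, "silac")
  }

  orth_tbl <- NULL
  if (!is.null(orthology)) {
    orth_tbl <- read_tsv_quiet(orthology, readr::cols(
      id = readr::col_character(), organism = readr::col_character()
    ))
    orth_tbl <- flag_unknown(orth_tbl, "orthology")
  }

  labels_tbl <- NULL
  if (!is.null(labels)) {
    labels_tbl <- read_tsv_quiet(labels, readr::cols(
      id = readr::col_character(), class = readr::col_character()
    ))
    if (anyDuplicated(labels_tbl$id)) {
      abort(paste0("labels table: duplicate protein id(s): ",
                   paste(unique(labels_tbl$id[duplicated(labels_tbl$id)]), collapse = ", ")))
    }
    labels_tbl$class <- as_nucleolar_class(labels_tbl$class)
    missing_seq <- setdiff(labels_tbl$id, ids)
    if (length(missing_seq) > 0) {
      abort(paste0("Labelled protein(s) absent from FASTA: ",
                   paste(missing_seq, collapse = ", ")))
    }
  }

  new_cohort(
    proteins = proteins, targeting = targeting_tbl, go = go_tbl,
    expression = expr_tbl, ppi = ppi_tbl, localisation = loc_tbl,
    silac = silac_tbl, orthology = orth_tbl, labels = labels_tbl,
    distances = distances
  )
}

#' Assemble a cohort from in-memory tables
#'
#' Programmatic counterpart of [load_cohort()] for cohorts built in code
#' (simulations, tests). Only light validation is applied: unique protein
#' ids, labelled proteins present, resolvable compartment labels.
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param targeting,go,expression,ppi,localisation,silac,orthology,labels
#'   Optional annotation tibbles in the shapes documented for
#'   [load_cohort()].
#' @param distances Compartment distance map.
#' @return A `nucleo_cohort`.
#' @export
as_cohort <- function(proteins, targeting = NULL, go = NULL, expression = NULL,
                      ppi = NULL, localisation = NULL, silac = NULL,
                      orthology = NULL, labels = NULL,
                      distances = localisation_distances()) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$id)) abort("Duplicate protein id(s) in `proteins`.")
  if (!is.null(localisation)) {
    lookup <- distance_lookup(distances)
    bad <- setdiff(unique(localisation$label), names(lookup))
    if (length(bad) > 0) {
      abort(paste0("Unknown compartment label(s): ", paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(labels)) {
    labels <- mutate(as_tibble(labels), class = as_nucleolar_class(.data$class))
    missing_seq <- setdiff(labels$id, proteins$id)
    if (length(missing_seq) > 0) {
      abort(paste0("Labelled protein(s) absent from `proteins`: ",
                   paste(missing_seq, collapse = ", ")))
    }
  }
  new_cohort(as_tibble(proteins), targeting, go, expression, ppi, localisation,
             silac, orthology, labels, distances)
}

new_cohort <- function(proteins, targeting = NULL, go = NULL, expression = NULL,
                       ppi = NULL, localisation = NULL, silac = NULL,
                       orthology = NULL, labels = NULL,
                       distances = localisation_distances()) {
  structure(
    list(
      proteins = proteins, targeting = targeting, go = go,
      expression = expression, ppi = ppi, localisation = localisation,
      silac = silac, orthology = orthology, labels = labels,
      distances = distances
    ),
    class = "nucleo_cohort"
  )
}

#' @export
print.nucleo_cohort <- function(x, ...) {
  cat("<nucleo_cohort> ", nrow(x$proteins), " proteins\n", sep = "")
  for (nm in c("targeting", "go", "expression", "ppi", "localisation",
               "silac", "orthology", "labels")) {
    tbl <- x[[nm]]
    cat("  ", format(nm, width = 12),
        if (is.null(tbl)) "absent" else paste0(nrow(tbl), " rows"), "\n", sep = "")
  }
  if (!is.null(x$labels)) {
    tab <- table(x$labels$class)
    cat("  classes: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read GO annotations from a two-column TSV or a GAF 2.x file
#'
#' GAF files are recognised by a `!gaf-version` header line or a `.gaf`
#' extension; columns 2 (object id) and 5 (term id) are used.
#'
#' @param path Path to the annotation file.
#' @return Tibble with columns `id`, `term_id` (distinct rows).
#' @export
read_go_annotations <- function(path) {
  first <- readLines(path, n = 1L)
  is_gaf <- grepl("^!gaf-version", first) || grepl("\\.gaf$", path)
  if (is_gaf) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, integer(1)) < 5
    if (any(short)) abort("Malformed GAF: fewer than 5 columns on some rows.")
    tbl <- tibble(
      id = vapply(fields, `[[`, character(1), 2L),
      term_id = vapply(fields, `[[`, character(1), 5L)
    )
  } else {
    tbl <- read_tsv_quiet(path, readr::cols(
      id = readr::col_character(), term_id = readr::col_character()
    ))
  }
  distinct(tbl, .data$id, .data$term_id)
}
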