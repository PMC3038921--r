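#' Whole-sequence percent identity between two proteins
#'
#' Computes a global (Needleman-Wunsch) alignment of the two sequences with
#' match score 1, mismatch 0 and linear gap penalty -1 (overridable), then
#' returns the fraction of alignment columns in which the two sequences carry
#' the same residue. Non-standard residues (X, U, B) are counted in the
#' alignment length but never as identical matches. The measure is symmetric.
#'
#' @param a,b Amino-acid sequences (non-empty character scalars).
#' @param match,mismatch,gap Alignment scores; `gap` is the (negative) linear
#'   per-column gap score.
#' @return Identity in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("AAAA", "AATT")
pairwise_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  if (!nzchar(a) || !nzchar(b)) abort("Sequences must be non-empty.")
  a <- toupper(a); b <- toupper(b)
  sub <- identity_substitution_matrix(match, mismatch)
  al <- Biostrings::pairwiseAlignment(
    a, b,
    substitutionMatrix = sub, type = "global",
    gapOpening = 0, gapExtension = -gap
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ident <- pa == sa & pa != "-" & !pa %in% c("X", "U", "B")
  sum(ident) / length(pa)
}

identity_substitution_matrix <- function(match, mismatch) {
  aas <- c(Biostrings::AA_STANDARD, "X", "U", "B")
  m <- matrix(mismatch, length(aas), length(aas), dimnames = list(aas, aas))
  diag(m) <- match
  # non-standard residues never score as matches
  for (r in c("X", "U", "B")) m[r, r] <- mismatch
  m
}

#' Remove redundant sequences by greedy identity filtering
#'
#' Sweeps the records in input order, keeping a record only if its whole-
#' sequence identity against every already-kept record is below `threshold`.
#' The greedy keep-first rule is deterministic and preserves input order.
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param threshold Identity threshold; default 0.25 (25 percent).
#' @param ... Passed to [pairwise_identity()].
#' @return The kept rows of `proteins`, input order preserved.
#' @export
redundancy_filter <- function(proteins, threshold = 0.25, ...) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  kept <- integer(0)
  for (i in seq_len(nrow(proteins))) {
    ok <- TRUE
    for (j in kept) {
      if (pairwise_identity(proteins$sequence[i], proteins$sequence[j], ...) >= threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  proteins[kept, , drop = FALSE]
}

#' Sample a non-nucleolar training set
#'
#' Draws `n` proteins uniformly at random (reproducibly, from `seed`) from a
#' pool, excluding any protein annotated as nucleolar, and labels them
#' `NON_NUCLEOLAR`.
#'
#' @param proteins Tibble with at least an `id` column (the candidate pool).
#' @param nucleolar_ids Character vector of ids that must be excluded.
#' @param n Number of proteins to draw.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return Tibble with columns `id`, `class` (all `NON_NUCLEOLAR`).
#' @export
sample_non_nucleolar <- function(proteins, nucleolar_ids, n, seed) {
  stopifnot(is.data.frame(proteins), "id" %in% names(proteins), n >= 1)
  pool <- setdiff(proteins$id, nucleolar_ids)
  if (length(pool) < n) {
    abort(paste0("Insufficient non-nucleolar pool: need ", n,
                 ", have ", length(pool), "."))
  }
  ids <- withr::with_seed(as.integer(seed), sample(pool, n))
  tibble(id = ids, class = as_nucleolar_class(rep("NON_NUCLEOLAR", n)))
}
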