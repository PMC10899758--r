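#' Build a miRNA gene registry from an annotation table
#'
#' The registry defines the gene universe for all downstream analyses. Each row
#' is one miRNA gene (precursor locus) identified by its HUGO symbol, carrying
#' the miRBase precursor identifier, which precursor arm(s) yield the
#' predominantly expressed mature miRNA, and the two validation flags used to
#' select the background list: miRBase "high confidence" designation and
#' MirGeneDB annotation. A gene belongs to the background (the scoring
#' universe) if either flag is set.
#'
#' @param x Path to a tab-separated annotation table with columns
#'   `hugo_id`, `mirbase_precursor_id`, `expressed_arms` (one of `5p`, `3p`,
#'   `both`), `mirbase_high_confidence` and `in_mirgenedb` (booleans coded
#'   `1`/`0`), or a data frame with those columns.
#' @return A data frame of class `cmc_registry` with the input columns plus a
#'   derived logical `is_background`.
#' @examples
#' reg <- load_registry(data.frame(
#'   hugo_id = c("MIR21", "MIR1-1", "MIR1-2"),
#'   mirbase_precursor_id = c("hsa-mir-21", "hsa-mir-1-1", "hsa-mir-1-2"),
#'   expressed_arms = c("5p", "3p", "3p"),
#'   mirbase_high_confidence = c(1, 1, 0),
#'   in_mirgenedb = c(1, 0, 1)
#' ))
#' select_background(reg)
#' @export
load_registry <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- read_tsv_checked(x, registry_columns())
  }
  if (!is.data.frame(x)) {
    stop("`x` must be a file path or a data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(registry_columns(), names(x))
  if (length(missing_cols)) {
    stop("registry table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reg <- as.data.frame(x)[registry_columns()]
  reg$hugo_id <- as.character(reg$hugo_id)
  reg$mirbase_precursor_id <- as.character(reg$mirbase_precursor_id)
  reg$expressed_arms <- as.character(reg$expressed_arms)
  reg$mirbase_high_confidence <- as_flag(reg$mirbase_high_confidence,
                                         "mirbase_high_confidence")
  reg$in_mirgenedb <- as_flag(reg$in_mirgenedb, "in_mirgenedb")

  if (any(!nzchar(reg$hugo_id)) || anyNA(reg$hugo_id)) {
    stop("hugo_id must be non-empty for every row", call. = FALSE)
  }
  dup <- unique(reg$hugo_id[duplicated(reg$hugo_id)])
  if (length(dup)) {
    stop("duplicate hugo_id in registry: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_arm <- setdiff(unique(reg$expressed_arms), c("5p", "3p", "both"))
  if (length(bad_arm)) {
    stop("expressed_arms must be one of '5p', '3p', 'both'; found: ",
         paste(bad_arm, collapse = ", "), call. = FALSE)
  }
  reg$is_background <- reg$mirbase_high_confidence | reg$in_mirgenedb
  class(reg) <- c("cmc_registry", "data.frame")
  reg
}

registry_columns <- function() {
  c("hugo_id", "mirbase_precursor_id", "expressed_arms",
    "mirbase_high_confidence", "in_mirgenedb")
}

as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- suppressWarnings(as.integer(as.character(x)))
  if (anyNA(v) || any(!v %in% c(0L, 1L))) {
    stop(what, " must be boolean (1/0)", call. = FALSE)
  }
  v == 1L
}

#' Select the validated background gene list
#'
#' Background genes are those designated high-confidence in miRBase and/or
#' annotated in MirGeneDB. Only background genes are scored; the remaining
#' universe members are retained solely for overlap statistics.
#'
#' @param registry A `cmc_registry` from [load_registry()].
#' @return Character vector of background `hugo_id`s, sorted lexicographically.
#' @export
select_background <- function(registry) {
  stopifnot(inherits(registry, "cmc_registry"))
  ids <- registry$hugo_id[registry$is_background]
  sort(ids, method = "radix")
}

#' @export
print.cmc_registry <- function(x, ...) {
  cat("miRNA gene registry: ", nrow(x), " genes (",
      sum(x$is_background), " background)\n", sep = "")
  cat("  miRBase high-confidence: ", sum(x$mirbase_high_confidence),
      "; MirGeneDB: ", sum(x$in_mirgenedb), "\n", sep = "")
  invisible(x)
}

#' Enrichment of the overlap between two gene sets in a common universe
#'
#' Quantifies whether two annotation sources agree more than chance expects:
#' the expected overlap under independent draws is
#' `n_set_a * n_set_b / n_universe`, fold enrichment is observed over
#' expected, and the p-value is the upper-tail hypergeometric probability of
#' drawing at least the observed overlap.
#'
#' @param n_universe,n_set_a,n_set_b,n_overlap Non-negative counts; the
#'   overlap must be feasible given the margins.
#' @return A list of class `cmc_overlap` with components `n_universe`,
#'   `n_set_a`, `n_set_b`, `n_overlap`, `expected_overlap`, `fold_enrichment`
#'   and `p_value`.
#' @examples
#' overlap_enrichment(1917, 505, 507, 378)
#' @export
overlap_enrichment <- function(n_universe, n_set_a, n_set_b, n_overlap) {
  counts <- c(n_universe, n_set_a, n_set_b, n_overlap)
  if (anyNA(counts) || any(counts < 0) || any(counts != trunc(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (n_set_a > n_universe || n_set_b > n_universe) {
    stop("set sizes cannot exceed the universe", call. = FALSE)
  }
  lo <- max(0, n_set_a + n_set_b - n_universe)
  hi <- min(n_set_a, n_set_b)
  if (n_overlap < lo || n_overlap > hi) {
    stop("infeasible overlap: ", n_overlap, " not in [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  expected <- n_set_a * n_set_b / n_universe
  fe <- if (expected > 0) n_overlap / expected else NA_real_
  # P(X >= n_overlap), X ~ Hypergeom(universe, set_a, draws = set_b)
  p <- stats::phyper(n_overlap - 1, n_set_a, n_universe - n_set_a, n_set_b,
                     lower.tail = FALSE)
  structure(
    list(n_universe = n_universe, n_set_a = n_set_a, n_set_b = n_set_b,
         n_overlap = n_overlap, expected_overlap = expected,
         fold_enrichment = fe, p_value = p),
    class = "cmc_overlap"
  )
}

#' @export
print.cmc_overlap <- function(x, ...) {
  cat("Set overlap enrichment\n")
  cat(sprintf("  universe %d; |A| = %d, |B| = %d, observed overlap = %d\n",
              x$n_universe, x$n_set_a, x$n_set_b, x$n_overlap))
  cat(sprintf("  expected = %.2f, fold enrichment = %.2f, P = %.3g\n",
              x$expected_overlap, x$fold_enrichment, x$p_value))
  invisible(x)
}
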