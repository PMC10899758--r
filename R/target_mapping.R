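#' Validate a miRNA-target evidence table
#'
#' @param targets Data frame with columns `mirna_id`, `target_symbol`,
#'   `n_methods`, `n_papers`, `n_strong`.
#' @return The validated data frame with uppercased target symbols.
#' @export
validate_targets <- function(targets) {
  required <- c("mirna_id", "target_symbol", "n_methods", "n_papers",
                "n_strong")
  missing_cols <- setdiff(required, names(targets))
  if (length(missing_cols)) {
    stop("target table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  targets <- as.data.frame(targets)
  if (nrow(targets) &&
      (any(targets$n_methods < 1) || any(targets$n_papers < 1) ||
       any(targets$n_strong < 0))) {
    stop("evidence counts out of range: need n_methods >= 1, ",
         "n_papers >= 1, n_strong >= 0", call. = FALSE)
  }
  targets$target_symbol <- toupper(as.character(targets$target_symbol))
  targets
}

#' Select the top-validated targets of one mature miRNA
#'
#' The validation score of a target is `n_methods * n_papers`. Targets are
#' ranked by that score (descending), ties broken by the number of
#' strong-evidence (low-throughput) supports (descending), remaining ties
#' alphabetically by symbol. The first `k` symbols are returned; fewer if
#' fewer are available.
#'
#' @param records Target records sharing one `mirna_id` (see
#'   [validate_targets()]).
#' @param k Maximum number of targets to keep (default 2).
#' @return Character vector of at most `k` target symbols, best first.
#' @examples
#' recs <- data.frame(mirna_id = "miR-21-5p",
#'                    target_symbol = c("A", "B", "C"),
#'                    n_methods = c(2, 3, 1), n_papers = c(3, 2, 5),
#'                    n_strong = c(1, 2, 0))
#' select_top_targets(recs)  # "B" beats "A" on strong evidence
#' @export
select_top_targets <- function(records, k = 2) {
  records <- validate_targets(records)
  if (!nrow(records)) return(character(0))
  if (length(unique(records$mirna_id)) != 1) {
    stop("records must all share one mirna_id", call. = FALSE)
  }
  score <- records$n_methods * records$n_papers
  ord <- order(-score, -records$n_strong, records$target_symbol,
               method = "radix")
  syms <- records$target_symbol[ord]
  utils::head(syms[!duplicated(syms)], k)
}

#' Pool the top targets of census and non-census miRNA genes
#'
#' Each background gene contributes the top-`k` validated targets of the
#' mature miRNA(s) of its expressed arm(s); matching between the registry's
#' expected mature names and the target table's `mirna_id` is exact (after
#' case normalization). Targets of a mature miRNA shared by several genes
#' enter the pool of each gene's group. Pools are unique, sorted symbol sets.
#'
#' @param targets Target evidence table (see [validate_targets()]).
#' @param census A `cmc_census`.
#' @param registry The `cmc_registry` the census was built over.
#' @param k Targets kept per mature miRNA (default 2).
#' @return List of class `cmc_target_pools` with elements `CMC` and
#'   `non_CMC`, each a list `unique_targets` (sorted character vector) and
#'   `n_mirnas` (mature miRNAs that contributed).
#' @export
build_pools <- function(targets, census, registry, k = 2) {
  stopifnot(inherits(census, "cmc_census"), inherits(registry, "cmc_registry"))
  targets <- validate_targets(targets)
  cmc <- census_genes(census)
  background <- registry[registry$is_background, , drop = FALSE]

  top_by_mirna <- if (nrow(targets)) {
    lapply(split(targets, tolower(targets$mirna_id)), select_top_targets,
           k = k)
  } else list()

  pools <- list(CMC = character(0), non_CMC = character(0))
  n_mirnas <- c(CMC = 0L, non_CMC = 0L)
  for (i in seq_len(nrow(background))) {
    gene <- background$hugo_id[i]
    group <- if (gene %in% cmc) "CMC" else "non_CMC"
    matures <- tolower(mature_names_for_gene(
      background$mirbase_precursor_id[i], background$expressed_arms[i]))
    for (m in matures) {
      top <- top_by_mirna[[m]]
      if (is.null(top) || !length(top)) next
      n_mirnas[group] <- n_mirnas[group] + 1L
      pools[[group]] <- c(pools[[group]], top)
    }
  }
  res <- list(
    CMC = list(group = "CMC",
               unique_targets = sort(unique(pools$CMC), method = "radix"),
               n_mirnas = unname(n_mirnas["CMC"])),
    non_CMC = list(group = "non-CMC",
                   unique_targets = sort(unique(pools$non_CMC),
                                         method = "radix"),
                   n_mirnas = unname(n_mirnas["non_CMC"]))
  )
  class(res) <- "cmc_target_pools"
  res
}

#' @export
print.cmc_target_pools <- function(x, ...) {
  cat("Target pools (top-validated targets per mature miRNA)\n")
  cat(sprintf("  CMC:     %4d unique targets from %d mature miRNAs\n",
              length(x$CMC$unique_targets), x$CMC$n_mirnas))
  cat(sprintf("  non-CMC: %4d unique targets from %d mature miRNAs\n",
              length(x$non_CMC$unique_targets), x$non_CMC$n_mirnas))
  invisible(x)
}

#' Overlap of two target pools with a reference gene list
#'
#' Compares the reference-list hit rates of two pools: fold enrichment is the
#' hit rate of pool A over the pooled hit rate of A and B, and the p-value is
#' a two-sided Fisher exact test of the 2x2 hit/miss table. Supply either
#' pools from [build_pools()] / character vectors, or the four counts
#' directly via [pool_overlap_stats()].
#'
#' @param pool_a,pool_b Character vectors of gene symbols (or pool entries
#'   from [build_pools()]).
#' @param reference Character vector of reference gene symbols.
#' @return A one-row data frame of class `cmc_enrichment` (see
#'   [fold_enrichment_test()] for columns).
#' @export
reference_overlap <- function(pool_a, pool_b, reference) {
  grab <- function(p) {
    if (is.list(p) && !is.null(p$unique_targets)) p$unique_targets
    else as.character(p)
  }
  a <- unique(toupper(grab(pool_a)))
  b <- unique(toupper(grab(pool_b)))
  reference <- unique(toupper(as.character(reference)))
  pool_overlap_stats(length(a), sum(a %in% reference),
                     length(b), sum(b %in% reference),
                     set_label = "pool A vs B in reference")
}

#' @rdname reference_overlap
#' @param n_a,hits_a,n_b,hits_b Pool sizes and reference hit counts.
#' @param set_label Label carried into the result row.
#' @export
pool_overlap_stats <- function(n_a, hits_a, n_b, hits_b,
                               set_label = "pool A vs B in reference") {
  stopifnot(hits_a <= n_a, hits_b <= n_b, hits_a >= 0, hits_b >= 0)
  flagged <- n_a == 0 || n_b == 0 || hits_a + hits_b == 0
  if (flagged) {
    fe <- NA_real_
    p <- NA_real_
    expected <- NA_real_
  } else {
    expected <- n_a * (hits_a + hits_b) / (n_a + n_b)
    fe <- (hits_a / n_a) / ((hits_a + hits_b) / (n_a + n_b))
    tab <- matrix(c(hits_a, n_a - hits_a, hits_b, n_b - hits_b),
                  nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
  }
  enrichment_row(set_label = set_label, n_set = n_a, n_in_census = hits_a,
                 expected_in_census = expected, fold_enrichment = fe,
                 p_value = p, flagged = flagged)
}
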