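# Shared constructor for enrichment result rows.
enrichment_row <- function(set_label, n_set, n_in_census,
                           expected_in_census, fold_enrichment, p_value,
                           q_value = NA_real_, flagged = FALSE) {
  out <- data.frame(set_label = set_label, n_set = n_set,
                    n_in_census = n_in_census,
                    expected_in_census = expected_in_census,
                    fold_enrichment = fold_enrichment, p_value = p_value,
                    q_value = q_value, flagged = flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("cmc_enrichment", "data.frame")
  out
}

#' @export
print.cmc_enrichment <- function(x, ...) {
  cat("Fold-enrichment results (Fisher exact, two-sided)\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Fold enrichment of a gene set in the census
#'
#' Observed census members of the set are compared with the expectation under
#' proportional chance, `|set| * |census| / |background|`; significance is a
#' two-sided Fisher exact test on the membership 2x2 table. An empty set or
#' empty census yields a flagged row with undefined statistics.
#'
#' @param gene_set Character vector of `hugo_id`s, a subset of the scored
#'   background.
#' @param census A `cmc_census`.
#' @param set_label Label for the result row.
#' @return One-row `cmc_enrichment` data frame: `set_label`, `n_set`,
#'   `n_in_census`, `expected_in_census`, `fold_enrichment`, `p_value`,
#'   `q_value` (NA until FDR adjustment), `flagged`.
#' @export
fold_enrichment_test <- function(gene_set, census, set_label = "gene set") {
  stopifnot(inherits(census, "cmc_census"))
  gene_set <- unique(gene_set)
  outside <- setdiff(gene_set, census$hugo_id)
  if (length(outside)) {
    stop("gene_set contains genes outside the scored background: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  cmc <- census_genes(census)
  n_bg <- nrow(census)
  n_set <- length(gene_set)
  n_cmc <- length(cmc)
  if (n_set == 0 || n_cmc == 0) {
    return(enrichment_row(set_label, n_set, 0L, NA_real_, NA_real_,
                          NA_real_, flagged = TRUE))
  }
  obs <- sum(gene_set %in% cmc)
  expected <- n_set * n_cmc / n_bg
  tab <- matrix(c(obs, n_set - obs,
                  n_cmc - obs, n_bg - n_set - n_cmc + obs),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  enrichment_row(set_label, n_set, obs, expected, obs / expected, p)
}

criterion_names <- function() c("I", "II", "III", "IV", "V", "VI", "VII")

#' Leave-one-out validation of one scoring criterion
#'
#' The tested criterion is removed from the score (its points zeroed), the
#' census is re-selected at the unchanged threshold, and the genes that
#' scored under the removed criterion in the original scoring are tested for
#' enrichment in the new census. A criterion that scored no genes yields a
#' flagged row.
#'
#' @param profiles A `cmc_profiles` table.
#' @param flags Binary evidence flags.
#' @param config A [score_config()].
#' @param criterion One of `"I"` ... `"VII"`.
#' @return One-row `cmc_enrichment` data frame.
#' @export
leave_one_out <- function(profiles, flags, config = score_config(),
                          criterion) {
  criterion <- match.arg(criterion, criterion_names())
  full <- build_census(profiles, flags, config)
  col <- paste0("pts_", criterion)
  scored <- full$hugo_id[full[[col]] > 0]
  reduced <- full
  reduced[[col]] <- 0
  reduced <- census_from_points(reduced, config)
  if (!length(scored)) {
    return(enrichment_row(paste0("criterion ", criterion), 0L, 0L, NA_real_,
                          NA_real_, NA_real_, flagged = TRUE))
  }
  res <- fold_enrichment_test(scored, reduced,
                              set_label = paste0("criterion ", criterion))
  res
}

#' Graded-score fold enrichment for one criterion
#'
#' After removing the criterion from the score, genes are binned by their
#' remaining score and each bin is tested for enrichment of the genes the
#' removed criterion had scored. With the default half-point-aware bins
#' (0, 1-1.5, 2-2.5, ...) this profiles how the criterion's evidence
#' accumulates across the score range independently of the census threshold.
#'
#' @inheritParams leave_one_out
#' @param breaks Left edges of the score bins (default
#'   `c(0, 1, 2, ..., 7)`, each bin spanning up to the next edge).
#' @return A `cmc_enrichment` data frame, one row per non-degenerate bin;
#'   empty bins are flagged.
#' @export
graded_fe <- function(profiles, flags, config = score_config(), criterion,
                      breaks = 0:7) {
  criterion <- match.arg(criterion, criterion_names())
  full <- build_census(profiles, flags, config)
  col <- paste0("pts_", criterion)
  scored <- full$hugo_id[full[[col]] > 0]
  remaining <- full$cmc_score - full[[col]]
  n_bg <- nrow(full)
  n_scored <- length(scored)
  edges <- c(breaks, Inf)
  rows <- vector("list", length(breaks))
  for (i in seq_along(breaks)) {
    in_bin <- remaining >= edges[i] & remaining < edges[i + 1]
    bin_genes <- full$hugo_id[in_bin]
    label <- if (is.finite(edges[i + 1])) {
      sprintf("score [%g, %g) | criterion %s", edges[i], edges[i + 1],
              criterion)
    } else sprintf("score >= %g | criterion %s", edges[i], criterion)
    n_bin <- length(bin_genes)
    if (n_bin == 0 || n_scored == 0) {
      rows[[i]] <- enrichment_row(label, n_bin, 0L, NA_real_, NA_real_,
                                  NA_real_, flagged = TRUE)
      next
    }
    obs <- sum(bin_genes %in% scored)
    expected <- n_bin * n_scored / n_bg
    tab <- matrix(c(obs, n_bin - obs,
                    n_scored - obs, n_bg - n_bin - n_scored + obs),
                  nrow = 2, byrow = TRUE)
    rows[[i]] <- enrichment_row(label, n_bin, obs, expected, obs / expected,
                                stats::fisher.test(tab)$p.value)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cmc_enrichment", "data.frame")
  out
}

#' Pairwise Spearman correlation of per-gene association counts
#'
#' Rank correlation (average ranks for ties) between the association counts
#' of each database pair, with the large-sample t-approximation p-value. For
#' very small samples (`n <= 8`) an exact permutation p-value can be
#' requested instead. Constant count vectors yield a flagged pair.
#'
#' @param profiles A `cmc_profiles` table.
#' @param exact Use exact permutation p-values (full enumeration; only for
#'   `n <= 8`).
#' @return Data frame with one row per database pair: `db_a`, `db_b`, `rho`,
#'   `p_value`, `flagged`.
#' @export
spearman_matrix <- function(profiles, exact = FALSE) {
  stopifnot(inherits(profiles, "cmc_profiles"))
  dbs <- association_databases()
  pairs <- utils::combn(dbs, 2)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    x <- profiles[[paste0(pairs[1, j], "_n_assoc")]]
    y <- profiles[[paste0(pairs[2, j], "_n_assoc")]]
    rows[[j]] <- c(spearman_test(x, y, exact = exact),
                   list(db_a = pairs[1, j], db_b = pairs[2, j]))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(db_a = r$db_a, db_b = r$db_b, rho = r$rho,
               p_value = r$p_value, flagged = r$flagged,
               stringsAsFactors = FALSE)
  }))
}

spearman_test <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2 || n < 3) {
    return(list(rho = NA_real_, p_value = NA_real_, flagged = TRUE))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (exact) {
    if (n > 8) {
      stop("exact permutation p-value supported only for n <= 8",
           call. = FALSE)
    }
    perms <- permutations_of(n)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(p) stats::cor(rank(x), ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, flagged = FALSE)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Compare group means with a Welch t-test
#'
#' @param values_a,values_b Numeric samples, each of size at least 2.
#' @return List `mean_a`, `mean_b`, `p_value`, `flagged` (`TRUE` with an
#'   undefined p when both samples are essentially constant).
#' @export
compare_group_means <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("both samples must have at least 2 values", call. = FALSE)
  }
  p <- tryCatch(stats::t.test(values_a, values_b)$p.value,
                error = function(e) NA_real_)
  list(mean_a = mean(values_a), mean_b = mean(values_b), p_value = p,
       flagged = is.na(p))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min over j >= i of p_(j) * m / j`,
#' clipped to 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values of the same length.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Term overrepresentation of a gene pool
#'
#' Generic Fisher-exact overrepresentation of pool genes in each term of a
#' term table, against a fixed gene universe: per term, fold enrichment is
#' observed pool genes in the term over `|term| * |pool| / |universe|`, and
#' q-values are Benjamini-Hochberg adjusted over all tested terms. Genes
#' outside the universe are ignored; terms with no universe genes are skipped
#' with a warning.
#'
#' @param pool Character vector of gene symbols (e.g. a target pool).
#' @param term_table Long-format data frame `term_id`, `term_name`,
#'   `gene_symbol`.
#' @param universe Character vector of all eligible gene symbols.
#' @return A `cmc_enrichment` data frame, one row per tested term, ordered by
#'   q-value.
#' @export
term_overrepresentation <- function(pool, term_table, universe) {
  required <- c("term_id", "term_name", "gene_symbol")
  missing_cols <- setdiff(required, names(term_table))
  if (length(missing_cols)) {
    stop("term table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  universe <- unique(toupper(universe))
  pool <- unique(toupper(pool))
  pool <- pool[pool %in% universe]
  n_u <- length(universe)
  n_pool <- length(pool)
  term_table$gene_symbol <- toupper(term_table$gene_symbol)
  terms <- split(term_table$gene_symbol, term_table$term_id)
  term_names <- term_table$term_name[!duplicated(term_table$term_id)]
  names(term_names) <- term_table$term_id[!duplicated(term_table$term_id)]

  rows <- list()
  for (id in names(terms)) {
    tg <- unique(terms[[id]])
    tg <- tg[tg %in% universe]
    if (!length(tg)) {
      warning("term ", id, " has no genes in the universe; skipped",
              call. = FALSE)
      next
    }
    obs <- sum(pool %in% tg)
    expected <- length(tg) * n_pool / n_u
    tab <- matrix(c(obs, n_pool - obs,
                    length(tg) - obs, n_u - n_pool - length(tg) + obs),
                  nrow = 2, byrow = TRUE)
    rows[[id]] <- enrichment_row(
      paste0(id, " ", term_names[[id]]), length(tg), obs, expected,
      if (expected > 0) obs / expected else NA_real_,
      stats::fisher.test(tab)$p.value)
  }
  if (!length(rows)) {
    out <- enrichment_row("none", 0L, 0L, NA_real_, NA_real_, NA_real_)
    return(out[0, , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$q_value, out$p_value, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cmc_enrichment", "data.frame")
  out
}
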