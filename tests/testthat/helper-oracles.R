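# Independent brute-force oracles. These deliberately avoid the code paths
# (and the closed-form distributions) used by the package.

# P(overlap >= k) when a fixed K-element set and a uniformly drawn n-element
# set share a universe of size N: enumerated over all C(N, n) draws.
enum_hypergeom_upper <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# Two-sided Fisher exact p for a 2x2 table: enumerate all tables with the
# observed margins, sum the probabilities of tables no more likely than the
# observed one. Probabilities via products of binomial coefficients only.
enum_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  obs <- prob[xs == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Rank points by explicit optimistic ranking: a gene's rank is 1 + the number
# of genes with a strictly larger count ("ranked upwards"), and it scores at
# a level iff that rank clears the level's ceiling cutoff and its count is
# positive.
oracle_rank_points <- function(counts, frac_full = 0.10, frac_half = 0.25) {
  n <- length(counts)
  cut_full <- ceiling(frac_full * n)
  cut_half <- ceiling(frac_half * n)
  pts <- numeric(n)
  for (i in seq_len(n)) {
    if (counts[i] <= 0) next
    rank_i <- 1 + sum(counts > counts[i])
    if (rank_i <= cut_full) pts[i] <- 1
    else if (rank_i <= cut_half) pts[i] <- 0.5
  }
  stats::setNames(pts, names(counts))
}

# Per-record accumulation of association profiles, one record at a time.
oracle_profiles <- function(records, registry, genes) {
  dbs <- c("miRCancer", "dbDEMC", "oncomiRDB")
  counters <- c("n_assoc", "n_pos", "n_neg", "n_undet")
  prof <- matrix(0L, nrow = length(genes),
                 ncol = length(dbs) * length(counters),
                 dimnames = list(genes, as.vector(outer(dbs, counters,
                                                        paste, sep = "_"))))
  for (r in seq_len(nrow(records))) {
    hits <- suppressWarnings(
      map_mirna_to_genes(records$mirna_id[r], registry))
    db <- records$database[r]
    cat_col <- switch(records$direction[r],
                      up = , oncogenic = "n_pos",
                      down = , suppressive = "n_neg",
                      "n_undet")
    for (g in intersect(hits, genes)) {
      prof[g, paste0(db, "_n_assoc")] <- prof[g, paste0(db, "_n_assoc")] + 1L
      prof[g, paste0(db, "_", cat_col)] <-
        prof[g, paste0(db, "_", cat_col)] + 1L
    }
  }
  prof
}

# Benjamini-Hochberg step-up by the textbook loop.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(p[o][i:m] * m / (i:m), 1))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Small registry builder used across tests.
make_registry <- function(hugo, precursor, arms = "5p", high = 1,
                          mirgene = 1) {
  load_registry(data.frame(
    hugo_id = hugo, mirbase_precursor_id = precursor,
    expressed_arms = rep_len(arms, length(hugo)),
    mirbase_high_confidence = rep_len(high, length(hugo)),
    in_mirgenedb = rep_len(mirgene, length(hugo)),
    stringsAsFactors = FALSE))
}

# Empty flags table (no binary evidence).
no_flags <- function(genes = character(0)) {
  data.frame(hugo_id = genes,
             hallmark = integer(length(genes)),
             kegg_mir_cancer = integer(length(genes)),
             genetic_evidence = integer(length(genes)),
             stringsAsFactors = FALSE)
}

# Profiles table built directly from per-database direction tallies.
make_profiles <- function(hugo, ...) {
  tallies <- list(...)
  prof <- data.frame(hugo_id = hugo, stringsAsFactors = FALSE)
  for (db in c("miRCancer", "dbDEMC", "oncomiRDB")) {
    for (suf in c("n_pos", "n_neg", "n_undet")) {
      col <- paste0(db, "_", suf)
      prof[[col]] <- if (!is.null(tallies[[col]])) tallies[[col]]
                     else integer(length(hugo))
    }
    prof[[paste0(db, "_n_assoc")]] <- prof[[paste0(db, "_n_pos")]] +
      prof[[paste0(db, "_n_neg")]] + prof[[paste0(db, "_n_undet")]]
  }
  class(prof) <- c("cmc_profiles", "data.frame")
  prof
}
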