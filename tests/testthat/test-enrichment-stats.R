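census_with <- function(n_bg, cmc_ids) {
  genes <- sprintf("G%03d", seq_len(n_bg))
  pts <- data.frame(hugo_id = genes, pts_I = 0, pts_II = 0, pts_III = 0,
                    pts_IV = 0, pts_V = ifelse(genes %in% cmc_ids, 1, 0),
                    pts_VI = ifelse(genes %in% cmc_ids, 1, 0), pts_VII = 0)
  census_from_points(pts)
}

test_that("fold enrichment follows the observed/expected ratio", {
  cen <- census_with(634, sprintf("G%03d", 1:165))
  # 100-gene set, 44 in census: FE = 44 / (100 * 165 / 634)
  set_genes <- sprintf("G%03d", c(1:44, 200:255))
  res <- fold_enrichment_test(set_genes, cen)
  expect_equal(res$fold_enrichment, 44 / (100 * 165 / 634))
  expect_equal(round(res$fold_enrichment, 2), 1.69)

  # the census itself is maximally enriched
  self <- fold_enrichment_test(census_genes(cen), cen)
  expect_equal(self$fold_enrichment, 634 / 165)

  expect_true(fold_enrichment_test(character(0), cen)$flagged)
  expect_error(fold_enrichment_test("NOT_A_GENE", cen), "outside")
})

test_that("random sets concentrate near FE = 1", {
  cen <- census_with(300, sprintf("G%03d", 1:90))
  set.seed(31)
  fes <- replicate(1000, {
    fold_enrichment_test(sample(cen$hugo_id, 60), cen)$fold_enrichment
  })
  expect_equal(mean(fes), 1, tolerance = 0.02)
  expect_lt(stats::sd(fes), 0.25)
})

test_that("fisher p on small tables matches exhaustive enumeration", {
  set.seed(13)
  for (rep in 1:40) {
    cells <- as.vector(stats::rmultinom(1, sample(6:25, 1), rep(1, 4)))
    tab <- matrix(cells, 2)
    p_pkg <- stats::fisher.test(tab)$p.value
    expect_equal(p_pkg, enum_fisher_two_sided(cells[1], cells[3], cells[2],
                                              cells[4]),
                 tolerance = 1e-9, info = paste(cells, collapse = ","))
  }
})

sim_profiles_flags <- function(seed, latent_driven = TRUE) {
  # small scoring universe where all criteria share (or do not share) a
  # latent cancer label
  set.seed(seed)
  n <- 200
  genes <- sprintf("G%03d", 1:n)
  latent <- c(rep(TRUE, 50), rep(FALSE, 150))
  boost <- function(on) ifelse(on, 8, 1)
  driver_I <- if (latent_driven) latent else sample(latent)
  driver_II <- if (latent_driven) latent else sample(latent)
  driver_III <- if (latent_driven) latent else sample(latent)
  driver_bin <- if (latent_driven) list(latent, latent, latent)
                else list(sample(latent), sample(latent), sample(latent))
  prof <- make_profiles(
    genes,
    miRCancer_n_pos = rpois(n, 3 * boost(driver_I)),
    dbDEMC_n_pos = rpois(n, 8 * boost(driver_II)),
    oncomiRDB_n_pos = rpois(n, 1.5 * boost(driver_III)))
  flags <- data.frame(
    hugo_id = genes,
    hallmark = as.integer(ifelse(driver_bin[[1]], runif(n) < 0.8,
                                 runif(n) < 0.05)),
    kegg_mir_cancer = as.integer(ifelse(driver_bin[[2]], runif(n) < 0.7,
                                        runif(n) < 0.05)),
    genetic_evidence = as.integer(ifelse(driver_bin[[3]], runif(n) < 0.2,
                                         FALSE)))
  list(profiles = prof, flags = flags, latent = latent)
}

test_that("leave-one-out enrichment recovers latent-label-driven criteria", {
  fx <- sim_profiles_flags(101, latent_driven = TRUE)
  for (cr in c("I", "II", "V", "VI")) {
    res <- leave_one_out(fx$profiles, fx$flags, criterion = cr)
    expect_false(res$flagged)
    expect_gt(res$fold_enrichment, 1.5)
  }
})

test_that("leave-one-out of an independent criterion hovers near FE = 1", {
  fes <- vapply(1:8, function(s) {
    fx <- sim_profiles_flags(200 + s, latent_driven = FALSE)
    leave_one_out(fx$profiles, fx$flags, criterion = "V")$fold_enrichment
  }, numeric(1))
  expect_equal(mean(fes), 1, tolerance = 0.35)
})

test_that("leave-one-out of an unscored criterion returns the flagged contract", {
  fx <- sim_profiles_flags(77)
  fx$flags$genetic_evidence <- 0L
  res <- leave_one_out(fx$profiles, fx$flags, criterion = "VII")
  expect_true(res$flagged)
  expect_true(is.na(res$fold_enrichment))
})

test_that("graded enrichment is flat for a whole-range bin and rises with score", {
  fx <- sim_profiles_flags(55, latent_driven = TRUE)
  whole <- graded_fe(fx$profiles, fx$flags, criterion = "V", breaks = 0)
  expect_equal(whole$fold_enrichment, 1)

  graded <- graded_fe(fx$profiles, fx$flags, criterion = "V")
  defined <- graded[!graded$flagged, ]
  # zero-point genes are depleted; the top defined bin is enriched
  expect_lt(defined$fold_enrichment[1], 1)
  expect_gt(defined$fold_enrichment[nrow(defined)], 1)
})

test_that("spearman matrix reports tie-aware rho and the t-approximation p", {
  prof <- make_profiles(sprintf("G%d", 1:8),
                        miRCancer_n_pos = c(3, 3, 5, 7, 0, 0, 2, 9),
                        dbDEMC_n_pos = c(2, 4, 4, 9, 1, 0, 2, 11),
                        oncomiRDB_n_pos = c(9, 7, 5, 3, 8, 6, 4, 1))
  res <- spearman_matrix(prof)
  x <- c(3, 3, 5, 7, 0, 0, 2, 9); y <- c(2, 4, 4, 9, 1, 0, 2, 11)
  # tie-corrected rho: Pearson correlation of average ranks
  rx <- rank(x); ry <- rank(y)
  rho_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$rho[res$db_a == "miRCancer" & res$db_b == "dbDEMC"],
               rho_hand, tolerance = 1e-12)
  t_hand <- rho_hand * sqrt(6 / (1 - rho_hand^2))
  expect_equal(res$p_value[1], 2 * stats::pt(abs(t_hand), 6,
                                             lower.tail = FALSE),
               tolerance = 1e-12)

  ident <- make_profiles(sprintf("G%d", 1:6),
                         miRCancer_n_pos = 1:6, dbDEMC_n_pos = 1:6,
                         oncomiRDB_n_pos = 6:1)
  ri <- spearman_matrix(ident)
  expect_equal(ri$rho[ri$db_a == "miRCancer" & ri$db_b == "dbDEMC"], 1)
  expect_equal(ri$rho[ri$db_a == "miRCancer" & ri$db_b == "oncomiRDB"], -1)

  const <- make_profiles(sprintf("G%d", 1:6), miRCancer_n_pos = rep(2, 6),
                         dbDEMC_n_pos = 1:6, oncomiRDB_n_pos = 1:6)
  rc <- spearman_matrix(const)
  expect_true(rc$flagged[rc$db_a == "miRCancer" & rc$db_b == "dbDEMC"])

  # exact permutation option agrees with cor.test's exact p when tie-free
  xs <- c(1, 4, 2, 8, 5); ys <- c(2, 3, 1, 9, 4)
  pkg <- cmcensus:::spearman_test(xs, ys, exact = TRUE)
  ref <- stats::cor.test(xs, ys, method = "spearman", exact = TRUE)
  expect_equal(pkg$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("group-mean comparison uses Welch and survives degenerate variance", {
  same <- compare_group_means(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$mean_a, same$mean_b)
  expect_equal(same$p_value, 1)

  degen <- compare_group_means(c(0, 0, 0, 0), c(10, 10, 10, 10))
  expect_true(degen$flagged)

  expect_error(compare_group_means(1, c(1, 2)), "at least 2")

  set.seed(91)
  a <- rnorm(50, 0); b <- rnorm(50, 0.8)
  w <- compare_group_means(a, b)
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  perm <- replicate(1e4, {
    idx <- sample(100, 50)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  expect_equal(w$p_value, mean(perm >= obs), tolerance = 0.02)
})

test_that("BH q-values match the hand oracle and preserve monotonicity", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")

  set.seed(17)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))^2
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
  }
})

test_that("term overrepresentation equals a per-term 2x2 oracle with BH q", {
  set.seed(29)
  universe <- sprintf("U%03d", 1:200)
  pool <- sample(universe, 40)
  term_table <- do.call(rbind, lapply(1:20, function(t) {
    data.frame(term_id = sprintf("T%02d", t), term_name = "random term",
               gene_symbol = sample(universe, sample(5:30, 1)),
               stringsAsFactors = FALSE)
  }))
  res <- term_overrepresentation(pool, term_table, universe)
  expect_equal(nrow(res), 20)
  ps <- numeric(20); fes <- numeric(20)
  for (t in 1:20) {
    tg <- unique(term_table$gene_symbol[term_table$term_id ==
                                          sprintf("T%02d", t)])
    a <- sum(pool %in% tg)
    fes[t] <- a / (length(tg) * length(pool) / 200)
    ps[t] <- enum_fisher_two_sided(a, length(pool) - a, length(tg) - a,
                                   200 - length(pool) - length(tg) + a)
  }
  ord <- match(substr(res$set_label, 1, 3), sprintf("T%02d", 1:20))
  expect_equal(res$p_value, ps[ord], tolerance = 1e-9)
  expect_equal(res$fold_enrichment, fes[ord], tolerance = 1e-12)
  expect_equal(res$q_value, oracle_bh(ps)[ord], tolerance = 1e-12)

  # perfect and zero overlap extremes
  exact <- term_overrepresentation(
    pool, data.frame(term_id = "T1", term_name = "pool itself",
                     gene_symbol = pool), universe)
  expect_equal(exact$fold_enrichment, 200 / 40)
  disjoint <- term_overrepresentation(
    pool, data.frame(term_id = "T1", term_name = "elsewhere",
                     gene_symbol = setdiff(universe, pool)[1:30]), universe)
  expect_equal(disjoint$fold_enrichment, 0)
  expect_warning(
    term_overrepresentation(pool, data.frame(term_id = "T1",
                                             term_name = "alien",
                                             gene_symbol = "XXX"),
                            universe),
    "no genes in the universe")
})
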