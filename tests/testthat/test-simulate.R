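# Small configurations keep the suite fast; paper-scale behavior is covered
# by the recovery checks in test-acceptance.R.
small_config <- function(seed, ...) {
  sim_config(n_genes = 120, n_universe = 360, seed = seed, ...)
}

test_that("simulation is a deterministic function of the seed", {
  s1 <- simulate_cmc_data(small_config(42))
  s2 <- simulate_cmc_data(small_config(42))
  expect_identical(s1$registry, s2$registry)
  expect_identical(s1$associations, s2$associations)
  expect_identical(s1$flags, s2$flags)
  expect_identical(s1$targets, s2$targets)
  s3 <- simulate_cmc_data(small_config(43))
  expect_false(identical(s1$associations, s3$associations))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(999)
  before <- runif(3)
  set.seed(999)
  invisible(runif(1))
  invisible(simulate_universe(small_config(1)))
  after <- runif(2)
  expect_identical(before[2:3], after)
})

test_that("universe counts and ground truth respect the configuration", {
  cfg <- small_config(7)
  uni <- simulate_universe(cfg)
  expect_equal(nrow(uni$registry), 360)
  expect_equal(sum(uni$registry$is_background), 120)
  n_latent <- sum(uni$truth$latent_cancer)
  expect_equal(n_latent, round(0.26 * 120))
  expect_true(all(uni$truth$hugo_id[uni$truth$latent_cancer] %in%
                    select_background(uni$registry)))
  # sign defined exactly on latent genes
  expect_equal(is.na(uni$truth$latent_sign), !uni$truth$latent_cancer)

  none <- simulate_universe(small_config(7, cancer_fraction = 0))
  expect_equal(sum(none$truth$latent_cancer), 0)
})

test_that("association records use valid schemas and exercise mapping rules", {
  cfg <- small_config(11)
  uni <- simulate_universe(cfg)
  assoc <- simulate_associations(cfg, uni)
  expect_true(all(assoc$database %in%
                    c("miRCancer", "dbDEMC", "oncomiRDB")))
  expect_true(any(grepl("-(5p|3p)$", assoc$mirna_id)))
  expect_true(any(!grepl("-(5p|3p)$", assoc$mirna_id)))
  # shared-mature names from duplicated loci are present
  fam_bases <- unique(sub("-[0-9]+$", "",
                          grep("-mir-[0-9]+-[0-9]+$",
                               uni$registry$mirbase_precursor_id,
                               value = TRUE)))
  expect_gt(length(fam_bases), 0)
  # every emitted name is attributable to at least one registry gene
  prof <- build_profiles(assoc, uni$registry)
  expect_equal(sum(prof$miRCancer_n_assoc > 0) > 0, TRUE)
  expect_equal(nrow(prof), 120)
})

test_that("correlation calibration lands in band and collapses when disabled", {
  rhos <- unlist(lapply(1:5, function(s) {
    cfg <- small_config(300 + s)
    sim <- simulate_cmc_data(cfg)
    prof <- build_profiles(sim$associations, sim$registry)
    spearman_matrix(prof)$rho
  }))
  expect_true(all(rhos > 0.70) && all(rhos < 0.95))
  expect_equal(mean(rhos), 0.85, tolerance = 0.05)

  cfg0 <- small_config(301, count_correlation = 0, cancer_fraction = 0)
  sim0 <- simulate_cmc_data(cfg0)
  prof0 <- build_profiles(sim0$associations, sim0$registry)
  expect_true(all(abs(spearman_matrix(prof0)$rho) < 0.25))
})

test_that("forced direction consistency fires criterion IV for eligible genes", {
  cfg <- small_config(21, direction_consistency = 1, cancer_fraction = 1,
                      npa_fraction = 0, undet_fraction = 0)
  sim <- simulate_cmc_data(cfg)
  prof <- build_profiles(sim$associations, sim$registry)
  pts <- consistency_point(prof)
  in_all_three <- prof$miRCancer_n_pos + prof$miRCancer_n_neg > 0 &
    prof$dbDEMC_n_pos + prof$dbDEMC_n_neg > 0 &
    prof$oncomiRDB_n_pos + prof$oncomiRDB_n_neg > 0
  # duplicated loci can mix the signs of two different genes; restrict the
  # forced-consistency claim to genes with a private mature name
  shared <- grepl("-[0-9]+$", prof$hugo_id)
  expect_true(all(pts[in_all_three & !shared] == 1))
  expect_true(all(pts[!in_all_three] == 0))
})

test_that("auxiliary tables track the ground truth rates", {
  hall_latent <- numeric(0); hall_bg <- numeric(0); genetic <- integer(0)
  for (s in 1:20) {
    cfg <- small_config(400 + s)
    uni <- simulate_universe(cfg)
    aux <- simulate_auxiliary(cfg, uni)
    latent <- uni$truth$latent_cancer[match(aux$flags$hugo_id,
                                            uni$truth$hugo_id)]
    hall_latent <- c(hall_latent, mean(aux$flags$hallmark[latent]))
    hall_bg <- c(hall_bg, mean(aux$flags$hallmark[!latent]))
    genetic <- c(genetic, sum(aux$flags$genetic_evidence))
  }
  expect_equal(mean(hall_latent), 0.85, tolerance = 0.04)
  expect_lt(mean(hall_bg), 0.10)
  expect_true(all(genetic == 7))

  # null model: no latent genes, flags fire at the background rate only
  cfg0 <- small_config(444, cancer_fraction = 0)
  uni0 <- simulate_universe(cfg0)
  aux0 <- simulate_auxiliary(cfg0, uni0)
  expect_lt(mean(aux0$flags$hallmark), 0.15)
  sig0 <- aux0$tcga_directions$p_nominal < 1e-4
  expect_lt(mean(sig0), 0.25)
})

test_that("tcga table passes its own validator and matches latent signs", {
  cfg <- small_config(33)
  uni <- simulate_universe(cfg)
  aux <- simulate_auxiliary(cfg, uni)
  expect_silent(validate_tcga_directions(aux$tcga_directions))
  tt <- aux$tcga_directions
  sig <- tt[tt$p_nominal < 1e-4, ]
  lat <- uni$truth[uni$truth$latent_cancer, ]
  sig_lat <- sig[sig$hugo_id %in% lat$hugo_id, ]
  want_up <- lat$latent_sign[match(sig_lat$hugo_id, lat$hugo_id)] ==
    "oncogenic"
  agree <- mean((sig_lat$sign == "increased") == want_up)
  expect_gt(agree, 0.8)
})

test_that("a seed is mandatory and configuration bounds are enforced", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(n_genes = 100, n_universe = 50, seed = 1))
  expect_error(sim_config(cancer_fraction = 1.2, seed = 1))
})
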