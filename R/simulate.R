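# Run `code` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All generator randomness flows through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the census construction: a
#' 1917-gene annotation universe with 634 validated background genes, about a
#' quarter of which carry a latent cancer label (165/634 = 26% census
#' members), cross-database association counts rank-correlated around 0.85
#' (the observed pairwise range was 0.79-0.88), 90% of a cancer gene's
#' association directions matching its latent sign, and per-database mean
#' association loads proportional to the source databases' sizes (about 9000,
#' 53000 and 2300 associations for the literature-mined, differential
#' expression and curated-function databases respectively).
#'
#' @param n_genes Background genes (default 634).
#' @param n_universe Annotation universe size (default 1917).
#' @param cancer_fraction Fraction of background genes given a latent cancer
#'   label (default 0.26).
#' @param count_correlation Target pairwise rank correlation of per-gene
#'   association counts across databases (default 0.85; realized values form
#'   a band around this).
#' @param direction_consistency Probability that one association of a latent
#'   cancer gene matches the gene's latent sign (default 0.9).
#' @param cancer_effect Multiplier on the association intensity of latent
#'   cancer genes (default 6); this is what makes cancer genes climb the
#'   count rankings.
#' @param db_size_params Per-database list of `mean` (associations per
#'   background gene) and `size` (gamma shape; smaller = heavier tail, more
#'   zeros and more boundary ties in the rank scoring).
#' @param npa_fraction Fraction of curated-database associations with
#'   undetermined direction (NPA; default 0.15).
#' @param undet_fraction Fraction of undetermined directions in the other two
#'   databases (default 0.03).
#' @param family_fraction Fraction of background genes emitted as duplicated
#'   two-copy loci sharing one mature miRNA name (default 0.08), exercising
#'   the multi-gene attribution rule.
#' @param arm_suffix_prob Probability that a single-arm association record
#'   carries an explicit -5p/-3p suffix (default 0.7).
#' @param hallmark_rates,kegg_rates Named `c(latent=, background=)` flag
#'   probabilities for criteria V and VI.
#' @param n_genetic Number of genes given genetic evidence (criterion VII,
#'   default 7), drawn from the latent cancer genes.
#' @param n_cancer_types Number of tumor-versus-normal study types
#'   (default 16).
#' @param tcga_sig_prob Named `c(latent=, background=)` per-type probability
#'   of a significant differential call (defaults 0.48 and 0.14, giving about
#'   7.7 and 2.2 significant types per gene).
#' @param tcga_sign_consistency Probability a latent gene's significant call
#'   matches its latent sign (default 0.92).
#' @param seed Integer seed; mandatory, all outputs are deterministic
#'   functions of the configuration including the seed.
#' @return A list of class `cmc_sim_config`.
#' @export
sim_config <- function(n_genes = 634,
                       n_universe = 1917,
                       cancer_fraction = 0.26,
                       count_correlation = 0.85,
                       direction_consistency = 0.9,
                       cancer_effect = 6,
                       db_size_params = list(
                         miRCancer = list(mean = 14, size = 0.45),
                         dbDEMC = list(mean = 84, size = 0.45),
                         oncomiRDB = list(mean = 3.6, size = 0.55)),
                       npa_fraction = 0.15,
                       undet_fraction = 0.03,
                       family_fraction = 0.08,
                       arm_suffix_prob = 0.7,
                       hallmark_rates = c(latent = 0.85, background = 0.05),
                       kegg_rates = c(latent = 0.75, background = 0.06),
                       n_genetic = 7,
                       n_cancer_types = 16,
                       tcga_sig_prob = c(latent = 0.48, background = 0.14),
                       tcga_sign_consistency = 0.92,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory: simulations must be reproducible",
         call. = FALSE)
  }
  stopifnot(n_genes >= 1, n_genes <= n_universe,
            cancer_fraction >= 0, cancer_fraction <= 1,
            count_correlation >= 0, count_correlation <= 1,
            direction_consistency >= 0, direction_consistency <= 1,
            npa_fraction >= 0, npa_fraction < 1,
            family_fraction >= 0, family_fraction <= 1,
            cancer_effect >= 1,
            identical(sort(names(db_size_params)),
                      sort(association_databases())))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "cmc_sim_config"
  cfg
}

#' Simulate the gene universe and its ground truth
#'
#' Generates `n_universe` miRNA genes with precursor names, expressed arms
#' and annotation flags; exactly `n_genes` of them are background
#' (high-confidence and/or curated, with the two flags overlapping at
#' roughly the observed proportions). A `family_fraction` of background genes
#' come as duplicated two-copy loci whose precursors share a mature name.
#' Latent cancer labels and signs are assigned to background genes at
#' `cancer_fraction`; the ground truth is returned separately and is never
#' consumed by the pipeline.
#'
#' @param config A [sim_config()].
#' @return List with `registry` (a `cmc_registry`) and `truth` (data frame
#'   `hugo_id`, `latent_cancer`, `latent_sign`).
#' @export
simulate_universe <- function(config) {
  stopifnot(inherits(config, "cmc_sim_config"))
  with_seed(config$seed, {
    n_bg <- config$n_genes
    n_fam <- floor(config$family_fraction * n_bg / 2)

    # duplicated loci first (copies -1/-2 of one numbered family), then
    # singletons; numbering is disjoint so names never collide
    fam_ids <- seq_len(n_fam)
    n_single <- config$n_universe - 2 * n_fam
    single_ids <- n_fam + seq_len(n_single)
    hugo <- c(paste0("MIR", rep(fam_ids, each = 2), "-", rep(1:2, n_fam)),
              paste0("MIR", single_ids))
    prec <- c(paste0("hsa-mir-", rep(fam_ids, each = 2), "-",
                     rep(1:2, n_fam)),
              paste0("hsa-mir-", single_ids))
    arms <- c(rep(sample(c("5p", "3p", "both"), n_fam, replace = TRUE,
                         prob = c(0.40, 0.35, 0.25)), each = 2),
              sample(c("5p", "3p", "both"), n_single, replace = TRUE,
                     prob = c(0.40, 0.35, 0.25)))

    # background = all duplicated loci plus the first singletons; the two
    # annotation flags overlap at roughly the observed 378/127/129 split
    is_bg <- c(rep(TRUE, 2 * n_fam),
               rep(c(TRUE, FALSE), c(n_bg - 2 * n_fam,
                                     n_single - (n_bg - 2 * n_fam))))
    flag_cat <- sample(c("both", "a_only", "b_only"), n_bg, replace = TRUE,
                       prob = c(378, 127, 129) / 634)
    high_conf <- rep(FALSE, config$n_universe)
    mirgene <- rep(FALSE, config$n_universe)
    high_conf[is_bg] <- flag_cat %in% c("both", "a_only")
    mirgene[is_bg] <- flag_cat %in% c("both", "b_only")

    registry <- load_registry(data.frame(
      hugo_id = hugo, mirbase_precursor_id = prec, expressed_arms = arms,
      mirbase_high_confidence = as.integer(high_conf),
      in_mirgenedb = as.integer(mirgene), stringsAsFactors = FALSE))

    n_latent <- round(config$cancer_fraction * n_bg)
    latent_idx <- sample(which(is_bg), n_latent)
    latent <- rep(FALSE, config$n_universe)
    latent[latent_idx] <- TRUE
    sign <- rep(NA_character_, config$n_universe)
    sign[latent_idx] <- sample(c("oncogenic", "suppressive"), n_latent,
                               replace = TRUE, prob = c(0.35, 0.65))
    truth <- data.frame(hugo_id = hugo, latent_cancer = latent,
                        latent_sign = sign, stringsAsFactors = FALSE)
    list(registry = registry, truth = truth)
  })
}

#' Simulate association records for the three databases
#'
#' Per-gene association counts arise from an overdispersed (gamma-mixed
#' Poisson) model with a shared latent intensity inducing the cross-database
#' rank correlation; the blend between shared and database-private intensity
#' is calibrated by bisection against `count_correlation` using pre-drawn
#' randomness, so the output is still a deterministic function of the seed.
#' Latent cancer genes have their intensity multiplied by `cancer_effect`.
#' Records are emitted at mature-miRNA granularity: duplicated loci emit the
#' shared unsuffixed name, and single-arm genes carry an explicit arm suffix
#' with probability `arm_suffix_prob`, exercising the gene-attribution rules.
#' Directions follow the gene's latent sign with probability
#' `direction_consistency`; background genes have a weakly preferred random
#' sign. The differential-expression database rows carry the design columns
#' expected by the ingest filter.
#'
#' @param config A [sim_config()].
#' @param universe Result of [simulate_universe()].
#' @return Data frame of association records (columns `database`, `mirna_id`,
#'   `cancer_type`, `direction`, `design`, `organism`, `method_class`).
#' @export
simulate_associations <- function(config, universe) {
  stopifnot(inherits(config, "cmc_sim_config"))
  registry <- universe$registry
  truth <- universe$truth
  bg <- registry$is_background
  n <- sum(bg)
  dbs <- association_databases()

  with_seed(config$seed + 1L, {
    # pre-drawn randomness for the calibration: shared and private gamma
    # intensities and the Poisson quantile draws
    shape <- 0.6
    z <- stats::rgamma(n, shape = shape, rate = shape)
    means <- vapply(dbs, function(d) config$db_size_params[[d]]$mean,
                    numeric(1))
    sizes <- vapply(dbs, function(d) config$db_size_params[[d]]$size,
                    numeric(1))
    e <- sapply(sizes, function(s) stats::rgamma(n, shape = s, rate = s))
    u <- matrix(stats::runif(n * 3), n, 3)
    boost <- ifelse(truth$latent_cancer[bg], config$cancer_effect, 1)

    # blend weight w moves intensity from database-private (w = 0) to fully
    # shared (w = 1); counts are a fixed function of (w, pre-drawn draws)
    counts_for <- function(w) {
      sapply(seq_along(dbs), function(j) {
        intensity <- z^w * e[, j]^(1 - w)
        stats::qpois(u[, j], means[j] * boost * intensity)
      })
    }

    realized_rho <- function(w) {
      cc <- counts_for(w)
      mean(c(stats::cor(cc[, 1], cc[, 2], method = "spearman"),
             stats::cor(cc[, 1], cc[, 3], method = "spearman"),
             stats::cor(cc[, 2], cc[, 3], method = "spearman")))
    }

    if (config$count_correlation <= 0) {
      w <- 0
    } else if (config$count_correlation >= realized_rho(1)) {
      w <- 1
    } else {
      lo <- 0; hi <- 1
      for (it in 1:12) {
        w <- (lo + hi) / 2
        if (realized_rho(w) < config$count_correlation) lo <- w else hi <- w
      }
      w <- (lo + hi) / 2
    }
    counts <- counts_for(w)

    # emitted mature name per gene record; duplicated loci share the base
    base <- precursor_base(registry$mirbase_precursor_id[bg])
    base <- sub("^mir-", "miR-", base)
    arms <- registry$expressed_arms[bg]
    latent <- truth$latent_cancer[bg]
    sign_pos <- ifelse(latent, truth$latent_sign[bg] == "oncogenic",
                       stats::runif(n) < 0.5)
    match_prob <- ifelse(latent, config$direction_consistency, 0.55)
    cancers <- c("breast", "lung", "colorectal", "gastric", "liver",
                 "prostate", "ovarian", "leukemia", "melanoma", "bladder")

    out <- vector("list", 3L)
    for (j in seq_along(dbs)) {
      k <- counts[, j]
      total <- sum(k)
      if (total == 0) {
        out[[j]] <- NULL
        next
      }
      g <- rep.int(seq_len(n), k)
      name <- base[g]
      suffixed <- arms[g] != "both" & stats::runif(total) < config$arm_suffix_prob
      name[suffixed] <- paste0(name[suffixed], "-", arms[g][suffixed])
      pos <- stats::runif(total) < match_prob[g]
      pos <- ifelse(sign_pos[g], pos, !pos)
      undet_frac <- if (dbs[j] == "oncomiRDB") config$npa_fraction
                    else config$undet_fraction
      undet <- stats::runif(total) < undet_frac
      vocab <- if (dbs[j] == "oncomiRDB") c("oncogenic", "suppressive")
               else c("up", "down")
      direction <- ifelse(undet, "undetermined", ifelse(pos, vocab[1],
                                                        vocab[2]))
      df <- data.frame(
        database = dbs[j], mirna_id = name,
        cancer_type = sample(cancers, total, replace = TRUE),
        direction = direction,
        design = "", organism = "", method_class = "",
        stringsAsFactors = FALSE)
      if (dbs[j] == "dbDEMC") {
        df$design <- "cancer vs normal"
        df$organism <- "human"
        df$method_class <- "high-throughput"
      }
      out[[j]] <- df
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    rownames(res) <- NULL
    res
  })
}

#' Simulate the auxiliary evidence tables
#'
#' Emits the binary evidence flags (criteria V-VII), tumor-versus-normal
#' differential-direction calls, target evidence records, a term table and a
#' cancer-gene reference list, all structured around the ground truth:
#' hallmark/pathway flags fire at the `latent` rate for latent cancer genes
#' and at the `background` rate otherwise; exactly `n_genetic` genes receive
#' genetic evidence; significant differential calls are frequent and
#' sign-matched for latent genes and sparse with random signs otherwise;
#' targets of latent cancer genes are drawn preferentially from the
#' reference list; and half the terms are enriched for reference genes.
#'
#' @param config A [sim_config()].
#' @param universe Result of [simulate_universe()].
#' @return List of data frames: `flags`, `tcga_directions`, `targets`,
#'   `term_table`, `reference_genes`.
#' @export
simulate_auxiliary <- function(config, universe) {
  stopifnot(inherits(config, "cmc_sim_config"))
  registry <- universe$registry
  truth <- universe$truth
  bg_idx <- which(registry$is_background)
  genes <- registry$hugo_id[bg_idx]
  n <- length(genes)
  latent <- truth$latent_cancer[bg_idx]
  lsign <- truth$latent_sign[bg_idx]

  with_seed(config$seed + 2L, {
    rate <- function(r) ifelse(latent, r[["latent"]], r[["background"]])
    hall <- stats::runif(n) < rate(config$hallmark_rates)
    kegg <- stats::runif(n) < rate(config$kegg_rates)
    genetic <- rep(FALSE, n)
    pool <- if (any(latent)) which(latent) else seq_len(n)
    genetic[sample(pool, min(config$n_genetic, length(pool)))] <- TRUE
    flags <- data.frame(hugo_id = genes, hallmark = as.integer(hall),
                        kegg_mir_cancer = as.integer(kegg),
                        genetic_evidence = as.integer(genetic),
                        stringsAsFactors = FALSE)

    types <- paste0("TT", sprintf("%02d", seq_len(config$n_cancer_types)))
    sig_p <- rate(config$tcga_sig_prob)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      sig <- stats::runif(config$n_cancer_types) < sig_p[i]
      if (latent[i]) {
        up <- stats::runif(config$n_cancer_types) <
          config$tcga_sign_consistency
        if (lsign[i] == "suppressive") up <- !up
      } else {
        up <- stats::runif(config$n_cancer_types) < 0.5
      }
      p <- ifelse(sig, 10^stats::runif(config$n_cancer_types, -12, -4.05),
                  stats::runif(config$n_cancer_types, 1e-4, 1))
      rows[[i]] <- data.frame(
        hugo_id = genes[i], cancer_type = types,
        sign = ifelse(up, "increased", "decreased"), p_nominal = p,
        stringsAsFactors = FALSE)
    }
    tcga <- do.call(rbind, rows)
    rownames(tcga) <- NULL

    # target evidence: mature miRNAs of latent genes preferentially hit the
    # reference (cancer-driver stand-in) symbol pool
    ref_pool <- sprintf("CG%04d", 1:150)
    gen_pool <- sprintf("TG%04d", 1:1200)
    trows <- list()
    for (i in seq_len(n)) {
      matures <- mature_names_for_gene(
        registry$mirbase_precursor_id[bg_idx[i]],
        registry$expressed_arms[bg_idx[i]])
      for (m in matures) {
        k <- 1L + stats::rpois(1, 3)
        p_ref <- if (latent[i]) 0.55 else 0.08
        from_ref <- stats::runif(k) < p_ref
        syms <- ifelse(from_ref, sample(ref_pool, k, replace = TRUE),
                       sample(gen_pool, k, replace = TRUE))
        syms <- unique(syms)
        trows[[length(trows) + 1L]] <- data.frame(
          mirna_id = m, target_symbol = syms,
          n_methods = 1L + stats::rpois(length(syms), 1.2),
          n_papers = 1L + stats::rpois(length(syms), 2),
          n_strong = stats::rpois(length(syms), 0.8),
          stringsAsFactors = FALSE)
      }
    }
    targets <- do.call(rbind, trows)
    rownames(targets) <- NULL

    # duplicated-locus genes share a mature name; drop duplicated emissions
    targets <- targets[!duplicated(paste(targets$mirna_id,
                                         targets$target_symbol)), ,
                       drop = FALSE]

    term_rows <- list()
    for (t in 1:20) {
      size <- 25 + stats::rpois(1, 10)
      enriched <- t <= 10
      p_ref <- if (enriched) 0.5 else 0.05
      from_ref <- stats::runif(size) < p_ref
      syms <- unique(ifelse(from_ref, sample(ref_pool, size, replace = TRUE),
                            sample(gen_pool, size, replace = TRUE)))
      term_rows[[t]] <- data.frame(
        term_id = sprintf("T%03d", t),
        term_name = if (enriched) sprintf("cancer process %d", t)
                    else sprintf("housekeeping process %d", t),
        gene_symbol = syms, stringsAsFactors = FALSE)
    }
    term_table <- do.call(rbind, term_rows)
    rownames(term_table) <- NULL

    list(flags = flags, tcga_directions = tcga, targets = targets,
         term_table = term_table,
         reference_genes = data.frame(gene_symbol = ref_pool,
                                      stringsAsFactors = FALSE))
  })
}

#' Simulate a complete synthetic data set
#'
#' Convenience wrapper running [simulate_universe()],
#' [simulate_associations()] and [simulate_auxiliary()] under one
#' configuration.
#'
#' @param config A [sim_config()].
#' @return List of class `cmc_sim`: `config`, `registry`, `truth`,
#'   `associations`, `flags`, `tcga_directions`, `targets`, `term_table`,
#'   `reference_genes`.
#' @examples
#' sim <- simulate_cmc_data(sim_config(n_genes = 60, n_universe = 150,
#'                                     seed = 7))
#' sim
#' @export
simulate_cmc_data <- function(config) {
  universe <- simulate_universe(config)
  assoc <- simulate_associations(config, universe)
  aux <- simulate_auxiliary(config, universe)
  res <- c(list(config = config, registry = universe$registry,
                truth = universe$truth, associations = assoc), aux)
  class(res) <- "cmc_sim"
  res
}

#' @export
print.cmc_sim <- function(x, ...) {
  cat("Synthetic census inputs (seed ", x$config$seed, ")\n", sep = "")
  cat("  universe: ", nrow(x$registry), " genes, ",
      sum(x$registry$is_background), " background, ",
      sum(x$truth$latent_cancer), " latent cancer\n", sep = "")
  cat("  associations: ", nrow(x$associations), " records\n", sep = "")
  cat("  targets: ", nrow(x$targets), " records; terms: ",
      length(unique(x$term_table$term_id)), "\n", sep = "")
  invisible(x)
}
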