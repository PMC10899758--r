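# TSV interchange: tab-separated, header row, UTF-8, "." decimal, no quoting.

read_tsv_checked <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  if (!is.null(required_cols)) {
    missing_cols <- setdiff(required_cols, names(df))
    if (length(missing_cols)) {
      stop(path, " is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  df
}

write_tsv_out <- function(df, path, force = FALSE) {
  if (file.exists(path) && !force) {
    stop("output exists (use force = TRUE to overwrite): ", path,
         call. = FALSE)
  }
  df <- as.data.frame(df)
  logicals <- vapply(df, is.logical, logical(1))
  df[logicals] <- lapply(df[logicals], as.integer)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a complete synthetic data set to TSV files
#'
#' Emits the exact schemas the analysis stages consume (`genes.tsv`,
#' `associations.tsv`, `flags.tsv`, `tcga_directions.tsv`, `targets.tsv`,
#' `term_table.tsv`, `reference_genes.tsv`) plus `ground_truth.tsv`, which no
#' analysis stage reads.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param force Overwrite existing outputs.
#' @return Invisibly, the named vector of file paths.
#' @export
cmc_simulate_files <- function(config, outdir, force = FALSE) {
  sim <- simulate_cmc_data(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(genes = "genes.tsv", associations = "associations.tsv",
             flags = "flags.tsv", tcga_directions = "tcga_directions.tsv",
             targets = "targets.tsv", term_table = "term_table.tsv",
             reference_genes = "reference_genes.tsv",
             truth = "ground_truth.tsv")
  tables <- list(genes = as.data.frame(sim$registry)[registry_columns()],
                 associations = sim$associations, flags = sim$flags,
                 tcga_directions = sim$tcga_directions,
                 targets = sim$targets, term_table = sim$term_table,
                 reference_genes = sim$reference_genes, truth = sim$truth)
  paths <- file.path(outdir, files)
  names(paths) <- names(files)
  for (nm in names(files)) write_tsv_out(tables[[nm]], paths[[nm]], force)
  message("simulated data set (seed ", config$seed, ") written to ", outdir)
  invisible(paths)
}

#' Score a data set from its TSV inputs
#'
#' Reads the gene annotation, association and flag tables, builds profiles
#' and the census, writes `census.tsv`, and reports a summary (census size,
#' per-criterion point totals, score distribution) to stderr.
#'
#' @param genes,associations,flags Paths to the input TSVs.
#' @param outdir Output directory.
#' @param config A [score_config()].
#' @param force Overwrite existing outputs.
#' @return The `cmc_census`, invisibly.
#' @export
cmc_score_files <- function(genes, associations, flags, outdir,
                            config = score_config(), force = FALSE) {
  registry <- load_registry(genes)
  assoc <- read_tsv_checked(associations,
                            c("database", "mirna_id", "cancer_type",
                              "direction"))
  flag_tab <- read_tsv_checked(flags, c("hugo_id", "hallmark",
                                        "kegg_mir_cancer",
                                        "genetic_evidence"))
  profiles <- build_profiles(assoc, registry)
  census <- build_census(profiles, flag_tab, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_out(census, file.path(outdir, "census.tsv"), force)
  s <- summary(census)
  message("census: ", s$n_cmc, " of ", s$n_background,
          " background genes at score >= ", s$threshold)
  message("points per criterion: ",
          paste(names(s$points_per_criterion), s$points_per_criterion,
                sep = "=", collapse = ", "))
  invisible(census)
}

#' Run the criterion-validation analyses from TSV inputs
#'
#' Writes `leave_one_out.tsv` (one row per criterion), `graded_fe.tsv` (score
#' bins per criterion) and `spearman.tsv` (the three database pairs).
#'
#' @inheritParams cmc_score_files
#' @return Invisibly, a list with the three result tables.
#' @export
cmc_validate_files <- function(genes, associations, flags, outdir,
                               config = score_config(), force = FALSE) {
  registry <- load_registry(genes)
  assoc <- read_tsv_checked(associations,
                            c("database", "mirna_id", "cancer_type",
                              "direction"))
  flag_tab <- read_tsv_checked(flags, c("hugo_id", "hallmark",
                                        "kegg_mir_cancer",
                                        "genetic_evidence"))
  profiles <- build_profiles(assoc, registry)

  loo <- do.call(rbind, lapply(criterion_names(), function(cr) {
    leave_one_out(profiles, flag_tab, config, cr)
  }))
  graded <- do.call(rbind, lapply(criterion_names(), function(cr) {
    graded_fe(profiles, flag_tab, config, cr)
  }))
  rho <- spearman_matrix(profiles)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_out(loo, file.path(outdir, "leave_one_out.tsv"), force)
  write_tsv_out(graded, file.path(outdir, "graded_fe.tsv"), force)
  write_tsv_out(rho, file.path(outdir, "spearman.tsv"), force)
  message("validation written: ", sum(!loo$flagged),
          " criteria with defined leave-one-out FE")
  invisible(list(leave_one_out = loo, graded_fe = graded, spearman = rho))
}

#' Oncogene/tumor-suppressor classification from TSV inputs
#'
#' @inheritParams cmc_score_files
#' @param tcga Path to the tumor-versus-normal direction table.
#' @return Invisibly, the label table (also written to `onco_ts.tsv`).
#' @export
cmc_classify_files <- function(genes, associations, flags, tcga, outdir,
                               config = score_config(), force = FALSE) {
  registry <- load_registry(genes)
  assoc <- read_tsv_checked(associations,
                            c("database", "mirna_id", "cancer_type",
                              "direction"))
  flag_tab <- read_tsv_checked(flags, c("hugo_id", "hallmark",
                                        "kegg_mir_cancer",
                                        "genetic_evidence"))
  tcga_tab <- read_tsv_checked(tcga, c("hugo_id", "cancer_type", "sign",
                                       "p_nominal"))
  profiles <- build_profiles(assoc, registry)
  census <- build_census(profiles, flag_tab, config)
  labels <- classify_onco_ts(census, profiles, tcga_tab, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_out(labels, file.path(outdir, "onco_ts.tsv"), force)
  message("labels: ", sum(labels$label == "oncogene"), " oncogene, ",
          sum(labels$label == "tumor_suppressor"), " tumor suppressor, ",
          sum(labels$label == "undetermined"), " undetermined")
  invisible(labels)
}

#' Target pooling and reference overlap from TSV inputs
#'
#' @inheritParams cmc_score_files
#' @param targets Path to the target evidence table.
#' @param reference Path to the reference gene list (column `gene_symbol`).
#' @param k Targets kept per mature miRNA.
#' @return Invisibly, a list with the pools and the overlap statistic; the
#'   pools are written to `target_pools.tsv`.
#' @export
cmc_targets_files <- function(genes, associations, flags, targets, reference,
                              outdir, config = score_config(), k = 2,
                              force = FALSE) {
  registry <- load_registry(genes)
  assoc <- read_tsv_checked(associations,
                            c("database", "mirna_id", "cancer_type",
                              "direction"))
  flag_tab <- read_tsv_checked(flags, c("hugo_id", "hallmark",
                                        "kegg_mir_cancer",
                                        "genetic_evidence"))
  target_tab <- read_tsv_checked(targets, c("mirna_id", "target_symbol",
                                            "n_methods", "n_papers",
                                            "n_strong"))
  ref <- read_tsv_checked(reference, "gene_symbol")$gene_symbol
  profiles <- build_profiles(assoc, registry)
  census <- build_census(profiles, flag_tab, config)
  pools <- build_pools(target_tab, census, registry, k = k)
  overlap <- reference_overlap(pools$CMC, pools$non_CMC, ref)
  pool_tab <- data.frame(
    group = rep(c("CMC", "non-CMC"),
                c(length(pools$CMC$unique_targets),
                  length(pools$non_CMC$unique_targets))),
    target_symbol = c(pools$CMC$unique_targets,
                      pools$non_CMC$unique_targets),
    stringsAsFactors = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_out(pool_tab, file.path(outdir, "target_pools.tsv"), force)
  if (nrow(pool_tab) == 0) {
    message("target pools are empty")
  } else {
    message("pools: ", length(pools$CMC$unique_targets), " CMC / ",
            length(pools$non_CMC$unique_targets), " non-CMC targets; ",
            "reference FE = ", signif(overlap$fold_enrichment, 3))
  }
  invisible(list(pools = pools, overlap = overlap))
}

#' Load the packaged published census table
#'
#' The package ships the published census of 165 miRNA genes with their
#' per-criterion points, total scores and oncogene/tumor-suppressor
#' annotations as a plain-TSV fixture. The table can be replayed through the
#' score-summation path with [census_from_points()].
#'
#' @return Data frame with columns `hugo_id`, `pts_I` ... `pts_VII`,
#'   `cmc_score` and `onco_ts` (`O`, `TS` or empty).
#' @examples
#' tab <- load_published_census()
#' replay <- census_from_points(tab)
#' sum(replay$is_cmc)
#' @export
load_published_census <- function() {
  path <- system.file("extdata", "table1_census.tsv", package = "cmcensus",
                      mustWork = TRUE)
  df <- read_tsv_checked(path, c("hugo_id",
                                 paste0("pts_", criterion_names()),
                                 "cmc_score", "onco_ts"))
  df$onco_ts[is.na(df$onco_ts)] <- ""
  df
}
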