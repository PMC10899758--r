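#' Scoring configuration
#'
#' All thresholds and weights of the census score live here so the scheme can
#' be re-weighted without code changes.
#'
#' @param top_fraction_full Fraction of the ranked background list awarded the
#'   full rank point (default 0.10, 1 point).
#' @param top_fraction_half Fraction awarded at least the half point (default
#'   0.25; genes between the two cutoffs get 0.5 points).
#' @param consistency_fraction Minimum fraction of direction-determined
#'   associations sharing one sign for within-database consistency
#'   (default 0.75).
#' @param census_threshold Minimum total score for census membership
#'   (default 2).
#' @param binary_point Points per satisfied binary criterion (default 1).
#' @return A list of class `cmc_score_config`.
#' @export
score_config <- function(top_fraction_full = 0.10,
                         top_fraction_half = 0.25,
                         consistency_fraction = 0.75,
                         census_threshold = 2,
                         binary_point = 1) {
  stopifnot(top_fraction_full > 0,
            top_fraction_full <= top_fraction_half,
            top_fraction_half <= 1,
            consistency_fraction > 0.5, consistency_fraction <= 1,
            census_threshold > 0,
            binary_point > 0)
  structure(list(top_fraction_full = top_fraction_full,
                 top_fraction_half = top_fraction_half,
                 consistency_fraction = consistency_fraction,
                 census_threshold = census_threshold,
                 binary_point = binary_point),
            class = "cmc_score_config")
}

#' Rank-percentile points for one database
#'
#' Genes are ranked by association count, descending. The top
#' `top_fraction_full` of the background list (cutoff rank
#' `ceiling(fraction * N)`) receives 1 point and the remainder of the top
#' `top_fraction_half` receives 0.5 points. A gene with the same count as the
#' gene at a cutoff rank is "ranked upwards", i.e. included at that level, so
#' boundary ties never split. Genes with zero associations never score.
#'
#' @param counts Named numeric vector of association counts, one entry per
#'   background gene (zeros allowed, names are `hugo_id`s).
#' @param config A [score_config()].
#' @return Named numeric vector of points in `{0, 0.5, 1}` aligned to
#'   `counts`.
#' @export
rank_points <- function(counts, config = score_config()) {
  stopifnot(inherits(config, "cmc_score_config"))
  if (is.null(names(counts)) || anyNA(counts)) {
    stop("counts must be a complete named vector over the background genes",
         call. = FALSE)
  }
  n <- length(counts)
  pts <- stats::setNames(numeric(n), names(counts))
  if (n == 0) return(pts)
  cutoff_full <- ceiling(config$top_fraction_full * n)
  cutoff_half <- ceiling(config$top_fraction_half * n)
  sorted <- sort(counts, decreasing = TRUE)
  thr_full <- sorted[cutoff_full]
  thr_half <- sorted[cutoff_half]
  pts[counts > 0 & counts >= thr_half] <- 0.5
  pts[counts > 0 & counts >= thr_full] <- 1
  pts
}

# Within-database direction summary for one profiles table: majority sign and
# whether the consistency fraction is met, per gene and database.
db_direction_summary <- function(profiles, db, consistency_fraction) {
  pos <- profiles[[paste0(db, "_n_pos")]]
  neg <- profiles[[paste0(db, "_n_neg")]]
  determined <- pos + neg
  major <- ifelse(determined == 0, "undetermined",
                  ifelse(pos >= neg, "positive", "negative"))
  met <- determined > 0 & pmax(pos, neg) / pmax(determined, 1) >=
    consistency_fraction
  # an exact 50/50 split can never meet a fraction > 0.5, so the arbitrary
  # pos-first majority above is harmless
  data.frame(majority = major, consistency_met = met,
             determined = determined)
}

#' Direction-consistency point (criterion IV)
#'
#' One point when (a) every database holds at least one direction-determined
#' association for the gene, (b) within each database at least
#' `consistency_fraction` of the determined associations share one sign
#' (up/oncogenic counted as positive, down/suppressive as negative;
#' undetermined entries excluded), and (c) the majority sign agrees across
#' all three databases.
#'
#' @param profiles A `cmc_profiles` table.
#' @param config A [score_config()].
#' @return Named numeric vector of points in `{0, 1}`, one per profile row.
#' @export
consistency_point <- function(profiles, config = score_config()) {
  stopifnot(inherits(profiles, "cmc_profiles"),
            inherits(config, "cmc_score_config"))
  summ <- lapply(association_databases(), db_direction_summary,
                 profiles = profiles,
                 consistency_fraction = config$consistency_fraction)
  present <- Reduce(`&`, lapply(summ, function(s) s$determined > 0))
  met <- Reduce(`&`, lapply(summ, function(s) s$consistency_met))
  same_sign <- summ[[1]]$majority == summ[[2]]$majority &
    summ[[2]]$majority == summ[[3]]$majority
  stats::setNames(as.numeric(present & met & same_sign), profiles$hugo_id)
}

#' Binary evidence points (criteria V-VII)
#'
#' @param flags Data frame with columns `hugo_id`, `hallmark`,
#'   `kegg_mir_cancer`, `genetic_evidence` (booleans). Genes absent from the
#'   table count as `FALSE`.
#' @param genes Character vector of genes to score.
#' @param config A [score_config()].
#' @return Data frame `hugo_id`, `pts_V`, `pts_VI`, `pts_VII`.
#' @export
binary_points <- function(flags, genes, config = score_config()) {
  required <- c("hugo_id", "hallmark", "kegg_mir_cancer", "genetic_evidence")
  missing_cols <- setdiff(required, names(flags))
  if (length(missing_cols)) {
    stop("flags table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  idx <- match(genes, flags$hugo_id)
  pick <- function(col) {
    v <- as_flag(flags[[col]], col)[idx]
    v[is.na(v)] <- FALSE
    as.numeric(v) * config$binary_point
  }
  data.frame(hugo_id = genes,
             pts_V = pick("hallmark"),
             pts_VI = pick("kegg_mir_cancer"),
             pts_VII = pick("genetic_evidence"),
             stringsAsFactors = FALSE)
}

#' Build the cancer miRNA census
#'
#' Assigns criteria I-III rank points from the per-database association
#' counts, the criterion IV consistency point, and the criteria V-VII binary
#' points; sums them into the census score; and classifies genes at the
#' configured threshold. The result covers every profiled (background) gene.
#'
#' @param profiles A `cmc_profiles` table over the background genes.
#' @param flags Binary evidence flags (see [binary_points()]).
#' @param config A [score_config()].
#' @return A data frame of class `cmc_census` with columns `hugo_id`,
#'   `pts_I` ... `pts_VII`, `cmc_score`, `is_cmc`, sorted by decreasing score
#'   then `hugo_id`.
#' @export
build_census <- function(profiles, flags, config = score_config()) {
  stopifnot(inherits(profiles, "cmc_profiles"),
            inherits(config, "cmc_score_config"))
  genes <- profiles$hugo_id
  rank_cols <- c(pts_I = "miRCancer_n_assoc", pts_II = "dbDEMC_n_assoc",
                 pts_III = "oncomiRDB_n_assoc")
  out <- data.frame(hugo_id = genes, stringsAsFactors = FALSE)
  for (crit in names(rank_cols)) {
    counts <- stats::setNames(profiles[[rank_cols[[crit]]]], genes)
    out[[crit]] <- unname(rank_points(counts, config))
  }
  out$pts_IV <- unname(consistency_point(profiles, config))
  out <- cbind(out, binary_points(flags, genes, config)[-1])
  crit_cols <- paste0("pts_", c("I", "II", "III", "IV", "V", "VI", "VII"))
  out$cmc_score <- rowSums(out[crit_cols])
  out$is_cmc <- out$cmc_score >= config$census_threshold
  census_from_points(out, config)
}

#' Assemble a census from per-criterion points
#'
#' The final summation/threshold/ordering step of [build_census()], exposed so
#' a table of pre-assigned points (e.g. a published census table) can be
#' replayed through the same path.
#'
#' @param points Data frame with `hugo_id` and `pts_I` ... `pts_VII`.
#' @param config A [score_config()].
#' @return A `cmc_census` data frame (see [build_census()]).
#' @export
census_from_points <- function(points, config = score_config()) {
  crit_cols <- paste0("pts_", c("I", "II", "III", "IV", "V", "VI", "VII"))
  missing_cols <- setdiff(c("hugo_id", crit_cols), names(points))
  if (length(missing_cols)) {
    stop("points table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(points)[c("hugo_id", crit_cols)]
  out$cmc_score <- rowSums(out[crit_cols])
  out$is_cmc <- out$cmc_score >= config$census_threshold
  out <- out[order(-out$cmc_score, out$hugo_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("cmc_census", "data.frame")
  out
}

#' Census genes
#'
#' @param census A `cmc_census`.
#' @return Character vector of `hugo_id`s classified into the census.
#' @export
census_genes <- function(census) {
  stopifnot(inherits(census, "cmc_census"))
  census$hugo_id[census$is_cmc]
}

#' @export
print.cmc_census <- function(x, n = 10, ...) {
  cat("Cancer miRNA census: ", sum(x$is_cmc), " of ", nrow(x),
      " background genes at score >= ",
      attr(x, "config")$census_threshold, "\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more genes\n", sep = "")
  invisible(x)
}

#' @export
summary.cmc_census <- function(object, ...) {
  crit_cols <- paste0("pts_", c("I", "II", "III", "IV", "V", "VI", "VII"))
  res <- list(
    n_background = nrow(object),
    n_cmc = sum(object$is_cmc),
    threshold = attr(object, "config")$census_threshold,
    points_per_criterion = colSums(object[crit_cols]),
    genes_per_criterion = colSums(object[crit_cols] > 0),
    score_distribution = table(object$cmc_score)
  )
  class(res) <- "summary.cmc_census"
  res
}

#' @export
print.summary.cmc_census <- function(x, ...) {
  cat("Census: ", x$n_cmc, " of ", x$n_background,
      " background genes (threshold >= ", x$threshold, ")\n", sep = "")
  cat("Total points per criterion:\n")
  print(x$points_per_criterion)
  cat("Genes scored per criterion:\n")
  print(x$genes_per_criterion)
  cat("Score distribution:\n")
  print(x$score_distribution)
  invisible(x)
}
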