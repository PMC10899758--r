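#' Validate tumor-versus-normal differential-direction calls
#'
#' @param tcga Data frame with columns `hugo_id`, `cancer_type`, `sign`
#'   (`increased`/`decreased`) and `p_nominal`; at most 16 distinct cancer
#'   types, one row per gene and cancer type.
#' @return The validated data frame.
#' @export
validate_tcga_directions <- function(tcga) {
  required <- c("hugo_id", "cancer_type", "sign", "p_nominal")
  missing_cols <- setdiff(required, names(tcga))
  if (length(missing_cols)) {
    stop("tcga_directions table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tcga <- as.data.frame(tcga)
  bad <- setdiff(unique(tcga$sign), c("increased", "decreased"))
  if (length(bad)) {
    stop("sign must be 'increased' or 'decreased'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(tcga$p_nominal) || any(tcga$p_nominal < 0 | tcga$p_nominal > 1)) {
    stop("p_nominal must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(tcga$hugo_id, tcga$cancer_type)
  if (anyDuplicated(key)) {
    stop("duplicate (hugo_id, cancer_type) rows in tcga_directions",
         call. = FALSE)
  }
  per_gene <- table(tcga$hugo_id)
  if (any(per_gene > 16)) {
    stop("more than 16 cancer-type calls for gene(s): ",
         paste(names(per_gene)[per_gene > 16], collapse = ", "),
         call. = FALSE)
  }
  tcga
}

#' Classify census genes as potential oncogenes or tumor suppressors
#'
#' A census gene is labeled an oncogene when (i) at least two of the three
#' association databases are internally consistent (the criterion-IV >= 75%
#' rule) with positive majority sign, (ii) no database is consistently
#' negative (an inconsistent or absent third database does not block the
#' label), and (iii) among its significant tumor-versus-normal calls
#' (nominal P below `p_cutoff`, at least one required) at least
#' `consistency_fraction` report increased levels. The tumor-suppressor rule
#' is the mirror image (negative majority, decreased levels). Everything else
#' is `undetermined`. Only census members may be classified; requesting a
#' label for a non-census gene is an error.
#'
#' @param census A `cmc_census` from [build_census()].
#' @param profiles The `cmc_profiles` the census was scored from.
#' @param tcga Differential-direction calls (see
#'   [validate_tcga_directions()]).
#' @param config A [score_config()]; supplies `consistency_fraction`.
#' @param genes Genes to classify; defaults to all census members.
#' @param p_cutoff Nominal significance gate on `p_nominal` (default 1e-4).
#' @return Data frame `hugo_id`, `label` with label one of `oncogene`,
#'   `tumor_suppressor`, `undetermined`.
#' @export
classify_onco_ts <- function(census, profiles, tcga,
                             config = score_config(),
                             genes = census_genes(census),
                             p_cutoff = 1e-4) {
  stopifnot(inherits(census, "cmc_census"),
            inherits(profiles, "cmc_profiles"))
  tcga <- validate_tcga_directions(tcga)
  cmc <- census_genes(census)
  outside <- setdiff(genes, cmc)
  if (length(outside)) {
    stop("oncogene/tumor-suppressor labels are defined only for census ",
         "genes; not in census: ", paste(outside, collapse = ", "),
         call. = FALSE)
  }

  summ <- lapply(association_databases(), db_direction_summary,
                 profiles = profiles,
                 consistency_fraction = config$consistency_fraction)
  prow <- match(genes, profiles$hugo_id)
  n_pos_consistent <- Reduce(`+`, lapply(summ, function(s) {
    as.integer(s$consistency_met & s$majority == "positive")[prow]
  }))
  n_neg_consistent <- Reduce(`+`, lapply(summ, function(s) {
    as.integer(s$consistency_met & s$majority == "negative")[prow]
  }))
  n_pos_consistent[is.na(n_pos_consistent)] <- 0L
  n_neg_consistent[is.na(n_neg_consistent)] <- 0L

  sig <- tcga[tcga$p_nominal < p_cutoff, , drop = FALSE]
  n_sig <- as.integer(table(factor(sig$hugo_id, levels = genes)))
  n_inc <- as.integer(table(factor(
    sig$hugo_id[sig$sign == "increased"], levels = genes)))
  frac_inc <- ifelse(n_sig > 0, n_inc / n_sig, NA_real_)

  f <- config$consistency_fraction
  onco <- n_pos_consistent >= 2 & n_neg_consistent == 0 &
    n_sig >= 1 & frac_inc >= f
  ts <- n_neg_consistent >= 2 & n_pos_consistent == 0 &
    n_sig >= 1 & (1 - frac_inc) >= f
  onco[is.na(onco)] <- FALSE
  ts[is.na(ts)] <- FALSE

  data.frame(hugo_id = genes,
             label = ifelse(onco, "oncogene",
                            ifelse(ts, "tumor_suppressor", "undetermined")),
             stringsAsFactors = FALSE)
}

#' Association between O/TS labels and an external sign annotation
#'
#' Cross-tabulates the oncogene/tumor-suppressor labels against a binary
#' per-gene annotation (e.g. the direction of expression change reported
#' elsewhere) on the shared genes and runs a two-sided Fisher exact test.
#' Tables with an empty row or column are returned flagged, with the p-value
#' undefined.
#'
#' @param labels Data frame `hugo_id`, `label` from [classify_onco_ts()];
#'   `undetermined` genes are excluded.
#' @param annotation Data frame `hugo_id`, `sign` with two sign levels
#'   (e.g. `up`/`down`).
#' @return List of class `cmc_assoc_test`: `table`, `odds_ratio`, `p_value`,
#'   `flagged`.
#' @export
association_with_annotations <- function(labels, annotation) {
  stopifnot(all(c("hugo_id", "label") %in% names(labels)),
            all(c("hugo_id", "sign") %in% names(annotation)))
  lab <- labels[labels$label %in% c("oncogene", "tumor_suppressor"), ,
                drop = FALSE]
  shared <- intersect(lab$hugo_id, annotation$hugo_id)
  tab <- table(
    label = factor(lab$label[match(shared, lab$hugo_id)],
                   levels = c("oncogene", "tumor_suppressor")),
    sign = annotation$sign[match(shared, annotation$hugo_id)]
  )
  degenerate <- ncol(tab) != 2 || any(rowSums(tab) == 0) ||
    any(colSums(tab) == 0)
  if (degenerate) {
    res <- list(table = tab, odds_ratio = NA_real_, p_value = NA_real_,
                flagged = TRUE)
  } else {
    ft <- stats::fisher.test(tab)
    res <- list(table = tab, odds_ratio = unname(ft$estimate),
                p_value = ft$p.value, flagged = FALSE)
  }
  class(res) <- "cmc_assoc_test"
  res
}

#' @export
print.cmc_assoc_test <- function(x, ...) {
  cat("Label-annotation association (Fisher exact, two-sided)\n")
  print(x$table)
  if (x$flagged) cat("  degenerate table; p undefined\n")
  else cat(sprintf("  odds ratio = %.3g, P = %.3g\n", x$odds_ratio,
                   x$p_value))
  invisible(x)
}
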