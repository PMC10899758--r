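# Mature-name handling -------------------------------------------------------
#
# Associations and target records refer to mature miRNAs ("miR-125a-5p",
# "miR-1", "let-7a"), while all scoring is done at the gene (precursor) level.
# The mapping rules are:
#   * an arm suffix (-5p/-3p) is ignored for gene attribution: both arms of a
#     precursor accumulate onto the same gene;
#   * a mature name shared by several precursors (miR-1 from MIR1-1 and
#     MIR1-2) is attributed to every one of those genes;
#   * a name without an arm suffix maps to all genes carrying that base name.
#
# The base name of a precursor is its miRBase id without the species prefix
# and, for duplicated loci, without the trailing copy index ("hsa-mir-1-1" ->
# "mir-1"). A trailing "-<digits>" is a copy index only when what precedes it
# still names a miRNA (e.g. "mir-125b-1" -> "mir-125b", but "mir-21" keeps
# its "21").

normalize_mature <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("^hsa-", "", x)
  x <- sub("^microrna-", "mir-", x)
  sub("-(5p|3p)$", "", x)
}

precursor_base <- function(precursor_id) {
  x <- tolower(trimws(precursor_id))
  x <- sub("^hsa-", "", x)
  # strip a copy index: requires a name chunk (digits + optional letters)
  # between the mir/let prefix and the trailing index
  sub("^((?:mir|let)-[0-9]+[a-z]*)-[0-9]+$", "\\1", x)
}

# Expected mature names for one gene given its expressed arm(s); used by the
# target-selection stage, which matches arm-resolved mature ids exactly.
mature_names_for_gene <- function(precursor_id, arms) {
  base <- precursor_base(precursor_id)
  base <- sub("^mir-", "miR-", base)
  switch(arms,
         "5p"   = paste0(base, "-5p"),
         "3p"   = paste0(base, "-3p"),
         "both" = paste0(base, c("-5p", "-3p")),
         stop("unknown arms value: ", arms, call. = FALSE))
}

#' Map a mature miRNA name to the genes that can express it
#'
#' @param mirna_id Mature miRNA identifier, with or without a `-5p`/`-3p`
#'   suffix (e.g. `"miR-1"`, `"miR-125a-5p"`).
#' @param registry A `cmc_registry`.
#' @return Character vector of `hugo_id`s (possibly empty; an unknown name
#'   yields an empty vector with a warning).
#' @examples
#' reg <- load_registry(data.frame(
#'   hugo_id = c("MIR1-1", "MIR1-2", "MIR125A"),
#'   mirbase_precursor_id = c("hsa-mir-1-1", "hsa-mir-1-2", "hsa-mir-125a"),
#'   expressed_arms = c("3p", "3p", "both"),
#'   mirbase_high_confidence = 1, in_mirgenedb = 1
#' ))
#' map_mirna_to_genes("miR-1", reg)       # both MIR1 copies
#' map_mirna_to_genes("miR-125a-5p", reg) # MIR125A
#' @export
map_mirna_to_genes <- function(mirna_id, registry) {
  stopifnot(inherits(registry, "cmc_registry"), length(mirna_id) == 1)
  base <- normalize_mature(mirna_id)
  hits <- registry$hugo_id[precursor_base(registry$mirbase_precursor_id) == base]
  if (!length(hits)) {
    warning("unknown miRNA name skipped: ", mirna_id, call. = FALSE)
  }
  hits
}

association_databases <- function() c("miRCancer", "dbDEMC", "oncomiRDB")

direction_vocabulary <- function(database) {
  if (database == "oncomiRDB") c("oncogenic", "suppressive", "undetermined")
  else c("up", "down", "undetermined")
}

#' Validate and normalize raw association records
#'
#' Checks the database label and per-database direction vocabulary
#' (miRCancer/dbDEMC use up/down, oncomiRDB uses oncogenic/suppressive;
#' `undetermined` stands for directionless entries such as oncomiRDB's NPA),
#' and applies the dbDEMC design filter: only human, cancer-versus-normal,
#' high-throughput records are retained. Dropped rows are reported with a
#' message.
#'
#' @param records Data frame with columns `database`, `mirna_id`,
#'   `cancer_type`, `direction` and (for dbDEMC) `design`, `organism`,
#'   `method_class`.
#' @return The validated, filtered data frame.
#' @export
validate_associations <- function(records) {
  required <- c("database", "mirna_id", "cancer_type", "direction")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("association table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)
  bad_db <- setdiff(unique(records$database), association_databases())
  if (length(bad_db)) {
    stop("unknown database label(s): ", paste(bad_db, collapse = ", "),
         call. = FALSE)
  }
  for (db in association_databases()) {
    dirs <- records$direction[records$database == db]
    bad <- setdiff(unique(dirs), direction_vocabulary(db))
    if (length(bad)) {
      stop("invalid direction(s) for ", db, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  is_demc <- records$database == "dbDEMC"
  if (any(is_demc)) {
    for (col in c("design", "organism", "method_class")) {
      if (is.null(records[[col]])) records[[col]] <- NA_character_
    }
    keep <- !is_demc |
      (records$design == "cancer vs normal" &
         records$organism == "human" &
         records$method_class == "high-throughput")
    keep[is.na(keep)] <- FALSE
    n_drop <- sum(!keep)
    if (n_drop > 0) {
      message("dropped ", n_drop,
              " dbDEMC record(s) outside the cancer-vs-normal/human/",
              "high-throughput design")
      records <- records[keep, , drop = FALSE]
    }
  }
  records
}

#' Accumulate association records into per-gene profiles
#'
#' Every record increments the counters of every gene its mature miRNA maps
#' to, within its source database: `n_assoc` always, and one of `n_pos`
#' (up/oncogenic), `n_neg` (down/suppressive) or `n_undet`. Genes with no
#' records keep all-zero profiles, so the result always covers the requested
#' gene set.
#'
#' @param records Association records (validated with
#'   [validate_associations()]; raw records are validated on the fly).
#' @param registry A `cmc_registry`.
#' @param background_only Restrict profiles to background genes (default);
#'   otherwise all registry genes are profiled.
#' @return A data frame of class `cmc_profiles`: `hugo_id` plus, per database,
#'   `<db>_n_assoc`, `<db>_n_pos`, `<db>_n_neg`, `<db>_n_undet`.
#' @export
build_profiles <- function(records, registry, background_only = TRUE) {
  stopifnot(inherits(registry, "cmc_registry"))
  records <- validate_associations(records)

  genes <- if (background_only) select_background(registry)
           else sort(registry$hugo_id, method = "radix")
  prof <- data.frame(hugo_id = genes, stringsAsFactors = FALSE)
  for (db in association_databases()) {
    for (suf in c("n_assoc", "n_pos", "n_neg", "n_undet")) {
      prof[[paste0(db, "_", suf)]] <- 0L
    }
  }

  if (nrow(records)) {
    # vectorized mapping: one lookup per distinct mature name
    reg_base <- precursor_base(registry$mirbase_precursor_id)
    uniq <- unique(records$mirna_id)
    hit_list <- lapply(normalize_mature(uniq),
                       function(b) registry$hugo_id[reg_base == b])
    names(hit_list) <- uniq
    n_unknown <- sum(lengths(hit_list) == 0)
    if (n_unknown > 0) {
      warning(n_unknown, " miRNA name(s) not found in the registry; ",
              "their records were skipped", call. = FALSE)
    }
    per_record <- hit_list[records$mirna_id]
    idx <- rep.int(seq_len(nrow(records)), lengths(per_record))
    gene <- unlist(per_record, use.names = FALSE)
    db <- records$database[idx]
    dircat <- ifelse(records$direction[idx] %in% c("up", "oncogenic"), "n_pos",
              ifelse(records$direction[idx] %in% c("down", "suppressive"),
                     "n_neg", "n_undet"))
    keep <- gene %in% genes
    gene <- gene[keep]; db <- db[keep]; dircat <- dircat[keep]
    if (length(gene)) {
      row <- match(gene, prof$hugo_id)
      for (d in association_databases()) {
        sel <- db == d
        if (!any(sel)) next
        tot <- table(row[sel])
        col <- paste0(d, "_n_assoc")
        prof[[col]][as.integer(names(tot))] <-
          prof[[col]][as.integer(names(tot))] + as.integer(tot)
        for (cc in c("n_pos", "n_neg", "n_undet")) {
          sel2 <- sel & dircat == cc
          if (!any(sel2)) next
          tt <- table(row[sel2])
          col2 <- paste0(d, "_", cc)
          prof[[col2]][as.integer(names(tt))] <-
            prof[[col2]][as.integer(names(tt))] + as.integer(tt)
        }
      }
    }
  }
  class(prof) <- c("cmc_profiles", "data.frame")
  prof
}

#' @export
print.cmc_profiles <- function(x, ...) {
  cat("Association profiles for ", nrow(x), " genes\n", sep = "")
  for (db in association_databases()) {
    n <- sum(x[[paste0(db, "_n_assoc")]])
    cat(sprintf("  %-10s %6d associations on %d genes\n", db, n,
                sum(x[[paste0(db, "_n_assoc")]] > 0)))
  }
  invisible(x)
}
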