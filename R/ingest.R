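#' Filter probes by detection p-value, bead count and exclusion lists
#'
#' Applies the standard array-QC probe filters: a probe is removed when its
#' detection p-value exceeds `p_threshold` in at least `frac_threshold` of
#' samples, when its bead count falls below `min_beads` in at least
#' `frac_threshold` of samples, or when it appears on any supplied exclusion
#' list (sex-chromosome, SNP-overlapping, cross-reactive probes are the usual
#' ones). A probe failing several rules is removed once; the report
#' attributes it to every rule it failed.
#'
#' @param beta a [beta_matrix()].
#' @param detection_p optional numeric matrix of detection p-values with the
#'   same dimnames as `beta`.
#' @param bead_counts optional numeric matrix of bead counts with the same
#'   dimnames as `beta`.
#' @param exclusion_lists named list of character vectors of probe ids.
#'   Ids absent from `beta` produce a warning, not an error (lists are
#'   array-agnostic).
#' @param p_threshold detection p-value above which a sample fails (default
#'   0.05).
#' @param frac_threshold fraction of samples that must fail for removal
#'   (default 0.05).
#' @param min_beads minimum acceptable bead count (default 3).
#' @return list with elements `beta` (the filtered [beta_matrix()]) and
#'   `report` (a `filter_report`: per-rule removal counts, unique removals,
#'   probes retained).
#' @export
filter_probes <- function(beta, detection_p = NULL, bead_counts = NULL,
                          exclusion_lists = list(),
                          p_threshold = 0.05, frac_threshold = 0.05,
                          min_beads = 3) {
  probes <- rownames(beta)
  n_samp <- ncol(beta)
  removed <- list()

  check_aligned <- function(m, what) {
    if (!identical(rownames(m), probes) || !identical(colnames(m), colnames(beta)))
      stop(what, " matrix must share probe and sample ids with `beta`")
  }
  if (!is.null(detection_p)) {
    check_aligned(detection_p, "detection_p")
    n_fail <- rowSums(detection_p > p_threshold, na.rm = TRUE)
    removed[["detection_p"]] <- probes[n_fail / n_samp >= frac_threshold]
  }
  if (!is.null(bead_counts)) {
    check_aligned(bead_counts, "bead_counts")
    n_fail <- rowSums(bead_counts < min_beads, na.rm = TRUE)
    removed[["bead_count"]] <- probes[n_fail / n_samp >= frac_threshold]
  }
  for (nm in names(exclusion_lists)) {
    ids <- as.character(exclusion_lists[[nm]])
    unknown <- setdiff(ids, probes)
    if (length(unknown))
      warning(sprintf("exclusion list '%s': %d ids not in the beta matrix",
                      nm, length(unknown)))
    removed[[nm]] <- intersect(ids, probes)
  }

  drop <- unique(unlist(removed, use.names = FALSE))
  keep <- setdiff(probes, drop)
  report <- structure(list(
    input_probes = length(probes),
    removed_per_rule = vapply(removed, length, integer(1)),
    removed_unique = length(drop),
    retained = length(keep),
    removed_ids = removed
  ), class = "filter_report")
  out <- beta_matrix(unclass(beta)[keep, , drop = FALSE])
  list(beta = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d probes in, %d removed (unique), %d retained\n",
              x$input_probes, x$removed_unique, x$retained))
  if (length(x$removed_per_rule))
    for (nm in names(x$removed_per_rule))
      cat(sprintf("  %-14s %d\n", nm, x$removed_per_rule[[nm]]))
  invisible(x)
}

#' Read an Illumina-manifest-style probe annotation
#'
#' Expects a CSV with at least a `Name` column; recognised optional columns
#' are `CHR`, `UCSC_RefGene_Group` (semicolon-delimited),
#' `UCSC_RefGene_Name` (semicolon-delimited gene symbols),
#' `Relation_to_UCSC_CpG_Island`, `Enhancer`, `DHS` and
#' `Regulatory_Feature_Group`. Extra columns are ignored.
#'
#' @param path path to the CSV file.
#' @param clock_lists optional named list of character vectors of probe ids
#'   giving clock memberships (e.g. `list(Horvath = ...)`).
#' @return a data frame of class `probe_annotation` with columns `probe_id`,
#'   `chromosome`, `gene_region_groups` (list of character vectors), `genes`
#'   (list), `regulatory_features` (list), `island_context` and
#'   `clock_memberships` (list).
#' @export
read_annotation <- function(path, clock_lists = list()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Name" %in% names(df))
    stop("annotation file lacks the probe-id column `Name`")
  probe_annotation(
    probe_id = df$Name,
    chromosome = if ("CHR" %in% names(df)) as.character(df$CHR) else NA_character_,
    gene_region_group = if ("UCSC_RefGene_Group" %in% names(df))
      df$UCSC_RefGene_Group else "",
    gene = if ("UCSC_RefGene_Name" %in% names(df)) df$UCSC_RefGene_Name else "",
    island_relation = if ("Relation_to_UCSC_CpG_Island" %in% names(df))
      df$Relation_to_UCSC_CpG_Island else "",
    enhancer = if ("Enhancer" %in% names(df)) df$Enhancer else "",
    dhs = if ("DHS" %in% names(df)) df$DHS else "",
    regulatory_feature_group = if ("Regulatory_Feature_Group" %in% names(df))
      df$Regulatory_Feature_Group else "",
    clock_lists = clock_lists
  )
}

split_semicolon <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) unique(v[nzchar(v)]))
}

#' Build a probe annotation table from manifest-style columns
#'
#' Lower-level constructor behind [read_annotation()]; useful when the
#' annotation is assembled in code (e.g. by the synthetic-cohort generator).
#' Semicolon-delimited region and gene strings are split and de-duplicated;
#' island relations collapse `N_`/`S_` prefixes so `N_Shore` and `S_Shore`
#' both map to `Shore`, and empty values map to `OpenSea`.
#'
#' @param probe_id character vector (one row per probe).
#' @param chromosome,gene_region_group,gene,island_relation,enhancer,dhs,regulatory_feature_group
#'   manifest-style per-probe columns (recycled scalars allowed).
#' @param clock_lists named list of probe-id vectors for clock memberships.
#' @return a `probe_annotation` data frame; see [read_annotation()].
#' @export
probe_annotation <- function(probe_id, chromosome = NA_character_,
                             gene_region_group = "", gene = "",
                             island_relation = "", enhancer = "", dhs = "",
                             regulatory_feature_group = "",
                             clock_lists = list()) {
  n <- length(probe_id)
  if (anyDuplicated(probe_id))
    stop("duplicate probe ids in annotation")
  rec <- function(x) rep_len(x, n)
  island <- rec(as.character(island_relation))
  island[is.na(island)] <- ""
  island <- sub("^[NS]_", "", island)
  island[island %in% c("Sea", "")] <- "OpenSea"
  ok <- island %in% c("Island", "Shore", "Shelf", "OpenSea")
  if (!all(ok))
    stop("unrecognised island relation: ", island[!ok][1L])

  reg <- split_semicolon(rec(as.character(regulatory_feature_group)))
  enh <- rec(as.character(enhancer))
  dhs <- rec(as.character(dhs))
  truthy <- function(x) !is.na(x) & toupper(as.character(x)) %in% c("TRUE", "1", "YES")
  reg <- mapply(function(r, e, d) {
    r <- unique(c(r, if (e) "Enhancer", if (d) "DHS"))
    # manifest promoter/TFBS labels come as e.g. "Promoter_Associated"
    r[grepl("^Promoter", r)] <- "Promoter"
    unique(r)
  }, reg, truthy(enh), truthy(dhs), SIMPLIFY = FALSE)

  clocks <- rep(list(character(0)), n)
  names(clocks) <- NULL
  for (nm in names(clock_lists)) {
    hit <- probe_id %in% clock_lists[[nm]]
    clocks[hit] <- lapply(clocks[hit], function(v) c(v, nm))
  }

  out <- data.frame(probe_id = as.character(probe_id),
                    chromosome = rec(as.character(chromosome)),
                    island_context = island,
                    stringsAsFactors = FALSE)
  out$gene_region_groups <- split_semicolon(rec(as.character(gene_region_group)))
  out$genes <- split_semicolon(rec(as.character(gene)))
  out$regulatory_features <- reg
  out$clock_memberships <- clocks
  class(out) <- c("probe_annotation", class(out))
  out
}
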