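#' Collection of probe sets over a common universe
#'
#' @param sets named list of character vectors of probe ids.
#' @param universe character vector of probe ids; every set is intersected
#'   with it (ids outside the universe are dropped with a warning).
#' @return object of class `probe_set_collection`.
#' @export
probe_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  outside <- vapply(sets, function(s) length(setdiff(s, universe)), integer(1))
  if (any(outside > 0))
    warning(sprintf("%d set(s) contained ids outside the universe; dropped",
                    sum(outside > 0)))
  sets <- lapply(sets, intersect, y = universe)
  structure(list(sets = sets, universe = universe),
            class = "probe_set_collection")
}

#' Per-participant hypergeometric enrichment of SEMs in probe sets
#'
#' For each sample and each probe set, tests whether the sample's SEMs are
#' over-represented in the set: with N the universe size, K the set size,
#' n the sample's SEM count (within the universe) and k the overlap, the
#' p-value is the upper tail P(X >= k) of the hypergeometric distribution.
#' One-sided by design — the question is enrichment, not depletion.
#'
#' @param calls a `sem_calls` object; calls on probes outside the universe
#'   are dropped (the dropped count is recorded in the
#'   `dropped_outside_universe` attribute).
#' @param sets a [probe_set_collection()].
#' @param alpha significance threshold for the indicator (default 0.05,
#'   nominal — prevalence is interpreted descriptively, so no per-sample
#'   multiplicity correction is applied).
#' @return data frame of class `enrichment_result`: `sample_id`,
#'   `set_name`, `k`, `n`, `K`, `N`, `p`, `significant`, `no_draws` (TRUE
#'   for samples with zero in-universe SEMs, which get p = 1).
#' @export
sample_enrichment <- function(calls, sets, alpha = 0.05) {
  stopifnot(inherits(calls, "sem_calls"),
            inherits(sets, "probe_set_collection"))
  N <- length(sets$universe)
  cc <- calls$calls
  inside <- cc$probe_id %in% sets$universe
  dropped <- sum(!inside)
  cc <- cc[inside, , drop = FALSE]
  by_sample <- split(unique(cc[, c("sample_id", "probe_id")])$probe_id,
                     factor(cc$sample_id, levels = calls$sample_ids))
  rows <- lapply(calls$sample_ids, function(sid) {
    probes <- by_sample[[sid]]
    n <- length(probes)
    K <- vapply(sets$sets, length, integer(1))
    k <- vapply(sets$sets, function(s) sum(probes %in% s), integer(1))
    p <- if (n == 0) rep(1, length(K))
         else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(sample_id = sid, set_name = names(sets$sets),
               k = k, n = n, K = K, N = N, p = p,
               significant = p < alpha, no_draws = n == 0,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "dropped_outside_universe") <- dropped
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Prevalence of significant enrichment per probe set
#'
#' Counts, for each set, in how many participants the per-sample
#' hypergeometric test was significant — the descriptive summary that shows
#' whether any region or pathway is enriched consistently across people or
#' only in a few.
#'
#' @param results rows from [sample_enrichment()].
#' @return data frame with `set_name`, `n_significant`, `n_tested`,
#'   `fraction`.
#' @export
enrichment_prevalence <- function(results) {
  agg <- stats::aggregate(list(n_significant = results$significant),
                          by = list(set_name = results$set_name), FUN = sum)
  n_tested <- stats::aggregate(list(n_tested = results$significant),
                               by = list(set_name = results$set_name),
                               FUN = length)
  out <- merge(agg, n_tested, by = "set_name")
  out$fraction <- out$n_significant / out$n_tested
  out[order(-out$n_significant, out$set_name), , drop = FALSE]
}

#' Pathway-enrichment to age-acceleration regression
#'
#' Per probe set, fits AgeAccel_i = b0 + b1 * Enrich_ij + b2 * log(EML_i),
#' where Enrich_ij is the 0/1 significance indicator of participant i for
#' set j — i.e. asks whether people whose SEMs are enriched in the set show
#' faster age acceleration, over and above their total mutation load.
#'
#' @param accel numeric vector of per-sample accelerations (one measure).
#' @param enrichment rows from [sample_enrichment()] (supplies the
#'   indicator), or a data frame with `sample_id`, `set_name`,
#'   `significant`.
#' @param log_total_eml numeric vector of log total EML, aligned with
#'   `accel`.
#' @param sample_ids sample ids aligned with `accel`; defaults to
#'   `names(accel)`.
#' @return data frame with `set_name`, `beta1`, `beta2`, `p_beta1`, `n`,
#'   `estimable` (FALSE when the indicator is constant, which leaves b1
#'   unidentified).
#' @export
pathway_association <- function(accel, enrichment, log_total_eml,
                                sample_ids = names(accel)) {
  stopifnot(length(accel) == length(log_total_eml))
  if (is.null(sample_ids)) stop("sample ids are required to align the indicator")
  rows <- lapply(split(enrichment, enrichment$set_name), function(e) {
    ind <- e$significant[match(sample_ids, e$sample_id)]
    ok <- !is.na(ind) & !is.na(accel) & is.finite(log_total_eml)
    if (sum(ok) < 4L || length(unique(ind[ok])) < 2L)
      return(data.frame(set_name = e$set_name[1L], beta1 = NA_real_,
                        beta2 = NA_real_, p_beta1 = NA_real_, n = sum(ok),
                        estimable = FALSE, stringsAsFactors = FALSE))
    fit <- stats::lm(accel[ok] ~ ind[ok] + log_total_eml[ok])
    sm <- summary(fit)$coefficients
    data.frame(set_name = e$set_name[1L],
               beta1 = sm[2L, 1L], beta2 = sm[3L, 1L],
               p_beta1 = sm[2L, 4L], n = sum(ok), estimable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expand gene sets into probe sets via the annotation's probe-gene map
#'
#' A probe joins every set that contains any of its annotated genes.
#' Empty resulting sets are dropped with a warning.
#'
#' @param gene_sets named list of character vectors of gene ids (e.g. from
#'   [read_gmt()]).
#' @param annot a `probe_annotation` with a `genes` list column.
#' @param universe probe-id universe for the resulting collection; defaults
#'   to all annotated probes.
#' @return a [probe_set_collection()].
#' @export
gene_sets_to_probe_sets <- function(gene_sets, annot,
                                    universe = annot$probe_id) {
  stopifnot(inherits(annot, "probe_annotation"))
  pairs <- data.frame(
    probe_id = rep(annot$probe_id, lengths(annot$genes)),
    gene = unlist(annot$genes, use.names = FALSE),
    stringsAsFactors = FALSE)
  probe_sets <- lapply(gene_sets, function(genes)
    unique(pairs$probe_id[pairs$gene %in% genes]))
  empty <- lengths(probe_sets) == 0L
  if (any(empty)) {
    warning(sprintf("%d gene set(s) map to no probes; dropped", sum(empty)))
    probe_sets <- probe_sets[!empty]
  }
  probe_set_collection(probe_sets, universe)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT line(s): need name, description, >= 1 gene")
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Built-in probe-set collections from an annotation
#'
#' Convenience constructor for the standard enrichment scans: one set per
#' gene-region group, regulatory feature, island context and clock
#' membership present in the annotation.
#'
#' @param annot a `probe_annotation`.
#' @param universe probe universe; defaults to all annotated probes (set it
#'   to the filtered analysis universe in a real run).
#' @param which any of `"region"`, `"regulatory"`, `"island"`, `"clock"`.
#' @return a [probe_set_collection()].
#' @export
annotation_probe_sets <- function(annot, universe = annot$probe_id,
                                  which = c("region", "regulatory",
                                            "island", "clock")) {
  which <- match.arg(which, several.ok = TRUE)
  sets <- list()
  grab <- function(memberships, prefix) {
    lv <- sort(unique(unlist(memberships)))
    out <- lapply(lv, function(l)
      annot$probe_id[vapply(memberships, function(v) l %in% v, logical(1))])
    stats::setNames(out, paste0(prefix, lv))
  }
  if ("region" %in% which)
    sets <- c(sets, grab(annot$gene_region_groups, "region_"))
  if ("regulatory" %in% which)
    sets <- c(sets, grab(annot$regulatory_features, "regulatory_"))
  if ("island" %in% which) {
    lv <- c("Island", "Shore", "Shelf", "OpenSea")
    sets <- c(sets, stats::setNames(
      lapply(lv, function(l) annot$probe_id[annot$island_context == l]),
      paste0("island_", lv)))
  }
  if ("clock" %in% which)
    sets <- c(sets, grab(annot$clock_memberships, "clock_"))
  sets <- sets[lengths(sets) > 0L]
  probe_set_collection(sets, universe)
}
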