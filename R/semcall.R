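#' Per-probe interquartile-range fences
#'
#' For each probe, computes Q1 and Q3 across all non-missing samples of the
#' matrix (fences are cohort-specific: every cohort gets its own fence
#' table), the interquartile range IQR = Q3 - Q1, and the outlier fences
#' Q1 - k*IQR and Q3 + k*IQR. The default multiplier k = 3 defines the
#' standard stochastic epigenetic mutation; k = 2 and k = 4 give the loose
#' and stringent variants used for sensitivity analysis.
#'
#' Quantiles use linear interpolation between order statistics at position
#' p*(n-1) (`stats::quantile` type 7). Probes with fewer than 4 non-missing
#' values are flagged unusable and excluded from calling with a warning.
#'
#' @param beta a [beta_matrix()].
#' @param k fence multiplier in IQR units (> 0); default 3.
#' @return data frame of class `fence_table` with columns `probe_id`, `q1`,
#'   `q3`, `iqr`, `lower_fence`, `upper_fence`, `n_used`, `usable`, and
#'   attribute `k`.
#' @export
compute_fences <- function(beta, k = 3) {
  stopifnot(is.numeric(k), length(k) == 1L, k > 0)
  q <- row_quartiles(unclass(beta))
  n_used <- rowSums(!is.na(unclass(beta)))
  usable <- n_used >= 4L
  if (any(!usable))
    warning(sprintf("%d probe(s) with < 4 non-missing values: fences flagged unusable",
                    sum(!usable)))
  iqr <- q[, 2L] - q[, 1L]
  out <- data.frame(probe_id = rownames(beta),
                    q1 = q[, 1L], q3 = q[, 2L], iqr = iqr,
                    lower_fence = q[, 1L] - k * iqr,
                    upper_fence = q[, 2L] + k * iqr,
                    n_used = n_used, usable = usable,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[!usable, c("q1", "q3", "iqr", "lower_fence", "upper_fence")] <- NA_real_
  attr(out, "k") <- k
  class(out) <- c("fence_table", class(out))
  out
}

# Exact type-7 Q1/Q3 per row via partial sorting of the four order
# statistics the interpolation touches; much faster than per-row
# stats::quantile on array-sized matrices.
row_quartiles <- function(m) {
  dimnames(m) <- NULL  # row extraction must not drag probe/sample names along
  out <- matrix(NA_real_, nrow(m), 2L)
  q7 <- function(v) {
    n <- length(v)
    if (n == 1L) return(c(v, v))
    h1 <- (n - 1) * 0.25; h3 <- (n - 1) * 0.75
    lo1 <- floor(h1) + 1L; lo3 <- floor(h3) + 1L
    hi1 <- min(lo1 + 1L, n); hi3 <- min(lo3 + 1L, n)
    g1 <- h1 - floor(h1); g3 <- h3 - floor(h3)
    v <- sort.int(v, partial = unique(c(lo1, hi1, lo3, hi3)))
    c((1 - g1) * v[lo1] + g1 * v[hi1],
      (1 - g3) * v[lo3] + g3 * v[hi3])
  }
  if (!anyNA(m) && ncol(m) > 1L) {
    # constant column count: hoist the order-statistic indices out of the loop
    n <- ncol(m)
    h1 <- (n - 1) * 0.25; h3 <- (n - 1) * 0.75
    lo1 <- floor(h1) + 1L; lo3 <- floor(h3) + 1L
    hi1 <- min(lo1 + 1L, n); hi3 <- min(lo3 + 1L, n)
    g1 <- h1 - floor(h1); g3 <- h3 - floor(h3)
    part <- unique(c(lo1, hi1, lo3, hi3))
    for (i in seq_len(nrow(m))) {
      v <- sort.int(m[i, ], partial = part)
      out[i, 1L] <- (1 - g1) * v[lo1] + g1 * v[hi1]
      out[i, 2L] <- (1 - g3) * v[lo3] + g3 * v[hi3]
    }
  } else {
    for (i in seq_len(nrow(m))) {
      v <- m[i, ]
      v <- v[!is.na(v)]
      if (length(v) >= 1L) out[i, ] <- q7(v)
    }
  }
  out
}

#' Call stochastic epigenetic mutations against a fence table
#'
#' A value v at probe j in sample i is a hypermethylated SEM iff
#' v > upper_fence(j) and a hypomethylated SEM iff v < lower_fence(j);
#' inequalities are strict, so a value exactly on a fence is not called and
#' a constant probe (IQR = 0, fences collapsed onto the constant) yields no
#' calls. Missing values are never called.
#'
#' @param beta a [beta_matrix()] over the same probe universe the fences
#'   were computed from.
#' @param fences a `fence_table` from [compute_fences()].
#' @return an object of class `sem_calls`: list with `calls` (data frame
#'   `sample_id`, `probe_id`, `direction`, `beta`), `fences`, `k`,
#'   `sample_ids` and `probe_ids` (the full universes, including samples and
#'   probes with no calls).
#' @export
call_sems <- function(beta, fences) {
  if (!inherits(fences, "fence_table")) stop("`fences` must be a fence_table")
  missing_probes <- setdiff(rownames(beta), fences$probe_id)
  if (length(missing_probes))
    stop("probes present in `beta` but absent from `fences`: ",
         paste(utils::head(missing_probes, 5), collapse = ", "))
  f <- fences[match(rownames(beta), fences$probe_id), ]
  m <- unclass(beta)
  lower <- ifelse(f$usable, f$lower_fence, -Inf)
  upper <- ifelse(f$usable, f$upper_fence, Inf)
  # row-vector recycling runs down columns, aligning fence i with row i
  hyper <- which(!is.na(m) & m > upper)
  hypo <- which(!is.na(m) & m < lower)
  idx <- c(hyper, hypo)
  ri <- (idx - 1L) %% nrow(m) + 1L
  ci <- (idx - 1L) %/% nrow(m) + 1L
  calls <- data.frame(
    sample_id = colnames(beta)[ci],
    probe_id = rownames(beta)[ri],
    direction = rep(c("hyper", "hypo"), c(length(hyper), length(hypo))),
    beta = m[idx],
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$sample_id, calls$probe_id), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(calls = calls, fences = fences, k = attr(fences, "k"),
                 sample_ids = colnames(beta), probe_ids = rownames(beta)),
            class = "sem_calls")
}

#' @export
print.sem_calls <- function(x, ...) {
  cat(sprintf("sem_calls: %d calls (%d hyper, %d hypo) over %d samples x %d probes, k = %g\n",
              nrow(x$calls), sum(x$calls$direction == "hyper"),
              sum(x$calls$direction == "hypo"),
              length(x$sample_ids), length(x$probe_ids), x$k))
  invisible(x)
}

#' @export
summary.sem_calls <- function(object, ...) {
  eml <- compute_eml(object)
  cat(sprintf("sem_calls over %d samples, %d probes (k = %g)\n",
              length(object$sample_ids), length(object$probe_ids), object$k))
  cat("per-sample EML:\n")
  print(summary(eml$eml))
  invisible(eml)
}

#' Epigenetic mutation load per sample
#'
#' Counts SEM calls per sample, optionally restricted to a probe subset
#' and/or direction, and returns the natural-log load used in all regression
#' analyses. Samples with zero calls get `log_eml = NA` unless a
#' `pseudocount` is supplied explicitly (real-data loads are in the
#' thousands, so zero counts signal something worth noticing, not a value to
#' fabricate).
#'
#' @param calls a `sem_calls` object.
#' @param subset optional character vector of probe ids to restrict to.
#' @param direction optional `"hyper"` or `"hypo"`.
#' @param pseudocount optional value added inside the log for zero counts.
#' @return data frame of class `eml_table` with `sample_id`, `eml`,
#'   `log_eml`; one row per sample in the call set's sample universe.
#' @export
compute_eml <- function(calls, subset = NULL, direction = NULL,
                        pseudocount = NULL) {
  stopifnot(inherits(calls, "sem_calls"))
  cc <- calls$calls
  if (!is.null(subset)) {
    extra <- setdiff(subset, calls$probe_ids)
    if (length(extra))
      stop("subset contains probes outside the probe universe: ",
           paste(utils::head(extra, 5), collapse = ", "))
    cc <- cc[cc$probe_id %in% subset, , drop = FALSE]
  }
  if (!is.null(direction)) {
    direction <- match.arg(direction, c("hyper", "hypo"))
    cc <- cc[cc$direction == direction, , drop = FALSE]
  }
  n <- table(factor(cc$sample_id, levels = calls$sample_ids))
  eml <- as.integer(n)
  log_eml <- ifelse(eml > 0, log(eml),
                    if (is.null(pseudocount)) NA_real_ else log(eml + pseudocount))
  out <- data.frame(sample_id = calls$sample_ids, eml = eml,
                    log_eml = log_eml, stringsAsFactors = FALSE)
  class(out) <- c("eml_table", class(out))
  out
}

#' Region-, feature-, context- and clock-specific EML counts
#'
#' One count column per gene-region group, regulatory feature, island
#' context, clock membership and call direction. A call on a probe annotated
#' to several region groups increments each group's count once (region
#' groups overlap; they do not partition the probe universe, so region
#' counts need not sum to the total EML — directions do).
#'
#' @param calls a `sem_calls` object.
#' @param annot a `probe_annotation` covering (at least) the called probes;
#'   unannotated probes are allowed and contribute only to direction counts.
#' @return data frame: `sample_id`, `eml`, then one integer column per
#'   subset, named `region_*`, `regulatory_*`, `island_*`, `clock_*`,
#'   `direction_*`.
#' @export
region_emls <- function(calls, annot) {
  stopifnot(inherits(calls, "sem_calls"), inherits(annot, "probe_annotation"))
  cc <- calls$calls
  idx <- match(cc$probe_id, annot$probe_id)
  samples <- factor(cc$sample_id, levels = calls$sample_ids)

  count_sets <- function(memberships, prefix) {
    # column per level present anywhere in the annotation, so a clock or
    # region with zero mutated CpGs still reports an explicit 0
    levels_all <- as.character(sort(unique(unlist(memberships))))
    if (!length(levels_all)) return(list())
    called <- memberships[idx]
    out <- lapply(levels_all, function(lv) {
      hit <- vapply(called, function(v) !is.null(v) && lv %in% v, logical(1))
      as.integer(table(samples[hit]))
    })
    names(out) <- paste0(prefix, levels_all)
    out
  }

  cols <- c(
    count_sets(annot$gene_region_groups, "region_"),
    count_sets(annot$regulatory_features, "regulatory_"),
    {
      ic <- annot$island_context[idx]
      lv <- c("Island", "Shore", "Shelf", "OpenSea")
      out <- lapply(lv, function(l) as.integer(table(samples[!is.na(ic) & ic == l])))
      names(out) <- paste0("island_", lv)
      out
    },
    count_sets(annot$clock_memberships, "clock_"),
    {
      out <- lapply(c("hyper", "hypo"),
                    function(d) as.integer(table(samples[cc$direction == d])))
      names(out) <- paste0("direction_", c("hyper", "hypo"))
      out
    }
  )
  base <- compute_eml(calls)
  cbind(base[, c("sample_id", "eml")],
        as.data.frame(cols, check.names = FALSE))
}

#' Recurrently mutated CpGs
#'
#' CpGs mutated in the same direction in more than `min_participants`
#' participants (strict greater-than; the consistency definition counts
#' carriers per direction separately).
#'
#' @param calls a `sem_calls` object.
#' @param min_participants carrier threshold (default 10).
#' @return data frame with `probe_id`, `direction`, `n_carriers`, sorted by
#'   decreasing carrier count.
#' @export
recurrent_sems <- function(calls, min_participants = 10) {
  cc <- calls$calls
  if (!nrow(cc))
    return(data.frame(probe_id = character(0), direction = character(0),
                      n_carriers = integer(0)))
  agg <- stats::aggregate(list(n_carriers = cc$sample_id),
                          by = list(probe_id = cc$probe_id,
                                    direction = cc$direction),
                          FUN = function(s) length(unique(s)))
  agg <- agg[agg$n_carriers > min_participants, , drop = FALSE]
  agg <- agg[order(-agg$n_carriers, agg$probe_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
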