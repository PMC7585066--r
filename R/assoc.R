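#' Residualize a variable on covariates
#'
#' Regresses `values` on the supplied covariates by ordinary least squares
#' (with intercept) and returns the residuals, which have zero sample
#' covariance with every column of the design. Rows with any missing field
#' are dropped from the fit (listwise deletion) and get `NA` residuals.
#' Categorical covariates are expanded to treatment contrasts; a
#' single-level categorical is dropped with a warning; a rank-deficient
#' design is an error naming the collinear columns.
#'
#' @param values numeric vector.
#' @param covariates data frame of numeric and/or categorical columns, same
#'   number of rows as `length(values)`. May be `NULL`/empty, in which case
#'   the residuals are simply the centered values.
#' @return numeric vector of residuals aligned with `values`.
#' @export
residualize <- function(values, covariates = NULL) {
  n <- length(values)
  if (is.null(covariates) || !NCOL(covariates) || !length(covariates)) {
    out <- values - mean(values, na.rm = TRUE)
    return(out)
  }
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  stopifnot(nrow(covariates) == n)
  keep <- rep(TRUE, ncol(covariates))
  for (j in seq_along(covariates)) {
    v <- covariates[[j]]
    if (is.character(v) || is.logical(v)) covariates[[j]] <- v <- factor(v)
    if (is.factor(v) && nlevels(droplevels(v[!is.na(v)])) < 2L) {
      warning("covariate '", names(covariates)[j],
              "' has a single level; dropped")
      keep[j] <- FALSE
    }
  }
  covariates <- covariates[, keep, drop = FALSE]
  if (!ncol(covariates)) return(values - mean(values, na.rm = TRUE))
  ok <- stats::complete.cases(covariates) & !is.na(values)
  X <- stats::model.matrix(~ ., data = droplevels(covariates[ok, , drop = FALSE]))
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  out <- rep(NA_real_, n)
  out[ok] <- stats::lm.fit(X, values[ok])$residuals
  out
}

#' Biweight midcorrelation
#'
#' Robust correlation built from medians and Tukey biweights. With
#' m = median(x) and d = median(|x - m|) (raw MAD, no consistency factor),
#' u = (x - m) / (9 d), weights w = (1 - u^2)^2 * 1(|u| < 1), and
#' x~ = (x - m) * w (same construction for y):
#'
#'   bicor(x, y) = sum(x~ y~) / ( sqrt(sum(x~^2)) * sqrt(sum(y~^2)) )
#'
#' A vector with d = 0 (more than half its values tied at the median) falls
#' back to mean-centering with unit weights — Pearson-style — with a
#' warning. Pairwise-complete observations are used.
#'
#' @param x,y numeric vectors of equal length, n >= 3 after removing
#'   incomplete pairs.
#' @return correlation in [-1, 1], or `NA` (with a warning) when a weighted
#'   sum of squares degenerates to zero.
#' @export
bicor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("bicor needs at least 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  xt <- bicor_weighted(x)
  yt <- bicor_weighted(y)
  den <- sqrt(sum(xt^2)) * sqrt(sum(yt^2))
  if (den == 0) {
    warning("zero denominator after biweighting; returning NA")
    return(NA_real_)
  }
  sum(xt * yt) / den
}

bicor_weighted <- function(x) {
  m <- stats::median(x)
  d <- stats::median(abs(x - m))
  if (d == 0) {
    warning("median absolute deviation is zero; falling back to mean-centering")
    return(x - mean(x))
  }
  u <- (x - m) / (9 * d)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - m) * w
}

#' Biweight midcorrelation with a p-value
#'
#' The two-sided p-value uses the Student-t transform
#' t = r * sqrt((n - 2) / (1 - r^2)) with n - 2 degrees of freedom, the
#' same mapping used for a Pearson correlation test.
#'
#' @param x,y numeric vectors, n >= 4 complete pairs.
#' @param variable_x,variable_y,cohort optional labels carried into the
#'   result row.
#' @return one-row data frame of class `correlation_result`: `cohort`,
#'   `variable_x`, `variable_y`, `r`, `p`, `n`. `|r| = 1` gives p = 0 with
#'   attribute `degenerate = TRUE`.
#' @export
bicor_test <- function(x, y, variable_x = "x", variable_y = "y", cohort = "") {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 4L) stop("bicor_test needs at least 4 complete pairs")
  r <- bicor(x[ok], y[ok])
  out <- data.frame(cohort = cohort, variable_x = variable_x,
                    variable_y = variable_y, r = r,
                    p = cor_t_pvalue(r, n), n = n,
                    stringsAsFactors = FALSE)
  if (!is.na(r) && abs(r) == 1) attr(out, "degenerate") <- TRUE
  class(out) <- c("correlation_result", class(out))
  out
}

# two-sided p for a correlation via the t transform with n - 2 df
cor_t_pvalue <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Cohort-level association scan
#'
#' For each target variable, residualizes the outcome on the covariates
#' (excluding the target itself when it appears among them — the
#' association of the outcome with age cannot be estimated after removing
#' age) and correlates the residuals with the untouched target by biweight
#' midcorrelation. Optional stratification by a grouping factor (e.g. sex)
#' and/or by the sign of an acceleration measure (acceleration = value > 0,
#' deceleration = value < 0; zeros excluded).
#'
#' @param data data frame holding outcome, targets and covariates per
#'   sample.
#' @param outcome name of the outcome column (e.g. `"log_eml"`, `"entropy"`).
#' @param targets character vector of target column names.
#' @param covariates character vector of covariate column names (may
#'   include targets; the current target is dropped from its own fit).
#' @param group_by optional name of a categorical column to stratify by.
#' @param sign_split optional name of a numeric column whose sign defines
#'   acceleration/deceleration strata.
#' @param cohort cohort label carried into the rows.
#' @return data frame with one `correlation_result` row per
#'   (target, stratum); strata with fewer than 4 complete pairs get `NA`
#'   r/p and `size_flag = TRUE`.
#' @export
cohort_association <- function(data, outcome, targets, covariates = character(0),
                               group_by = NULL, sign_split = NULL,
                               cohort = "") {
  stopifnot(outcome %in% names(data))
  missing_cols <- setdiff(c(targets, covariates, group_by, sign_split), names(data))
  if (length(missing_cols))
    stop("columns absent from `data`: ", paste(missing_cols, collapse = ", "))

  strata <- list(all = rep(TRUE, nrow(data)))
  if (!is.null(group_by)) {
    g <- data[[group_by]]
    strata <- lapply(stats::setNames(nm = levels(factor(g))),
                     function(lv) !is.na(g) & g == lv)
  }
  if (!is.null(sign_split)) {
    s <- data[[sign_split]]
    strata <- unlist(lapply(names(strata), function(nm) {
      base <- strata[[nm]]
      out <- list(base & !is.na(s) & s > 0, base & !is.na(s) & s < 0)
      names(out) <- trimws(paste(if (nm == "all") "" else nm,
                                 c("acceleration", "deceleration")))
      out
    }), recursive = FALSE)
  }

  rows <- list()
  for (target in targets) {
    # the target itself and the stratifying factor cannot also be regressed
    # out (the former would remove the association under test, the latter is
    # constant within its strata)
    cov_use <- setdiff(covariates, c(target, group_by))
    for (snm in names(strata)) {
      sel <- strata[[snm]]
      d <- data[sel, , drop = FALSE]
      n_ok <- sum(stats::complete.cases(d[, c(outcome, target), drop = FALSE]))
      if (n_ok < 4L) {
        row <- data.frame(cohort = cohort, variable_x = outcome,
                          variable_y = target, r = NA_real_, p = NA_real_,
                          n = n_ok, stratum = snm, size_flag = TRUE,
                          stringsAsFactors = FALSE)
      } else {
        res <- residualize(d[[outcome]], d[cov_use])
        row <- bicor_test(res, d[[target]], variable_x = outcome,
                          variable_y = target, cohort = cohort)
        row$stratum <- snm
        row$size_flag <- FALSE
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Stouffer/Fisher-z meta-analysis of per-cohort correlations
#'
#' The meta correlation is the sample-size-weighted mean of Fisher-z
#' transforms, meta_r = sum(n_i * atanh(r_i)) / sum(n_i), reported on the z
#' scale by default (for the weak correlations this method targets, z and r
#' differ only in the third decimal; `backtransform = TRUE` applies tanh).
#' The meta p combines signed normal deviates with sqrt(n) weights
#' (weighted Stouffer): Z = sum(sqrt(n_i) * s_i) / sqrt(sum(n_i)), where
#' s_i is the normal quantile of the cohort's two-sided p, signed by its r,
#' mapped back to a two-sided probability.
#'
#' @param rows data frame with columns `r`, `n` and (for the meta p) `p` —
#'   e.g. rows from [bicor_test()] or [cohort_association()], one per
#'   cohort, all for the same variable pair. When `p` is absent it is
#'   derived from `r` and `n` via the t transform.
#' @param backtransform report meta_r as tanh(weighted mean z) instead of
#'   the z-scale value. Default `FALSE`.
#' @return object of class `meta_result`: list with `meta_r`, `meta_p`,
#'   `meta_z`, `total_n` and the input `rows`.
#' @export
stouffer_meta <- function(rows, backtransform = FALSE) {
  rows <- as.data.frame(rows)
  stopifnot(all(c("r", "n") %in% names(rows)))
  if (any(is.na(rows$n))) stop("missing cohort size `n`")
  if (!"p" %in% names(rows))
    rows$p <- mapply(cor_t_pvalue, rows$r, rows$n)
  z <- atanh(rows$r)
  meta_r <- sum(rows$n * z) / sum(rows$n)
  if (backtransform) meta_r <- tanh(meta_r)
  # signed deviate: cap the quantile so p = 0 inputs stay finite
  p_floor <- pmax(rows$p, .Machine$double.xmin)
  s <- sign(rows$r) * stats::qnorm(p_floor / 2, lower.tail = FALSE)
  Z <- sum(sqrt(rows$n) * s) / sqrt(sum(rows$n))
  structure(list(meta_r = meta_r, meta_z = Z,
                 meta_p = 2 * stats::pnorm(-abs(Z)),
                 total_n = sum(rows$n), rows = rows,
                 backtransform = backtransform),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result over %d cohorts (total n = %d):\n",
              nrow(x$rows), x$total_n))
  cat(sprintf("  meta r = %.3f%s, meta p = %.3g (Z = %.2f)\n",
              x$meta_r, if (x$backtransform) " (tanh scale)" else "",
              x$meta_p, x$meta_z))
  invisible(x)
}

#' Batch-effect ANOVA on the epigenetic mutation load
#'
#' One-way fixed-effects ANOVA of log EML on a technical batch factor
#' (microarray slide, position on the array). A significant F would point
#' to loads driven by batch rather than biology.
#'
#' @param log_eml numeric vector of log-transformed loads.
#' @param batch factor (or coercible) of batch labels; at least 2 groups,
#'   each with at least 2 observations.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
qc_batch_anova <- function(log_eml, batch) {
  batch <- droplevels(factor(batch[!is.na(log_eml)]))
  log_eml <- log_eml[!is.na(log_eml)]
  if (nlevels(batch) < 2L) stop("need at least 2 batch groups")
  if (any(table(batch) < 2L)) stop("every batch group needs at least 2 observations")
  a <- stats::anova(stats::lm(log_eml ~ batch))
  list(F = a$`F value`[1L], p = a$`Pr(>F)`[1L],
       df_between = a$Df[1L], df_within = a$Df[2L])
}

#' Bisulfite-conversion QC correlation
#'
#' Pearson correlation between EML (or log EML) and the average intensity
#' of bisulfite-conversion control probes; a strong correlation would
#' suggest SEMs driven by incomplete conversion.
#'
#' @param eml numeric vector.
#' @param control_intensity numeric vector, same length.
#' @return list with `r`, `p`, `n`; `r` is `NA` for constant input.
#' @export
qc_conversion_pearson <- function(eml, control_intensity) {
  ok <- !is.na(eml) & !is.na(control_intensity)
  if (sum(ok) < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(eml[ok]) == 0 || stats::sd(control_intensity[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(eml[ok], control_intensity[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
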