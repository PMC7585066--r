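#' Linear epigenetic clock model
#'
#' A clock is a linear predictor over CpG betas:
#' DNAm age = intercept + sum_j w_j * beta_j, optionally followed by a
#' post-transform (published clocks sometimes calibrate young ages
#' nonlinearly; the identity is the default and the only bundled option —
#' supply a function for anything else).
#'
#' @param name clock name.
#' @param intercept intercept in model units (years for age clocks).
#' @param coefficients named numeric vector, names are probe ids (unique).
#' @param post_transform `NULL` (identity) or a function applied to the
#'   linear predictor.
#' @return object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, coefficients, post_transform = NULL) {
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients)))
    stop("clock coefficients must be uniquely named by probe id")
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients,
                 post_transform = post_transform),
            class = "clock_model")
}

#' Read a clock coefficient file
#'
#' Two-column CSV (`probe_id`, `weight`) with a comment header line of the
#' form `#intercept=<float>`.
#'
#' @param path path to the file.
#' @param name clock name; defaults to the file name without extension.
#' @return a [clock_model()].
#' @export
read_clock <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  hdr <- grep("^#intercept=", lines, value = TRUE)
  if (!length(hdr)) stop("clock file lacks a `#intercept=` header line")
  intercept <- as.numeric(sub("^#intercept=", "", hdr[1L]))
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        stringsAsFactors = FALSE)
  w <- as.numeric(df[[2L]])
  names(w) <- df[[1L]]
  clock_model(name, intercept, w)
}

#' Write a clock coefficient file
#' @param clock a [clock_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clock <- function(clock, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#intercept=%.17g", clock$intercept), con)
  utils::write.csv(data.frame(probe_id = names(clock$coefficients),
                              weight = sprintf("%.17g", clock$coefficients)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply a linear clock to a beta matrix
#'
#' @param beta a [beta_matrix()].
#' @param clock a [clock_model()].
#' @param missing_policy what to do about clock probes absent from `beta`
#'   or with missing betas: `"error"` (default) or `"mean-impute"`, which
#'   substitutes the probe's cohort mean (or, for wholly absent probes, the
#'   mean beta of the available clock probes). More than 20% absent probes
#'   is always an error.
#' @return named numeric vector of DNAm ages, one per sample.
#' @export
apply_linear_clock <- function(beta, clock,
                               missing_policy = c("error", "mean-impute")) {
  missing_policy <- match.arg(missing_policy)
  w <- clock$coefficients
  absent <- setdiff(names(w), rownames(beta))
  if (length(absent) > 0.2 * length(w))
    stop(sprintf("%d of %d clock probes absent from the beta matrix: %s ...",
                 length(absent), length(w),
                 paste(utils::head(absent, 5), collapse = ", ")))
  present <- setdiff(names(w), absent)
  m <- unclass(beta)[present, , drop = FALSE]
  if (length(absent) || anyNA(m)) {
    if (missing_policy == "error")
      stop("missing clock-probe betas; set missing_policy = \"mean-impute\" to proceed")
    if (anyNA(m)) {
      rm_ <- rowMeans(m, na.rm = TRUE)
      na_idx <- which(is.na(m), arr.ind = TRUE)
      m[na_idx] <- rm_[na_idx[, 1L]]
    }
    if (length(absent)) {
      fill <- matrix(mean(m), length(absent), ncol(m),
                     dimnames = list(absent, colnames(m)))
      m <- rbind(m, fill)
      present <- c(present, absent)
    }
  }
  sel <- names(w)[names(w) %in% present]
  age <- clock$intercept + drop(crossprod(m[sel, , drop = FALSE], w[sel]))
  if (!is.null(clock$post_transform)) age <- clock$post_transform(age)
  names(age) <- colnames(beta)
  age
}

#' Residual epigenetic age acceleration
#'
#' Acceleration is the residual of the ordinary least-squares regression of
#' DNAm age on chronological age (with intercept). By construction the
#' residuals have mean zero and zero correlation with chronological age, so
#' "accelerated" means older-than-expected given one's chronological age,
#' not simply old.
#'
#' @param dnam_age numeric vector of DNAm ages.
#' @param chrono_age numeric vector of chronological ages, same length.
#' @return numeric vector of residuals (years), `NA` where either input is
#'   missing.
#' @export
age_acceleration <- function(dnam_age, chrono_age) {
  stopifnot(length(dnam_age) == length(chrono_age))
  ok <- !is.na(dnam_age) & !is.na(chrono_age)
  if (sum(ok) < 3L) stop("need at least 3 complete (dnam_age, chrono_age) pairs")
  if (stats::sd(chrono_age[ok]) == 0) stop("chronological age is constant")
  fit <- stats::lm.fit(cbind(1, chrono_age[ok]), dnam_age[ok])
  out <- rep(NA_real_, length(dnam_age))
  out[ok] <- fit$residuals
  names(out) <- names(dnam_age)
  out
}

#' Pairwise Pearson correlations among age measures
#'
#' @param measures data frame or matrix of per-sample numeric columns
#'   (chronological age, DNAm ages, accelerations ...).
#' @return symmetric correlation matrix with unit diagonal; columns that are
#'   constant (or with fewer than 3 complete pairs) get `NA` entries.
#' @export
measure_correlation_matrix <- function(measures) {
  m <- as.matrix(measures)
  storage.mode(m) <- "double"
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  const <- apply(m, 2L, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                   sum(!is.na(v)) < 3L)
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r)[!const] <- 1
  r
}
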