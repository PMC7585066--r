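#' Construct a validated methylation beta matrix
#'
#' A beta matrix stores methylation fractions (beta values) with probes in
#' rows and samples in columns. Values must lie in [0, 1]; missing values are
#' allowed and are skipped downstream (fence computation, entropy).
#'
#' @param values numeric matrix of methylation fractions, probes x samples.
#' @param probe_ids character vector of unique probe identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @return a numeric matrix of class `beta_matrix` with probe row names and
#'   sample column names.
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("probe and sample identifiers are required")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values))
    stop("length(probe_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)")
  dup_p <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup_p))
    stop("duplicate probe ids: ", paste(utils::head(dup_p, 5), collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(utils::head(dup_s, 5), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("beta value out of [0,1] at (%s, %s): %g (%d offending cells)",
                 probe_ids[i], sample_ids[j], values[i, j], nrow(bad)))
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' Read a beta matrix from delimited text
#'
#' @param path path to a TSV/CSV file (gzip accepted) with an identifier
#'   header row and an identifier first column.
#' @param orientation `"probes_in_rows"` (default) or `"samples_in_rows"`;
#'   the returned matrix is always probes x samples.
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (`.csv` means comma, anything else tab).
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path,
                             orientation = c("probes_in_rows", "samples_in_rows"),
                             sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
    m <- array(as.numeric(m), dim(m), dimnames = dimnames(m))
  }
  if (orientation == "samples_in_rows") m <- t(m)
  beta_matrix(m)
}

#' Write a beta matrix to delimited text
#'
#' @param beta a [beta_matrix()].
#' @param path output path; `.csv` extension selects comma separation.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # %.17g guarantees doubles survive the text round trip bit-for-bit
  chr <- array(ifelse(is.na(beta), "NA", sprintf("%.17g", unclass(beta))),
               dim(beta), dimnames = dimnames(beta))
  df <- data.frame(probe_id = rownames(beta), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d missing values)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}
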