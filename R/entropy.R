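#' Methylome Shannon entropy per sample
#'
#' For each sample, the normalized average binary entropy of its beta
#' values:
#'
#'   entropy = 1 / (N * log2(1/2)) * sum_i [ b_i*log2(b_i) + (1-b_i)*log2(1-b_i) ]
#'
#' with the convention 0*log2(0) = 0. The normalizer log2(1/2) = -1 flips
#' the sign, so entropy lies in [0, 1]: 1 when every site is
#' half-methylated (the methylome maximally unpredictable across the cell
#' population), 0 when every site is fully methylated or unmethylated.
#' Missing values are skipped, reducing N for that sample.
#'
#' @param beta a [beta_matrix()].
#' @param eps numerical guard: betas strictly inside (0, 1) are clipped to
#'   `[eps, 1 - eps]` before taking logs; exact 0/1 values are handled by
#'   the 0*log(0) = 0 convention first. Default 1e-12.
#' @return data frame of class `entropy_table` with `sample_id`, `entropy`,
#'   `n_probes_used`. Samples with zero usable probes get `NA` entropy.
#' @export
methylome_entropy <- function(beta, eps = 1e-12) {
  m <- unclass(beta)
  b <- pmin(pmax(m, eps), 1 - eps)
  term <- b * log2(b) + (1 - b) * log2(1 - b)
  term[!is.na(m) & (m == 0 | m == 1)] <- 0
  n_used <- colSums(!is.na(term))
  total <- colSums(term, na.rm = TRUE)
  entropy <- ifelse(n_used > 0, total / (n_used * log2(0.5)), NA_real_)
  out <- data.frame(sample_id = colnames(beta), entropy = entropy,
                    n_probes_used = n_used, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("entropy_table", class(out))
  out
}
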