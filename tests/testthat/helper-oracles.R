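# Independent oracles, deliberately written as literal transcriptions with
# explicit loops so they share no code path with the package internals.

# biweight midcorrelation, straight from the defining formula
oracle_bicor <- function(x, y) {
  transform_one <- function(v) {
    m <- sort(v)[ceiling(length(v) / 2)]
    if (length(v) %% 2 == 0) {
      s <- sort(v)
      m <- (s[length(v) / 2] + s[length(v) / 2 + 1]) / 2
    }
    dev <- abs(v - m)
    s <- sort(dev)
    d <- if (length(v) %% 2 == 0) (s[length(v) / 2] + s[length(v) / 2 + 1]) / 2
         else s[ceiling(length(v) / 2)]
    if (d == 0) return(v - sum(v) / length(v))
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      u <- (v[i] - m) / (9 * d)
      w <- if (abs(u) < 1) (1 - u^2)^2 else 0
      out[i] <- (v[i] - m) * w
    }
    out
  }
  xt <- transform_one(x)
  yt <- transform_one(y)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(xt)) {
    num <- num + xt[i] * yt[i]
    dx <- dx + xt[i]^2
    dy <- dy + yt[i]^2
  }
  num / (sqrt(dx) * sqrt(dy))
}

# brute-force SEM caller: per-probe quantiles via stats::quantile, cell by
# cell comparison
oracle_call_sems <- function(m, k) {
  out <- NULL
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    v_ok <- v[!is.na(v)]
    if (length(v_ok) < 4) next
    q <- stats::quantile(v_ok, c(0.25, 0.75), type = 7, names = FALSE)
    lo <- q[1] - k * (q[2] - q[1])
    up <- q[2] + k * (q[2] - q[1])
    for (j in seq_len(ncol(m))) {
      if (is.na(v[j])) next
      if (v[j] > up)
        out <- rbind(out, data.frame(sample_id = colnames(m)[j],
                                     probe_id = rownames(m)[i],
                                     direction = "hyper"))
      else if (v[j] < lo)
        out <- rbind(out, data.frame(sample_id = colnames(m)[j],
                                     probe_id = rownames(m)[i],
                                     direction = "hypo"))
    }
  }
  if (is.null(out)) data.frame(sample_id = character(0),
                               probe_id = character(0),
                               direction = character(0))
  else out
}

# exhaustive hypergeometric upper tail: enumerate every n-subset of an
# N-element universe and count how many share >= k elements with the set
oracle_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  universe <- seq_len(N)
  in_set <- universe <= K
  subsets <- utils::combn(N, n)
  hits <- 0
  for (j in seq_len(ncol(subsets)))
    if (sum(in_set[subsets[, j]]) >= k) hits <- hits + 1
  hits / ncol(subsets)
}

call_key <- function(d) paste(d$sample_id, d$probe_id, d$direction)

random_beta_matrix <- function(p, n, seed, na_frac = 0) {
  set.seed(seed)
  m <- matrix(runif(p * n), p, n,
              dimnames = list(sprintf("cg%05d", seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  if (na_frac > 0) m[sample(length(m), round(na_frac * length(m)))] <- NA
  beta_matrix(m)
}

# per-cohort rows printed for the EML associations (per-cohort bicor r and
# two-sided p, cohort sizes) used as inputs to the meta-analysis layer
printed_cohort_sizes <- c(FHS = 2326, WHI = 2091, JHS = 1734, PEG1 = 237)
printed_rows <- function(r, p = NULL) {
  out <- data.frame(cohort = names(printed_cohort_sizes), r = r,
                    n = unname(printed_cohort_sizes))
  if (!is.null(p)) out$p <- p
  out
}
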