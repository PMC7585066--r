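#' Configuration for the synthetic-cohort generator
#'
#' The generator emulates the statistical structure the SEM analysis
#' assumes: per-CpG beta baselines drawn by island context (islands mostly
#' unmethylated, open sea mostly methylated), rare per-person outlier
#' mutations whose expected count grows log-linearly with age and with a
#' latent acceleration factor, a clock-CpG subset carrying a simulated DNAm
#' age, hypermethylated outliers concentrated in islands and hypomethylated
#' ones in open sea, plus metadata (sex, ethnicity, Dirichlet cell
#' fractions, batch labels with no planted effect).
#'
#' The expected SEM count of sample i is
#' `lambda_i = exp(alpha + gamma_age * age_i + gamma_acc * acc_i)` with
#' `alpha` solved so that a sample of mid-range age with `acc = 0` expects
#' `mean_eml` mutations.
#'
#' @param n_samples samples per cohort (default 500).
#' @param n_probes probes (default 5000; array-scale generation works but
#'   is not the default).
#' @param seed integer RNG seed; fixed seed gives bit-reproducible output.
#' @param age_range uniform chronological-age draw, years (default 40-90).
#' @param island_fracs probe fractions per island context.
#' @param beta_shapes per-context Beta shape pairs for the per-probe
#'   baseline mean.
#' @param beta_precision precision of the per-cell Beta draw around the
#'   probe baseline (larger = tighter probes).
#' @param mean_eml expected SEM count at mid-range age and zero
#'   acceleration (default 0.5% of probes, the per-probe rate real arrays
#'   show).
#' @param gamma_age log-rate increase per year of age; the default doubles
#'   the expected load across the age range.
#' @param gamma_acc log-rate increase per year of latent acceleration.
#' @param sigma_acc SD of the latent acceleration (years, default 5, the
#'   scale real acceleration measures show).
#' @param delta fence-exceedance margin for injected outliers, in IQR
#'   units beyond the k = 3 fence (default 0.5).
#' @param hyper_fraction fraction of injected SEMs that are
#'   hypermethylated.
#' @param hyper_context_weights,hypo_context_weights probe-choice weights
#'   by island context for each direction.
#' @param n_clock_cpgs number of clock CpGs (default 30).
#' @param clock_noise_sd SD (years) of the DNAm-age noise around
#'   age + acc.
#' @param clock_beta_noise_sd per-cell beta noise on clock probes.
#' @param n_batches number of slide labels.
#' @param cell_dirichlet Dirichlet concentration for the five blood cell
#'   fractions.
#' @param cohort cohort label.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500, n_probes = 5000, seed = 1,
                       age_range = c(40, 90),
                       island_fracs = c(Island = 0.30, Shore = 0.25,
                                        Shelf = 0.15, OpenSea = 0.30),
                       beta_shapes = list(Island = c(2, 18),
                                          Shore = c(6, 14),
                                          Shelf = c(14, 6),
                                          OpenSea = c(18, 2)),
                       beta_precision = 100,
                       mean_eml = 0.005 * n_probes,
                       gamma_age = log(2) / diff(range(age_range)),
                       gamma_acc = 0.02,
                       sigma_acc = 5,
                       delta = 0.5,
                       hyper_fraction = 0.5,
                       hyper_context_weights = c(Island = 0.70, Shore = 0.15,
                                                 Shelf = 0.10, OpenSea = 0.05),
                       hypo_context_weights = c(Island = 0.05, Shore = 0.10,
                                                Shelf = 0.15, OpenSea = 0.70),
                       n_clock_cpgs = 30,
                       clock_noise_sd = 2,
                       clock_beta_noise_sd = 0.003,
                       n_batches = 8,
                       cell_dirichlet = c(CD8.naive = 2,
                                          CD8pCD28nCD45RAn = 1,
                                          PlasmaBlast = 0.5,
                                          CD4T = 8, Gran = 20),
                       cohort = "sim") {
  cfg <- as.list(environment())
  stopifnot(n_samples >= 3, n_probes >= 50, length(age_range) == 2,
            age_range[1] > 0, age_range[2] > age_range[1],
            abs(sum(island_fracs) - 1) < 1e-8, all(island_fracs >= 0),
            mean_eml > 0, sigma_acc >= 0, delta > 0,
            hyper_fraction >= 0, hyper_fraction <= 1,
            n_clock_cpgs >= 2, n_clock_cpgs < n_probes / 2)
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

#' Simulate a cohort with known SEM truth
#'
#' See [sim_config()] for the generative model. Injected outliers are
#' verified against fences recomputed after injection (injection shifts the
#' quantiles, so placement against pre-injection fences would under-call at
#' small n): the placement loop re-targets values until every injected cell
#' lies strictly beyond its probe's final k = 3 fence by at least `delta`
#' IQRs, or errors if a target is pushed outside [0, 1] everywhere.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_cohort`: list with `beta`
#'   (a [beta_matrix()]), `samples` (metadata data frame), `annotation`
#'   (a `probe_annotation`), `clock` (a [clock_model()] recoverable by
#'   [apply_linear_clock()]), and `truth` (injected calls, per-sample
#'   latent acceleration and lambda, true DNAm age, clock probe ids).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  p <- cfg$n_probes

  probe_ids <- sprintf("cg%07d", seq_len(p))
  sample_ids <- sprintf("%s_s%04d", cfg$cohort, seq_len(n))
  context <- sample(names(cfg$island_fracs), p, replace = TRUE,
                    prob = cfg$island_fracs)

  # per-probe baseline means by island context, kept off the boundaries so
  # per-cell Beta draws have usable spread
  mu <- numeric(p)
  for (ctx in names(cfg$beta_shapes)) {
    idx <- context == ctx
    sh <- cfg$beta_shapes[[ctx]]
    mu[idx] <- stats::rbeta(sum(idx), sh[1], sh[2])
  }
  mu <- pmin(pmax(mu, 0.05), 0.95)
  phi <- cfg$beta_precision
  beta <- matrix(stats::rbeta(p * n, mu * phi, (1 - mu) * phi),
                 nrow = p, ncol = n, dimnames = list(probe_ids, sample_ids))

  # ages, latent acceleration, true DNAm age
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  acc <- stats::rnorm(n, 0, cfg$sigma_acc)
  dnam_age <- age + acc + stats::rnorm(n, 0, cfg$clock_noise_sd)

  # clock CpGs carry DNAm age linearly: beta = 0.5 + a*d_j*(dnam-c0)/s0,
  # weights w_j = d_j*s0/(a*n_clock) recover dnam exactly up to beta noise
  clock_probes <- sample(probe_ids, cfg$n_clock_cpgs)
  a_amp <- 0.35; c0 <- mean(cfg$age_range); s0 <- 150
  d_sign <- sample(c(-1, 1), cfg$n_clock_cpgs, replace = TRUE)
  zz <- (dnam_age - c0) / s0
  clock_betas <- 0.5 + a_amp * outer(d_sign, zz) +
    stats::rnorm(cfg$n_clock_cpgs * n, 0, cfg$clock_beta_noise_sd)
  clock_betas <- pmin(pmax(clock_betas, 0), 1)
  beta[clock_probes, ] <- clock_betas
  w <- d_sign * s0 / (a_amp * cfg$n_clock_cpgs)
  names(w) <- clock_probes
  clock <- clock_model("SimClock", intercept = c0 - 0.5 * sum(w), w)

  # SEM injection
  alpha0 <- log(cfg$mean_eml) - cfg$gamma_age * mean(cfg$age_range)
  lambda <- exp(alpha0 + cfg$gamma_age * age + cfg$gamma_acc * acc)
  counts <- pmin(stats::rpois(n, lambda), floor(0.2 * p))
  # a probe is a feasible target for a direction only if the outlier value
  # (fence + delta*IQR, fence pre-injection plus a buffer for the shift the
  # injection itself causes) stays inside [0, 1]
  q0 <- row_quartiles(beta)
  iqr0 <- q0[, 2] - q0[, 1]
  feas_hyper <- q0[, 2] + (3 + cfg$delta) * iqr0 <= 0.98 & iqr0 > 1e-6
  feas_hypo <- q0[, 1] - (3 + cfg$delta) * iqr0 >= 0.02 & iqr0 > 1e-6
  not_clock <- !(probe_ids %in% clock_probes)
  cand_hyper <- probe_ids[feas_hyper & not_clock]
  cand_hypo <- probe_ids[feas_hypo & not_clock]
  if (length(cand_hyper) < 10 || length(cand_hypo) < 10)
    stop("too few feasible probes for outlier placement; try a smaller `delta`")
  w_hyper <- cfg$hyper_context_weights[context[match(cand_hyper, probe_ids)]]
  w_hypo <- cfg$hypo_context_weights[context[match(cand_hypo, probe_ids)]]

  inj <- vector("list", n)
  for (i in seq_len(n)) {
    k <- counts[i]
    if (k == 0) next
    n_hyper <- stats::rbinom(1, k, cfg$hyper_fraction)
    ph <- if (n_hyper > 0) sample(cand_hyper, n_hyper, prob = w_hyper) else character(0)
    rest <- !(cand_hypo %in% ph)
    plo <- if (k - n_hyper > 0)
      sample(cand_hypo[rest], k - n_hyper, prob = w_hypo[rest]) else character(0)
    inj[[i]] <- data.frame(sample_id = sample_ids[i],
                           probe_id = c(ph, plo),
                           direction = rep(c("hyper", "hypo"),
                                           c(n_hyper, k - n_hyper)),
                           stringsAsFactors = FALSE)
  }
  truth_calls <- do.call(rbind, inj)
  if (is.null(truth_calls))
    truth_calls <- data.frame(sample_id = character(0), probe_id = character(0),
                              direction = character(0))

  if (nrow(truth_calls)) {
    ri <- match(truth_calls$probe_id, probe_ids)
    ci <- match(truth_calls$sample_id, sample_ids)
    is_hyper <- truth_calls$direction == "hyper"
    orig <- beta[cbind(ri, ci)]
    uri <- unique(ri)
    q <- q0
    delta <- cfg$delta
    converged <- FALSE
    for (it in 1:20) {
      # only probes that ever held an injection can move their quantiles
      if (it > 1) q[uri, ] <- row_quartiles(beta[uri, , drop = FALSE])
      iqr <- q[, 2] - q[, 1]
      up <- q[, 2] + 3 * iqr
      lo <- q[, 1] - 3 * iqr
      target <- ifelse(is_hyper,
                       up[ri] + delta * iqr[ri],
                       lo[ri] - delta * iqr[ri])
      # injections whose target drifted outside [0,1] (the injection itself
      # shifted the quantiles): restore the original cell and re-place the
      # outlier on another feasible probe for the same sample and direction
      bad <- which((is_hyper & target > 1) | (!is_hyper & target < 0))
      for (j in bad) {
        beta[ri[j], ci[j]] <- orig[j]
        used <- truth_calls$probe_id[truth_calls$sample_id ==
                                       truth_calls$sample_id[j]]
        pool <- setdiff(if (is_hyper[j]) cand_hyper else cand_hypo, used)
        pidx <- match(pool, probe_ids)
        ok <- if (is_hyper[j]) up[pidx] + delta * iqr[pidx] <= 0.98
              else lo[pidx] - delta * iqr[pidx] >= 0.02
        pool <- pool[ok]
        if (!length(pool))
          stop("infeasible outlier placement: no probe can absorb the ",
               "required exceedance; try a smaller `delta`")
        newp <- if (length(pool) == 1L) pool else sample(pool, 1L)
        truth_calls$probe_id[j] <- newp
        ri[j] <- match(newp, probe_ids)
        orig[j] <- beta[ri[j], ci[j]]
        target[j] <- if (is_hyper[j]) up[ri[j]] + delta * iqr[ri[j]]
                     else lo[ri[j]] - delta * iqr[ri[j]]
      }
      uri <- unique(c(uri, ri))
      cur <- beta[cbind(ri, ci)]
      need <- !ifelse(is_hyper,
                      cur > up[ri] + (1 - 1e-9) * delta * iqr[ri],
                      cur < lo[ri] - (1 - 1e-9) * delta * iqr[ri])
      if (!any(need)) { converged <- TRUE; break }
      beta[cbind(ri, ci)[need, , drop = FALSE]] <- target[need]
    }
    if (!converged) stop("outlier placement did not stabilise in 20 iterations")
    truth_calls$beta <- beta[cbind(ri, ci)]
  }

  # metadata: nothing but age and acc drives the load. The five reported
  # cell fractions are a subset of the full composition (B/NK/monocyte mass
  # is generated but not reported), so they do not sum to one and stay
  # jointly usable as covariates alongside an intercept.
  cells <- rdirichlet1(n, c(cfg$cell_dirichlet,
                            .other_B = 2, .other_NK = 2, .other_Mono = 3))
  cells <- cells[, names(cfg$cell_dirichlet), drop = FALSE]
  samples <- data.frame(
    sample_id = sample_ids,
    cohort = cfg$cohort,
    age = age,
    sex = sample(c("F", "M"), n, replace = TRUE),
    ethnicity = sample(c("white", "hispanic", "african_american"), n,
                       replace = TRUE, prob = c(0.5, 0.2, 0.3)),
    bmi = stats::rnorm(n, 27, 4),
    slide = sample(sprintf("slide%02d", seq_len(cfg$n_batches)), n,
                   replace = TRUE),
    bisulfite_control_intensity = stats::rnorm(n, 2000, 200),
    stringsAsFactors = FALSE)
  samples <- cbind(samples, as.data.frame(cells))

  # annotation: genes of ~3 probes each, manifest-style region groups
  gene_of <- paste0("g", formatC(ceiling(sample(seq_len(p)) / 3), width = 5,
                                 flag = "0"))
  groups <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR", "")
  g1 <- sample(groups, p, replace = TRUE,
               prob = c(0.15, 0.12, 0.08, 0.05, 0.35, 0.05, 0.20))
  g2 <- ifelse(stats::runif(p) < 0.10,
               sample(groups[-7], p, replace = TRUE), "")
  region <- ifelse(nzchar(g1) & nzchar(g2), paste(g1, g2, sep = ";"),
                   paste0(g1, g2))
  annot <- probe_annotation(
    probe_id = probe_ids,
    chromosome = sample(paste0("chr", 1:22), p, replace = TRUE),
    gene_region_group = region,
    gene = ifelse(nzchar(region), gene_of, ""),
    island_relation = ifelse(context == "OpenSea", "", context),
    enhancer = ifelse(stats::runif(p) < 0.15, "TRUE", ""),
    dhs = ifelse(stats::runif(p) < 0.10, "TRUE", ""),
    clock_lists = list(SimClock = clock_probes))

  structure(list(
    beta = beta_matrix(beta),
    samples = samples,
    annotation = annot,
    clock = clock,
    truth = list(calls = truth_calls, acc = stats::setNames(acc, sample_ids),
                 lambda = stats::setNames(lambda, sample_ids),
                 dnam_age = stats::setNames(dnam_age, sample_ids),
                 clock_probes = clock_probes),
    config = cfg), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort '%s': %d samples x %d probes, %d injected SEMs (seed %d)\n",
              x$config$cohort, ncol(x$beta), nrow(x$beta),
              nrow(x$truth$calls), x$config$seed))
  invisible(x)
}

#' Simulate several cohorts sharing effect parameters
#'
#' Cohorts may differ in size, age range and probe count (450K-like vs
#' EPIC-like) but share the age and acceleration effects, which is what a
#' meta-analysis rehearsal needs.
#'
#' @param configs list of at least two [sim_config()] objects.
#' @param gamma_age,gamma_acc optional shared values overriding each
#'   config's own.
#' @return list of `sim_cohort` objects.
#' @export
simulate_multicohort <- function(configs, gamma_age = NULL, gamma_acc = NULL) {
  stopifnot(is.list(configs), length(configs) >= 2,
            all(vapply(configs, inherits, logical(1), "sim_config")))
  lapply(configs, function(cfg) {
    if (!is.null(gamma_age)) cfg$gamma_age <- gamma_age
    if (!is.null(gamma_acc)) cfg$gamma_acc <- gamma_acc
    simulate_cohort(cfg)
  })
}

#' Write a simulated cohort to disk
#'
#' Writes `beta.tsv`, `samples.tsv`, `manifest.csv`, `clock.csv` and
#' `truth.tsv` in the formats the ingest functions read back.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  an <- cohort$annotation
  manifest <- data.frame(
    Name = an$probe_id,
    CHR = an$chromosome,
    UCSC_RefGene_Group = vapply(an$gene_region_groups, paste, character(1),
                                collapse = ";"),
    UCSC_RefGene_Name = vapply(an$genes, paste, character(1), collapse = ";"),
    Relation_to_UCSC_CpG_Island = ifelse(an$island_context == "OpenSea", "",
                                         an$island_context),
    Enhancer = vapply(an$regulatory_features, function(v)
      if ("Enhancer" %in% v) "TRUE" else "", character(1)),
    DHS = vapply(an$regulatory_features, function(v)
      if ("DHS" %in% v) "TRUE" else "", character(1)),
    Regulatory_Feature_Group = "",
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write_clock(cohort$clock, file.path(dir, "clock.csv"))
  utils::write.table(cohort$truth$calls, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
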