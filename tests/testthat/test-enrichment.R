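fake_callset <- function(call_df, sample_ids, probe_ids) {
  structure(list(calls = call_df, fences = NULL, k = 3,
                 sample_ids = sample_ids, probe_ids = probe_ids),
            class = "sem_calls")
}

test_that("hypergeometric enrichment matches small closed forms", {
  universe <- sprintf("p%02d", 1:10)
  sets <- probe_set_collection(list(inset = universe[1:4]), universe)
  calls <- fake_callset(
    data.frame(sample_id = "s1", probe_id = universe[1:3],
               direction = "hyper", beta = 0.9, stringsAsFactors = FALSE),
    sample_ids = c("s1", "s2"), probe_ids = universe)
  res <- sample_enrichment(calls, sets, alpha = 0.05)

  r1 <- res[res$sample_id == "s1", ]
  # N=10, K=4, n=3, k=3: C(4,3)/C(10,3) = 4/120
  expect_equal(r1$k, 3L)
  expect_equal(r1$p, 4 / 120, tolerance = 1e-12)
  expect_true(r1$significant)

  # sample with zero draws: p = 1, flagged
  r2 <- res[res$sample_id == "s2", ]
  expect_equal(r2$p, 1)
  expect_true(r2$no_draws)

  # set = universe: k = n, p = 1
  sets_all <- probe_set_collection(list(everything = universe), universe)
  res_all <- sample_enrichment(calls, sets_all)
  expect_equal(res_all$p[res_all$sample_id == "s1"], 1)

  # k = 0: full upper-tail mass = 1
  sets_miss <- probe_set_collection(list(disjoint = universe[8:10]), universe)
  res_miss <- sample_enrichment(calls, sets_miss)
  expect_equal(res_miss$p[res_miss$sample_id == "s1"], 1)
})

test_that("enrichment p equals exhaustive subset enumeration on a grid", {
  # spot-check the enumeration oracle across N, K, n, k combinations
  for (N in c(5, 8, 11)) {
    universe <- sprintf("u%02d", seq_len(N))
    for (K in c(1, 3, N - 1)) {
      for (n in c(1, 2, 4)) {
        if (n > N) next
        for (k in 0:min(n, K)) {
          want <- oracle_hyper_tail(N, K, n, k)
          got <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
          expect_equal(got, want, tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("enrichment p is monotone non-increasing in the overlap k", {
  for (N in c(10, 20)) for (K in c(4, 8)) for (n in c(3, 6)) {
    p <- phyper(seq(0, min(n, K)) - 1, K, N - K, n, lower.tail = FALSE)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("prevalence counts significant participants per set", {
  universe <- sprintf("p%03d", 1:100)
  target <- universe[1:5]
  sets <- probe_set_collection(list(target = target, rest = universe[50:90]),
                               universe)
  # 3 of 100 participants have all their SEMs forced into the target set
  picks <- lapply(1:100, function(i) {
    if (i <= 3) sample(target, 3) else sample(universe[10:40], 3)
  })
  set.seed(40)
  calls <- fake_callset(
    data.frame(sample_id = rep(sprintf("s%03d", 1:100), each = 3),
               probe_id = unlist(picks), direction = "hyper", beta = 0.9,
               stringsAsFactors = FALSE),
    sample_ids = sprintf("s%03d", 1:100), probe_ids = universe)
  prev <- enrichment_prevalence(sample_enrichment(calls, sets))
  expect_equal(prev$n_significant[prev$set_name == "target"], 3L)
  expect_equal(prev$n_tested[prev$set_name == "target"], 100L)

  # no significant rows: all zeros
  none <- sample_enrichment(calls, probe_set_collection(
    list(empty_hits = universe[95:100]), universe))
  expect_equal(sum(enrichment_prevalence(none)$n_significant), 0L)
})

test_that("under uniform SEM placement the significant fraction tracks alpha", {
  set.seed(41)
  universe <- sprintf("p%03d", 1:200)
  sets <- probe_set_collection(
    stats::setNames(lapply(1:10, function(i) sample(universe, 40)),
                    paste0("set", 1:10)), universe)
  n_subj <- 200
  calls <- fake_callset(
    data.frame(sample_id = rep(sprintf("s%03d", 1:n_subj), each = 10),
               probe_id = unlist(lapply(1:n_subj, function(i) sample(universe, 10))),
               direction = "hyper", beta = 0.9, stringsAsFactors = FALSE),
    sample_ids = sprintf("s%03d", 1:n_subj), probe_ids = universe)
  res <- sample_enrichment(calls, sets, alpha = 0.05)
  # discreteness makes the test conservative: fraction <= alpha, same order
  frac <- mean(res$significant)
  expect_lt(frac, 0.05 + 0.02)
  expect_gt(frac, 0.001)
})

test_that("pathway regression recovers a planted enrichment effect", {
  set.seed(42)
  n <- 500
  ind <- rbinom(n, 1, 0.3)
  log_eml <- rnorm(n, 7, 0.3)
  accel <- 2 * ind + 0.5 * log_eml + rnorm(n)
  enr <- data.frame(sample_id = sprintf("s%03d", 1:n), set_name = "pw1",
                    significant = ind == 1, stringsAsFactors = FALSE)
  pa <- pathway_association(accel, enr, log_eml,
                            sample_ids = sprintf("s%03d", 1:n))
  expect_true(pa$estimable)
  se <- 2 * 1 / sqrt(n)  # generous CI half-width
  expect_lt(abs(pa$beta1 - 2), 4 * se)
  expect_lt(pa$p_beta1, 1e-6)

  # constant indicator: inestimable, flagged
  enr0 <- transform(enr, significant = FALSE)
  pa0 <- pathway_association(accel, enr0, log_eml,
                             sample_ids = sprintf("s%03d", 1:n))
  expect_false(pa0$estimable)
  expect_true(is.na(pa0$beta1))
})

test_that("null pathway regressions give uniform p-values", {
  set.seed(43)
  n <- 120
  ps <- replicate(400, {
    ind <- rbinom(n, 1, 0.4)
    log_eml <- rnorm(n)
    accel <- 0.7 * log_eml + rnorm(n)  # no indicator effect
    enr <- data.frame(sample_id = seq_len(n), set_name = "x",
                      significant = ind == 1)
    pathway_association(accel, enr, log_eml, sample_ids = seq_len(n))$p_beta1
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("gene sets expand to probe sets through the annotation", {
  an <- probe_annotation(
    probe_id = c("cg1", "cg2", "cg3", "cg4"),
    gene = c("A", "A;B", "B", ""),
    island_relation = "Island")
  ps <- gene_sets_to_probe_sets(list(setA = "A", setAB = c("A", "B")), an)
  expect_setequal(ps$sets$setA, c("cg1", "cg2"))
  expect_setequal(ps$sets$setAB, c("cg1", "cg2", "cg3"))
  expect_warning(
    gene_sets_to_probe_sets(list(none = "ZZZ", setA = "A"), an),
    "map to no probes")

  # GMT round trip
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tA", "setAB\tdesc\tA\tB"), path)
  gs <- read_gmt(path)
  expect_equal(gs$setAB, c("A", "B"))
  ps2 <- gene_sets_to_probe_sets(gs, an)
  expect_equal(ps2$sets, ps$sets)
})

test_that("annotation-derived probe set collections cover the standard scans", {
  co <- simulate_cohort(sim_config(n_samples = 20, n_probes = 300, seed = 6,
                                   mean_eml = 2))
  sets <- annotation_probe_sets(co$annotation,
                                universe = rownames(co$beta))
  expect_true(any(startsWith(names(sets$sets), "region_")))
  expect_true("island_Island" %in% names(sets$sets))
  expect_true("clock_SimClock" %in% names(sets$sets))
  expect_equal(length(sets$sets$clock_SimClock), 30L)
  expect_true(all(vapply(sets$sets, function(s)
    all(s %in% sets$universe), logical(1))))
})
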