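#' Run the full SEM analysis pipeline from a config
#'
#' Orchestrates, per cohort: probe filtering, fence computation and SEM
#' calling, EML (total + region-specific), methylome entropy, clock
#' application and residual age acceleration, covariate-residualized
#' biweight-midcorrelation association — then combines the per-cohort rows
#' across cohorts with the Stouffer/Fisher-z meta-analysis, and optionally
#' runs per-participant enrichment. All intermediate tables are written as
#' TSV under `outdir`, plus a JSON run manifest (parameters, per-stage row
#' counts, file checksums) sufficient to re-run bit-identically.
#'
#' @param config path to a YAML file, or an equivalent named list, with
#'   fields: `cohorts` (list; each with `name`, `beta`, `samples`, and
#'   optionally `manifest`, `clock`, `detection_p`, `bead_counts`,
#'   `exclusion_lists` (named list of one-id-per-line files)), `outdir`,
#'   and optional `k` (default 3), `alpha` (0.05), `covariates`
#'   (character), `targets` (character; defaults to age plus every
#'   acceleration column), `group_by`, `sign_split`, `backtransform`,
#'   `gene_sets` (GMT path), `seed`.
#' @return the run manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$cohorts), !is.null(config$outdir))
  k <- config$k %||% 3
  alpha <- config$alpha %||% 0.05
  covariates <- config$covariates %||% character(0)
  if (!is.null(config$seed)) set.seed(config$seed)

  # validate every referenced file before any computation
  for (co in config$cohorts) {
    for (f in c("beta", "samples", "manifest", "clock", "detection_p",
                "bead_counts")) {
      if (!is.null(co[[f]]) && !file.exists(co[[f]]))
        stop("cohort '", co$name, "': file not found: ", co[[f]])
    }
    for (f in co$exclusion_lists)
      if (!file.exists(f)) stop("exclusion list not found: ", f)
    hdr <- names(utils::read.delim(co$samples, nrows = 1))
    missing_cov <- setdiff(covariates, hdr)
    if (length(missing_cov))
      stop("cohort '", co$name, "': covariate column(s) absent from samples: ",
           paste(missing_cov, collapse = ", "))
  }
  if (!is.null(config$gene_sets) && !file.exists(config$gene_sets))
    stop("gene_sets file not found: ", config$gene_sets)

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = config, stages = list())
  assoc_rows <- list()
  outfiles <- character(0)

  emit <- function(df, cohort, stage) {
    path <- file.path(config$outdir, paste0(cohort, "_", stage, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outfiles <<- c(outfiles, path)
    manifest$stages[[paste0(cohort, "_", stage)]] <<- list(rows = nrow(df))
    path
  }

  for (co in config$cohorts) {
    nm <- co$name %||% "cohort"
    message("[semload] cohort ", nm, ": ingest")
    beta <- read_beta_matrix(co$beta)
    samples <- utils::read.delim(co$samples, stringsAsFactors = FALSE)
    missing_cov <- setdiff(covariates, names(samples))
    if (length(missing_cov))
      stop("cohort '", nm, "': covariate column(s) absent from samples: ",
           paste(missing_cov, collapse = ", "))

    detp <- if (!is.null(co$detection_p))
      as.matrix(utils::read.delim(co$detection_p, row.names = 1,
                                  check.names = FALSE))
    beads <- if (!is.null(co$bead_counts))
      as.matrix(utils::read.delim(co$bead_counts, row.names = 1,
                                  check.names = FALSE))
    excl <- lapply(co$exclusion_lists %||% list(), readLines)
    if (!is.null(detp) || !is.null(beads) || length(excl)) {
      message("[semload] cohort ", nm, ": filter")
      fl <- filter_probes(beta, detp, beads, excl)
      beta <- fl$beta
      manifest$stages[[paste0(nm, "_filter")]] <-
        list(retained = fl$report$retained,
             removed_unique = fl$report$removed_unique,
             removed_per_rule = as.list(fl$report$removed_per_rule))
    }

    message("[semload] cohort ", nm, ": call SEMs (k = ", k, ")")
    fences <- compute_fences(beta, k = k)
    calls <- call_sems(beta, fences)
    emit(calls$calls, nm, "calls")
    emit(as.data.frame(fences), nm, "fences")

    annot <- if (!is.null(co$manifest)) read_annotation(co$manifest)
    eml <- if (is.null(annot)) compute_eml(calls) else {
      e <- region_emls(calls, annot)
      e$log_eml <- ifelse(e$eml > 0, log(e$eml), NA_real_)
      e
    }
    emit(eml, nm, "eml")

    message("[semload] cohort ", nm, ": entropy")
    entropy <- methylome_entropy(beta)
    emit(entropy, nm, "entropy")

    dat <- merge(merge(samples, eml, by = "sample_id"),
                 entropy[, c("sample_id", "entropy")], by = "sample_id")
    accel_cols <- character(0)
    if (!is.null(co$clock)) {
      message("[semload] cohort ", nm, ": clock + acceleration")
      clock <- read_clock(co$clock)
      dnam <- apply_linear_clock(beta, clock, missing_policy = "mean-impute")
      dat[[paste0("dnamage_", clock$name)]] <- dnam[dat$sample_id]
      ac <- age_acceleration(dat[[paste0("dnamage_", clock$name)]], dat$age)
      accel_cols <- paste0("accel_", clock$name)
      dat[[accel_cols]] <- ac
      emit(dat[, c("sample_id", "age", paste0("dnamage_", clock$name),
                   accel_cols)], nm, "accel")
    }

    targets <- config$targets %||% c("age", accel_cols)
    targets <- intersect(targets, names(dat))
    message("[semload] cohort ", nm, ": association")
    assoc <- cohort_association(dat, outcome = "log_eml", targets = targets,
                                covariates = covariates,
                                group_by = config$group_by,
                                sign_split = config$sign_split, cohort = nm)
    emit(assoc, nm, "assoc")
    assoc_rows[[nm]] <- assoc

    if (!is.null(config$gene_sets) && !is.null(annot)) {
      message("[semload] cohort ", nm, ": enrichment")
      sets <- gene_sets_to_probe_sets(read_gmt(config$gene_sets), annot,
                                      universe = rownames(beta))
      enr <- sample_enrichment(calls, sets, alpha = alpha)
      emit(enrichment_prevalence(enr), nm, "enrichment_prevalence")
    }
  }

  message("[semload] meta-analysis")
  all_assoc <- do.call(rbind, assoc_rows)
  meta <- lapply(split(all_assoc, list(all_assoc$variable_y,
                                       all_assoc$stratum), drop = TRUE),
                 function(rows) {
    rows <- rows[!is.na(rows$r), , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    m <- stouffer_meta(rows, backtransform = isTRUE(config$backtransform))
    data.frame(variable = rows$variable_y[1L], stratum = rows$stratum[1L],
               meta_r = m$meta_r, meta_p = m$meta_p, total_n = m$total_n,
               n_cohorts = nrow(rows), stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta)
  if (!is.null(meta)) {
    rownames(meta) <- NULL
    path <- file.path(config$outdir, "meta.tsv")
    utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outfiles <- c(outfiles, path)
  }

  manifest$checksums <- as.list(tools::md5sum(sort(outfiles)))
  manifest$r_version <- R.version.string
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
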