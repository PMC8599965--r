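# End-to-end pipeline: simulate (or load) a cohort, quality control, HMM
# state dynamics, multiscale entropy, wavelet-correlation graph topology, and
# group statistics, from a single JSON configuration with a run manifest.

#' Read a subject timecourse table
#'
#' Tab-delimited, header row of channel names, one column per channel.
#'
#' @param path File path.
#' @return Numeric matrix (timepoints x channels).
#' @export
io_read_timeseries <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  m
}

#' Write a table as TSV
#'
#' Tab-delimited with header, full double precision, `NA` markers preserved;
#' [io_read_timeseries()] and [read.delim()] round-trip the values exactly.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
io_write_table <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  df[num] <- lapply(df[num], function(v) ifelse(v == "NA" | v == "nan", NA, v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All pipeline parameters with their defaults; any subset can be overridden
#' via a JSON file or a list. Every random stage draws its seed from the
#' top-level `seed`.
#'
#' @param ... Named overrides (nested lists are merged shallowly per section).
#' @return Nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    outdir = NULL,
    stages = c("simulate", "qc", "hmm", "entropy", "graph", "stats"),
    simulate = list(n_control = 22, n_case = 24, n_channels = 30,
                    n_timepoints = 305, TR = 2, K = 8, delta = 0.1,
                    severity_loading = 0.6, structural_loading = 0.3,
                    outlier_fraction = 0),
    qc = list(exclude = TRUE),
    hmm = list(K = 8, n_restarts = 3, tol = 1e-6, max_iter = 200,
               fo_from = "gamma"),
    entropy = list(m = 1, r = 0.35, S = NULL),
    graph = list(level = 2, filter = "d4", density = 0.05, n_null = 1000),
    stats = list(n_perm = 10000)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  }
  cfg
}

#' Read and validate a run configuration
#'
#' @param path JSON file of overrides to [default_config()].
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  ov <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                 error = function(e) config_error("malformed config JSON: ",
                                                  conditionMessage(e)))
  cfg <- do.call(default_config, as.list(ov))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    config_error("seed must be a single integer")
  bad <- setdiff(cfg$stages, c("simulate", "qc", "hmm", "entropy", "graph", "stats"))
  if (length(bad)) config_error("unknown stage(s): ", paste(bad, collapse = ", "))
  with(cfg$graph, {
    if (density <= 0 || density > 1) config_error("graph density must be in (0,1]")
    if (n_null < 1) config_error("n_null must be positive")
  })
  if (cfg$stats$n_perm < 1) config_error("n_perm must be positive")
  if (cfg$entropy$r <= 0 || cfg$entropy$m < 1) config_error("invalid entropy parameters")
  cfg
}

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("dynconn_config_error", "error")))
}

stage_error <- function(stage, e) {
  stop(errorCondition(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                      class = c("dynconn_stage_error", "error")))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate` (synthetic
#' cohort generation), `qc` (quality metrics, 1-SD exclusion, motion
#' covariate), `hmm` (state inference and temporal metrics), `entropy`
#' (subject multiscale entropy), `graph` (wavelet-correlation topology with
#' null normalization), and `stats` (occupancy-component group analysis and
#' permutation GLMs on switching rate and entropy). Excluded subjects are
#' removed before modelling and the motion covariate enters every design
#' matrix. Results tables are written under `outdir` (when set) together with
#' a manifest (config hash, package version, per-file checksums, wall times,
#' warnings).
#'
#' @param config A configuration list from [default_config()] /
#'   [read_run_config()], or a path to a JSON config.
#' @param cohort Optionally, a pre-built [simulate_cohort()] object to analyse
#'   instead of simulating (the `simulate` stage is then skipped).
#' @return List with the per-stage results and the `manifest`.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  times <- list()
  warns <- character(0)
  files <- character(0)
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(fn(), error = function(e) stage_error(stage, e)),
      warning = function(w) {
        warns <<- c(warns, sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    times[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  emit <- function(x, name) {
    if (is.null(outdir)) return(invisible(NULL))
    p <- file.path(outdir, name)
    io_write_table(x, p)
    files <<- c(files, p)
  }
  stages <- config$stages

  if (is.null(cohort)) {
    cohort <- run_stage("simulate", function() {
      sp <- do.call(cohort_spec, c(config$simulate, list(seed = config$seed)))
      simulate_cohort(sp)
    })
  }
  res$cohort <- cohort
  keep <- rep(TRUE, length(cohort$timeseries))
  covs <- cohort$covariates

  if ("qc" %in% stages) {
    res$qc <- run_stage("qc", function() {
      mets <- cohort$qc$metrics[, -1, drop = FALSE]
      excl <- exclusion_rule(mets)
      list(exclusion = excl, motion = motion_covariate(mets))
    })
    covs$motion <- res$qc$motion
    if (isTRUE(config$qc$exclude)) keep <- !res$qc$exclusion$excluded
    emit(cbind(res$qc$exclusion$report,
               motion = res$qc$motion), "qc_report.tsv")
  }
  series <- cohort$timeseries[keep]
  covs <- covs[keep, , drop = FALSE]

  if ("hmm" %in% stages) {
    res$hmm <- run_stage("hmm", function() {
      fit <- fit_hmm(series, K = config$hmm$K,
                     n_restarts = config$hmm$n_restarts,
                     tol = config$hmm$tol, max_iter = config$hmm$max_iter,
                     seed = config$seed)
      sm <- state_metrics(fit, fo_from = config$hmm$fo_from)
      list(fit = fit, metrics = sm)
    })
    sm <- res$hmm$metrics
    tab <- data.frame(subject_id = covs$subject_id, sm$fo,
                      switching_rate = sm$switching_rate)
    emit(tab, "state_metrics.tsv")
  }

  if ("entropy" %in% stages) {
    res$entropy <- run_stage("entropy", function() {
      prm <- entropy_params(nrow(series[[1]]), m = config$entropy$m,
                            r = config$entropy$r, S = config$entropy$S)
      mse <- vapply(series, function(x)
        subject_mse(scale(x), prm)$subject_mse, 1)
      list(params = prm, mse = mse)
    })
    emit(data.frame(subject_id = covs$subject_id, mse = res$entropy$mse),
         "entropy.tsv")
  }

  if ("graph" %in% stages) {
    res$graph <- run_stage("graph", function() {
      g <- lapply(seq_along(series), function(i) {
        R <- wavelet_correlation_matrix(series[[i]], level = config$graph$level,
                                        filter = config$graph$filter,
                                        TR = cohort$spec$TR)
        graph_metrics(R, density = config$graph$density,
                      n_null = config$graph$n_null, seed = config$seed + i)
      })
      data.frame(subject_id = covs$subject_id,
                 mean_weighted_degree = vapply(g, function(m) mean(m$weighted_degree), 1),
                 clustering_normalized = vapply(g, `[[`, 1, "clustering_normalized"),
                 path_length_normalized = vapply(g, `[[`, 1, "path_length_normalized"))
    })
    emit(res$graph, "graph_metrics.tsv")
  }

  if ("stats" %in% stages) {
    if (is.null(res$hmm)) config_error("stats stage requires the hmm stage")
    res$stats <- run_stage("stats", function() {
      sm <- res$hmm$metrics
      fo_res <- fo_group_analysis(sm$fo, covs, case_level = "case",
                                  n_perm = config$stats$n_perm,
                                  seed = config$seed)
      nuis <- intersect(c("age", "sex", "motion"), names(covs))
      X <- cbind(intercept = 1, group = as.numeric(covs$group == "case"))
      for (v in nuis) X <- cbind(X, as.numeric(covs[[v]]))
      colnames(X) <- c("intercept", "group", nuis)
      extra <- cbind(switching_rate = sm$switching_rate)
      if (!is.null(res$entropy)) extra <- cbind(extra, mse = res$entropy$mse)
      glm_extra <- permutation_glm(extra, X, contrasts = "group",
                                   n_perm = config$stats$n_perm,
                                   seed = config$seed + 1L)
      list(fo = fo_res, other = glm_extra)
    })
    emit(rbind(res$stats$fo$glm, res$stats$other), "glm_results.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dynconn")),
    config_hash = config_hash(config),
    stages = stages,
    wall_times_sec = as.list(round(unlist(times), 3)),
    warnings = warns,
    files = if (length(files))
      as.list(tools::md5sum(files)) else list()
  )
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
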