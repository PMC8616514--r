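# End-to-end pipeline: simulate (or ingest) -> extract QIBs -> screen ->
# fit clinical baselines -> extend by AIC backward elimination ->
# nested LR comparison -> risk stratification -> reports.

#' Pipeline configuration
#'
#' One object configures every stage. All randomness flows from the
#' single root `seed` through named child streams (phantoms, clinical,
#' survival), so changing e.g. the radiomics settings cannot perturb the
#' survival simulation.
#'
#' @param seed root seed.
#' @param phantom a [phantom_config()]; its `seed` is overridden by a
#'   child of the root seed.
#' @param survival_sim a [survival_sim_config()]; seed overridden
#'   likewise.
#' @param disc a [discretization_config()].
#' @param wcfg a [wavelet_config()].
#' @param baselines which clinical baseline models to fit and extend:
#'   subset of `c("haas", "xue")`.
#' @param screen_alpha univariable screening threshold (Wald p).
#' @param correlation_method `"spearman"` (default) or `"pearson"`.
#' @param write_volumes also write the NIfTI volumes when running the
#'   pipeline to a directory (tables are always written).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            phantom = phantom_config(),
                            survival_sim = survival_sim_config(),
                            disc = discretization_config(),
                            wcfg = wavelet_config(),
                            baselines = c("haas", "xue"),
                            screen_alpha = 0.2,
                            correlation_method = "spearman",
                            write_volumes = FALSE) {
  stopifnot(all(baselines %in% c("haas", "xue")), length(baselines) >= 1L)
  phantom$seed <- child_seed(seed, "phantom-stream")
  survival_sim$seed <- child_seed(seed, "survival-stream")
  structure(list(seed = as.integer(seed), phantom = phantom,
                 survival_sim = survival_sim, disc = disc, wcfg = wcfg,
                 baselines = baselines, screen_alpha = screen_alpha,
                 correlation_method = correlation_method,
                 write_volumes = write_volumes),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors the nested structure of [pipeline_config()]:
#' top-level keys `seed`, `baselines`, `screen_alpha`,
#' `correlation_method`, `write_volumes` plus blocks `phantom`,
#' `survival_sim`, `radiomics` (fields `bin_width`, `aggregation`,
#' `wavelet_family`, `wavelet_subband`). Missing keys take the package
#' defaults.
#'
#' @param path YAML file.
#' @param seed optional root-seed override.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  seed <- seed %||% y$seed %||% 1L
  ph <- do.call(phantom_config, y$phantom %||% list())
  sv <- y$survival_sim %||% list()
  if (!is.null(sv$beta)) sv$beta <- unlist(sv$beta)
  sv <- do.call(survival_sim_config, sv)
  rad <- y$radiomics %||% list()
  disc <- discretization_config(bin_width = rad$bin_width %||% 25,
                                aggregation = rad$aggregation %||% "merge")
  wcfg <- wavelet_config(family = rad$wavelet_family %||% "coif1",
                         subband = rad$wavelet_subband %||% "HLH")
  pipeline_config(seed = seed, phantom = ph, survival_sim = sv,
                  disc = disc, wcfg = wcfg,
                  baselines = y$baselines %||% c("haas", "xue"),
                  screen_alpha = y$screen_alpha %||% 0.2,
                  correlation_method = y$correlation_method %||% "spearman",
                  write_volumes = isTRUE(y$write_volumes))
}

#' Simulate a phantom cohort and its feature table
#'
#' Generates every subject of the configured phantom cohort, extracts
#' the 13-feature QIB vector per subject, simulates clinical covariates,
#' and simulates survival whose hazard is driven by the configured
#' coefficients over the extracted features and clinical covariates.
#'
#' @param config a [pipeline_config()].
#' @param keep_volumes keep the image/segmentation pairs in the result
#'   (memory permitting); otherwise only tables are returned.
#' @return list with `features` (data.frame, `subject_id` + 13 QIBs),
#'   `clinical` (incl. `time_months`, `event`) and optionally
#'   `volumes`.
#' @export
simulate_cohort <- function(config, keep_volumes = FALSE) {
  n <- config$phantom$subjects
  volumes <- if (keep_volumes) vector("list", n) else NULL
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(config$phantom, i)
    feats[[i]] <- extract_qib(ph$image, ph$seg,
                              disc = config$disc, wcfg = config$wcfg)
    if (keep_volumes) volumes[[i]] <- ph
  }
  features <- do.call(rbind, feats)
  features <- cbind(subject_id = sprintf("S%03d", seq_len(n)), features)
  clinical <- simulate_clinical(n, seed = config$seed)
  surv <- simulate_survival(cbind(features, clinical[-1]),
                            config$survival_sim)
  clinical$time_months <- surv$time_months
  clinical$event <- surv$event
  out <- list(features = features, clinical = clinical)
  if (keep_volumes) out$volumes <- volumes
  out
}

#' Run the full analysis on a feature + clinical table
#'
#' The modeling stages shared by the simulated and ingested entry
#' points: univariable screening, clinical baseline fits, AIC backward
#' elimination with forced-in clinical terms, nested LR comparison, and
#' median-split risk stratification per baseline.
#'
#' @param features data.frame with `subject_id` and the QIB columns.
#' @param clinical data.frame with `subject_id`, clinical covariates and
#'   the outcome (`time_months`, `event`), joined to `features` on
#'   `subject_id`.
#' @param config a [pipeline_config()].
#' @return list with `screen`, and per baseline a list `baseline`,
#'   `extension`, `comparison`, `stratification`; plus `correlation`.
#' @export
run_analysis <- function(features, clinical, config = pipeline_config()) {
  stopifnot("subject_id" %in% names(features),
            "subject_id" %in% names(clinical))
  tab <- merge(features, clinical, by = "subject_id", sort = TRUE)
  cc <- stats::complete.cases(tab)
  if (any(!cc))
    warning(sum(!cc), " subject(s) dropped (incomplete records)")
  tab <- tab[cc, ]
  time <- tab$time_months
  event <- tab$event
  qib <- tab[intersect(qib_feature_names(), names(tab))]

  screen <- univariable_screen(qib, time, event, alpha = config$screen_alpha)
  models <- list()
  for (b in config$baselines) {
    bdes <- if (b == "haas") haas_design(tab) else xue_design(tab)
    bfit <- fit_cox(bdes, time, event)
    cand_tab <- qib[screen$candidates]
    ext <- extend_model(bdes, cand_tab, time, event)
    cmp <- compare_nested(bfit, ext$fit)
    strat <- stratify_risk(ext$fit, cbind(bdes, cand_tab)[ext$fit$terms$name],
                           time, event)
    models[[b]] <- list(baseline = bfit, extension = ext, comparison = cmp,
                        stratification = strat)
  }
  corr <- correlation_report(
    qib, tab[c("ecog", "crp_mg_dl", "bilirubin_mg_dl", "ca19_9_u_ml")],
    method = config$correlation_method)
  list(screen = screen, models = models, correlation = corr,
       table = tab, time = time, event = event)
}

#' Run the whole pipeline and write its reports
#'
#' Simulation -> extraction -> modeling -> reports, with a JSON run
#' manifest. All CSVs have a fixed column order and locale so repeated
#' runs with the same configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; created if missing. `NULL` runs the
#'   pipeline without writing files.
#' @return invisibly, a list with all stage results (`cohort`,
#'   `analysis`) and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  warn <- character(0)
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  timings <- c()
  cohort <- wh(simulate_cohort(config, keep_volumes = config$write_volumes))
  timings["simulate_extract"] <- proc.time()[["elapsed"]] - t0

  t1 <- proc.time()[["elapsed"]]
  analysis <- wh(run_analysis(cohort$features, cohort$clinical, config))
  timings["model"] <- proc.time()[["elapsed"]] - t1

  outputs <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
    num <- function(df) {                 # stable rounding for diffable CSVs
      df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 10) else x)
      df
    }
    write_table_csv(num(cohort$features), file.path(out_dir, "features.csv"))
    write_table_csv(num(cohort$clinical), file.path(out_dir, "clinical.csv"))
    write_table_csv(num(analysis$screen$report),
                    file.path(out_dir, "table2.csv"))
    write_table_csv(num(table3_frame(analysis)),
                    file.path(out_dir, "table3.csv"))
    strat_df <- data.frame(subject_id = analysis$table$subject_id)
    for (b in names(analysis$models))
      strat_df[[paste0("risk_group_", b)]] <-
        as.character(analysis$models[[b]]$stratification$group)
    write_table_csv(strat_df, file.path(out_dir, "stratification.csv"))
    for (b in names(analysis$models))
      plot_km(analysis$models[[b]]$stratification,
              file = file.path(out_dir, paste0("km_", b, ".png")),
              main = paste("Extended model,", b, "baseline"))
    plot_correlation_heatmap(analysis$correlation,
                             file = file.path(out_dir, "correlation.png"))
    outputs <- list.files(out_dir)
    if (config$write_volumes)
      write_cohort(file.path(out_dir, "cohort"), cohort$volumes,
                   cohort$clinical, seed = config$seed, config = config)
  }
  manifest <- list(
    package = "wltb",
    version = pkg_version(),
    seed = config$seed,
    config_hash = config_hash(config),
    n_subjects = config$phantom$subjects,
    n_analyzed = nrow(analysis$table),
    stage_seconds = as.list(round(timings, 2)),
    outputs = outputs,
    warnings = warn)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, analysis = analysis, manifest = manifest))
}

# long-format multivariable report: baseline and extended fits per
# clinical baseline, with C-index and LR p on the extended rows
table3_frame <- function(analysis) {
  rows <- list()
  for (b in names(analysis$models)) {
    m <- analysis$models[[b]]
    for (kind in c("baseline", "extended")) {
      ft <- if (kind == "baseline") m$baseline else m$extension$fit
      tr <- ft$terms
      rows[[paste(b, kind)]] <- data.frame(
        model = paste0(kind, "_", b),
        term = tr$name, hr = tr$hr, hr_lo = tr$hr_lo, hr_hi = tr$hr_hi,
        wald_p = tr$wald_p, c_index = ft$c_index,
        lr_p = if (kind == "extended") m$comparison$p_value else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
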