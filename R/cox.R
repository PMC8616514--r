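# Survival modeling stage: Cox fits with Wald reports and concordance,
# univariable screening of imaging features, the two clinical baseline
# models, AIC backward elimination with forced-in clinical terms, nested
# likelihood-ratio comparison, and median-split risk stratification.

#' Fit a Cox proportional-hazards model with a tidy report
#'
#' Wraps [survival::coxph()] (Efron tie handling) and returns the
#' coefficient table in the layout of a published univariable/
#' multivariable report: hazard ratio, 95% CI and Wald p per term, plus
#' log partial likelihood, AIC and Harrell's concordance index.
#'
#' @param covariates data.frame of numeric/logical covariate columns.
#' @param time numeric survival times (months).
#' @param event 0/1 event indicator (1 = death observed).
#' @return object of class `cox_fit`: list with `terms` (data.frame
#'   `name`, `coefficient`, `se`, `hr`, `hr_lo`, `hr_hi`, `wald_p`),
#'   `loglik`, `aic`, `c_index`, `n`, `n_events`, and the underlying
#'   `fit`.
#' @export
fit_cox <- function(covariates, time, event) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(time),
            length(time) == length(event))
  if (sum(event) < 2L) stop("need at least 2 events")
  dat <- as.data.frame(lapply(covariates, function(x) {
    if (is.logical(x)) as.numeric(x) else x
  }))
  const <- vapply(dat, function(x) length(unique(x)) < 2L, TRUE)
  if (any(const))
    stop("constant covariate(s): ", paste(names(dat)[const], collapse = ", "))
  dat$.time <- time
  dat$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", setdiff(names(dat), c(".time", ".event"))),
          collapse = " + ")))
  fit_warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron", x = TRUE),
    warning = function(w) {
      fit_warn <<- c(fit_warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("Ran out of iterations", fit_warn)) &&
      !all(is.finite(fit$loglik)))
    stop("Cox fit did not converge: ",
         paste(fit_warn, collapse = "; "))
  co <- stats::coef(fit)
  if (any(is.na(co)))
    stop("singular design: ",
         paste(gsub("`", "", names(co)[is.na(co)]), collapse = ", "))
  se <- sqrt(diag(stats::vcov(fit)))
  # monotone partial likelihood (coxph's own diagnostics) = separation;
  # flagged, never silently returned
  if (any(!is.finite(se)) ||
      any(grepl("infinite|Ran out of iterations", fit_warn)))
    warning("possible complete separation: ",
            paste(unique(fit_warn), collapse = "; "))
  z <- co / se
  terms <- data.frame(
    name = gsub("`", "", names(co)),
    coefficient = unname(co), se = unname(se),
    hr = exp(unname(co)),
    hr_lo = exp(unname(co - 1.96 * se)),
    hr_hi = exp(unname(co + 1.96 * se)),
    wald_p = unname(2 * stats::pnorm(-abs(z))))
  structure(list(terms = terms,
                 loglik = fit$loglik[2],
                 aic = 2 * length(co) - 2 * fit$loglik[2],
                 c_index = unname(survival::concordance(fit)$concordance),
                 n = fit$n, n_events = fit$nevent,
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n =", x$n, ", events =", x$n_events,
      ", C-index =", round(x$c_index, 3), ", AIC =", round(x$aic, 1), "\n")
  df <- x$terms
  df[-1] <- lapply(df[-1], signif, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Univariable screening of imaging features
#'
#' One unadjusted Cox model per feature; features with Wald p below
#' `alpha` (default 0.2) become candidates for the combined models. A
#' feature whose fit fails is excluded with a warning, not an error.
#'
#' @param feature_table data.frame of imaging features (numeric/logical
#'   columns; non-numeric columns are ignored).
#' @param time,event survival outcome.
#' @param alpha screening threshold on the Wald p-value.
#' @return list with `report` (one row per feature: `feature`,
#'   `coefficient`, `hr`, `hr_lo`, `hr_hi`, `wald_p`, `candidate`),
#'   `candidates` (character vector), and `fits` (named list of
#'   `cox_fit`).
#' @export
univariable_screen <- function(feature_table, time, event, alpha = 0.2) {
  keep <- vapply(feature_table,
                 function(x) is.numeric(x) || is.logical(x), TRUE)
  feats <- names(feature_table)[keep]
  rows <- list(); fits <- list()
  for (f in feats) {
    ft <- tryCatch(
      fit_cox(stats::setNames(feature_table[f], f), time, event),
      error = function(e) {
        warning("screening fit failed for '", f, "': ", conditionMessage(e))
        NULL
      })
    if (is.null(ft)) next
    tr <- ft$terms[1, ]
    rows[[f]] <- data.frame(feature = f, coefficient = tr$coefficient,
                            hr = tr$hr, hr_lo = tr$hr_lo, hr_hi = tr$hr_hi,
                            wald_p = tr$wald_p,
                            candidate = tr$wald_p < alpha)
    fits[[f]] <- ft
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(report = report,
       candidates = report$feature[report$candidate],
       fits = fits)
}

# epsilon-offset log transform for lab values that can be reported as 0
safe_log <- function(x, what) {
  if (any(x <= 0)) {
    warning(sum(x <= 0), " nonpositive ", what,
            " value(s); epsilon offset applied before log")
    x <- pmax(x, 1e-6)
  }
  log(x)
}

#' Design matrix of the first clinical baseline model
#'
#' Performance status dichotomized as ECOG 0 vs >= 1, plus the natural
#' logarithms of CRP (mg/dl) and bilirubin (mg/dl).
#'
#' @param clinical data.frame with `ecog`, `crp_mg_dl`,
#'   `bilirubin_mg_dl`.
#' @return data.frame with columns `ecog_1plus`, `log_crp`,
#'   `log_bilirubin`.
#' @export
haas_design <- function(clinical) {
  data.frame(ecog_1plus = as.numeric(clinical$ecog >= 1),
             log_crp = safe_log(clinical$crp_mg_dl, "CRP"),
             log_bilirubin = safe_log(clinical$bilirubin_mg_dl, "bilirubin"))
}

#' Design matrix of the second clinical baseline model
#'
#' Three binary indicators: ECOG >= 2, CA19-9 >= 1000 U/ml, CRP >= 5.
#' Thresholds are inclusive. The CRP threshold value (and hence its
#' implied unit) is exposed because published variants state it in mg/l
#' while reporting it against mg/dl-scaled data; the default is 5 on the
#' mg/dl scale used throughout this package.
#'
#' @param clinical data.frame with `ecog`, `ca19_9_u_ml`, `crp_mg_dl`.
#' @param crp_threshold CRP cutoff on the mg/dl scale (default 5).
#' @return data.frame with columns `ecog_2plus`, `ca19_9_ge_1000`,
#'   `crp_ge_threshold`.
#' @export
xue_design <- function(clinical, crp_threshold = 5) {
  data.frame(ecog_2plus = as.numeric(clinical$ecog >= 2),
             ca19_9_ge_1000 = as.numeric(clinical$ca19_9_u_ml >= 1000),
             crp_ge_threshold = as.numeric(clinical$crp_mg_dl >= crp_threshold))
}

#' Fit a clinical baseline Cox model
#'
#' @param clinical data.frame of clinical covariates (see
#'   [haas_design()] / [xue_design()]).
#' @param time,event survival outcome.
#' @param crp_threshold CRP cutoff for the `"xue"` design.
#' @return a `cox_fit`.
#' @name baseline_models
NULL

#' @rdname baseline_models
#' @export
baseline_model_haas <- function(clinical, time, event) {
  fit_cox(haas_design(clinical), time, event)
}

#' @rdname baseline_models
#' @export
baseline_model_xue <- function(clinical, time, event, crp_threshold = 5) {
  fit_cox(xue_design(clinical, crp_threshold), time, event)
}

#' Extend a clinical baseline with imaging features by AIC backward
#' elimination
#'
#' Starts from baseline terms plus all screened candidates and
#' iteratively removes the single candidate whose removal most decreases
#' the AIC, stopping when no removal decreases it. The clinical baseline
#' terms are forced in (never eligible for removal) so that the final
#' model stays nested above the baseline for the likelihood-ratio
#' comparison. AIC ties between two removable features are broken by
#' removing the one with the larger Wald p (deterministic, recorded in
#' the trace).
#'
#' @param baseline_design data.frame of forced-in clinical terms.
#' @param candidate_table data.frame of candidate imaging features
#'   (typically the screened subset of the QIB table). May have zero
#'   columns, in which case the baseline fit is returned unchanged.
#' @param time,event survival outcome.
#' @return list with `fit` (final `cox_fit`), `kept` (character vector
#'   of retained candidates) and `trace` (data.frame: `step`, `removed`,
#'   `aic_before`, `aic_after`).
#' @export
extend_model <- function(baseline_design, candidate_table, time, event) {
  trace <- data.frame(step = integer(0), removed = character(0),
                      aic_before = numeric(0), aic_after = numeric(0))
  cand <- names(candidate_table)
  if (length(cand) == 0L) {
    return(list(fit = fit_cox(baseline_design, time, event),
                kept = character(0), trace = trace))
  }
  # candidates collinear with the running design cannot enter the start
  # model; drop them up front (greedy, in given order) with a warning
  num <- function(df) vapply(df, function(x) as.numeric(x), numeric(nrow(df)))
  base_m <- num(baseline_design)
  keep <- character(0)
  for (f in cand) {
    m <- cbind(base_m, num(candidate_table[c(keep, f)]))
    if (qr(scale(m))$rank == ncol(m)) keep <- c(keep, f)
    else warning("candidate '", f, "' dropped: collinear with the design")
  }
  cand <- keep
  if (length(cand) == 0L) {
    return(list(fit = fit_cox(baseline_design, time, event),
                kept = character(0), trace = trace))
  }
  design <- cbind(baseline_design, candidate_table[cand])
  current <- fit_cox(design, time, event)
  step <- 0L
  repeat {
    if (length(cand) == 0L) break
    aics <- rep(NA_real_, length(cand))
    fits <- vector("list", length(cand))
    for (i in seq_along(cand)) {
      sub <- design[, setdiff(names(design), cand[i]), drop = FALSE]
      ft <- tryCatch(fit_cox(sub, time, event), error = function(e) NULL)
      if (is.null(ft)) next                # non-convergence: skip this drop
      aics[i] <- ft$aic
      fits[[i]] <- ft
    }
    improving <- which(!is.na(aics) & aics < current$aic - 1e-9)
    if (!length(improving)) break
    best_aic <- min(aics[improving])
    tied <- improving[aics[improving] <= best_aic + 1e-9]
    if (length(tied) > 1L) {
      wp <- vapply(cand[tied], function(f) {
        current$terms$wald_p[current$terms$name == f]
      }, 0)
      drop_i <- tied[which.max(wp)]
    } else drop_i <- tied
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = cand[drop_i],
                                     aic_before = current$aic,
                                     aic_after = aics[drop_i]))
    design <- design[, setdiff(names(design), cand[drop_i]), drop = FALSE]
    current <- fits[[drop_i]]
    cand <- cand[-drop_i]
  }
  list(fit = current, kept = cand, trace = trace)
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' The LR test requires nesting: every term of the baseline must appear
#' in the extended model and both must be fitted on the same subjects.
#' LR = 2 (l_ext - l_base), p from a chi-square with df = difference in
#' parameter count.
#'
#' @param baseline,extended `cox_fit` objects.
#' @return object of class `model_comparison`: list with `lr_statistic`,
#'   `df`, `p_value`, `baseline_c_index`, `extended_c_index`.
#' @export
compare_nested <- function(baseline, extended) {
  stopifnot(inherits(baseline, "cox_fit"), inherits(extended, "cox_fit"))
  if (!all(baseline$terms$name %in% extended$terms$name))
    stop("models are not nested: baseline terms missing from the extended model")
  if (baseline$n != extended$n || baseline$n_events != extended$n_events)
    stop("models were fitted on different subjects")
  df <- nrow(extended$terms) - nrow(baseline$terms)
  lr <- 2 * (extended$loglik - baseline$loglik)
  p <- if (df == 0L) 1 else stats::pchisq(lr, df = df, lower.tail = FALSE)
  structure(list(lr_statistic = lr, df = df, p_value = p,
                 baseline_c_index = baseline$c_index,
                 extended_c_index = extended$c_index),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> LR =", round(x$lr_statistic, 3), "on", x$df,
      "df, p =", format.pval(x$p_value, digits = 3),
      "; C-index", round(x$baseline_c_index, 3), "->",
      round(x$extended_c_index, 3), "\n")
  invisible(x)
}

#' Median-split risk stratification with Kaplan-Meier comparison
#'
#' Computes the linear predictor of the fitted model per subject, splits
#' the cohort at its median into high- and low-risk groups, and compares
#' the groups by Kaplan-Meier curves and the two-sided log-rank test.
#' `split = "predicted_survival"` instead classifies subjects by whether
#' their model-predicted median survival exceeds the cohort's observed
#' median survival.
#'
#' @param fit a `cox_fit`.
#' @param covariates data.frame with the model's covariate columns.
#' @param time,event survival outcome.
#' @param split `"median_lp"` (default) or `"predicted_survival"`.
#' @return object of class `risk_stratification`: list with `group`
#'   (factor high/low per subject), `threshold`, `km` (a
#'   [survival::survfit()] object), `logrank_p`, and
#'   `median_survival_months` (named numeric, per group).
#' @export
stratify_risk <- function(fit, covariates, time, event,
                          split = c("median_lp", "predicted_survival")) {
  split <- match.arg(split)
  stopifnot(inherits(fit, "cox_fit"))
  dat <- as.data.frame(lapply(covariates, function(x) {
    if (is.logical(x)) as.numeric(x) else x
  }))
  lp <- unname(stats::predict(fit$fit, newdata = dat, type = "lp"))
  if (max(lp) - min(lp) < 1e-12) stop("non-informative risk score")
  if (split == "median_lp") {
    thr <- stats::median(lp)
    group <- factor(ifelse(lp > thr, "high", "low"), c("low", "high"))
  } else {
    sf <- survival::survfit(fit$fit, newdata = dat)
    pred_med <- summary(sf)$table[, "median"]
    thr <- stats::median(time)
    group <- factor(ifelse(pred_med <= thr, "high", "low"), c("low", "high"))
  }
  if (min(table(group)) < 2L)
    stop("fewer than 2 subjects in a risk group")
  sdat <- data.frame(time = time, event = event, group = group)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = sdat)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = sdat)
  logrank_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  med <- summary(km)$table[, "median"]
  names(med) <- sub("^group=", "", rownames(summary(km)$table))
  structure(list(group = group, threshold = thr, km = km,
                 logrank_p = logrank_p, median_survival_months = med),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat("<risk_stratification> log-rank p =",
      format.pval(x$logrank_p, digits = 3), "; median survival:",
      paste(names(x$median_survival_months),
            round(x$median_survival_months, 1), collapse = ", "), "months\n")
  invisible(x)
}

#' Rank-correlation structure of imaging and clinical variables
#'
#' Correlation matrix (Spearman by default; Pearson available) across
#' all numeric columns of the joined feature/clinical table, with an
#' average-linkage hierarchical clustering on 1 - |rho| that provides
#' the dendrogram ordering for a heatmap. Constant columns are masked
#' (correlations set to NA) with a warning.
#'
#' @param feature_table data.frame of imaging features.
#' @param clinical_table optional data.frame of clinical covariates
#'   (joined column-wise).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `correlation` (matrix), `order` (integer
#'   permutation), `hclust`, `method`.
#' @export
correlation_report <- function(feature_table, clinical_table = NULL,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  tab <- if (is.null(clinical_table)) feature_table
         else cbind(feature_table, clinical_table)
  tab <- as.data.frame(lapply(tab, function(x) {
    if (is.logical(x)) as.numeric(x) else x
  }))
  tab <- tab[vapply(tab, is.numeric, TRUE)]
  if (nrow(tab) < 3L) stop("need at least 3 subjects")
  const <- vapply(tab, function(x) stats::sd(x, na.rm = TRUE) == 0, TRUE)
  if (any(const))
    warning("constant column(s) masked: ",
            paste(names(tab)[const], collapse = ", "))
  rho <- suppressWarnings(
    stats::cor(tab, method = method, use = "pairwise.complete.obs"))
  rho[const, ] <- NA; rho[, const] <- NA; diag(rho) <- 1
  dmat <- 1 - abs(rho)
  dmat[is.na(dmat)] <- 1
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  list(correlation = rho, order = hc$order, hclust = hc, method = method)
}

#' Draw a correlation heatmap with dendrogram ordering
#'
#' @param report output of [correlation_report()].
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, the reordered correlation matrix.
#' @export
plot_correlation_heatmap <- function(report, file = NULL) {
  m <- report$correlation[report$order, report$order]
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 800)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mar = c(9, 9, 2, 2))
  on.exit(graphics::par(op), add = TRUE)
  k <- ncol(m)
  pal <- grDevices::hcl.colors(51, "Blue-Red 3")
  graphics::image(1:k, 1:k, t(m[k:1, ]), zlim = c(-1, 1), col = pal,
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste(report$method, "correlation"))
  graphics::axis(1, at = 1:k, labels = colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, at = k:1, labels = rownames(m), las = 2, cex.axis = 0.8)
  invisible(m)
}

#' Draw Kaplan-Meier curves for a risk stratification
#'
#' @param strat output of [stratify_risk()].
#' @param file optional PNG path.
#' @param main plot title.
#' @return invisibly, the `survfit` object.
#' @export
plot_km <- function(strat, file = NULL, main = "Risk stratification") {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot(strat$km, col = c("#2166ac", "#b2182b"), lwd = 2,
                 xlab = "Months", ylab = "Survival probability", main = main)
  graphics::legend("topright", legend = levels(strat$group),
                   col = c("#2166ac", "#b2182b"), lwd = 2, bty = "n")
  graphics::mtext(sprintf("log-rank p = %s",
                          format.pval(strat$logrank_p, digits = 3)),
                  side = 3, line = 0.2, cex = 0.9)
  invisible(strat$km)
}
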