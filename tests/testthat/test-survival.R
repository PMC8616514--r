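# Cox modeling stage: fits, screening, baselines, backward elimination,
# nested comparison, stratification, correlation.

test_that("a null binary covariate gives HR near 1", {
  tab <- sim_surv_table(1500, c(x2 = 0), seed = 2L)
  fit <- fit_cox(tab["x2"], tab$time_months, tab$event)
  expect_lt(abs(fit$terms$coefficient), 0.1)
  expect_equal(fit$terms$hr, 1, tolerance = 0.12)
})

test_that("a perfectly concordant risk score has C-index 1", {
  n <- 50
  x <- data.frame(risk = seq_len(n))
  time <- rev(seq_len(n)) + 0.5          # higher risk -> earlier death
  # a perfectly separating score makes coxph warn; the C-index is what
  # is under test here
  fit <- suppressWarnings(fit_cox(x, time, rep(1L, n)))
  expect_equal(fit$c_index, 1.0)
})

test_that("fit_cox reports the hazard-ratio algebra consistently", {
  tab <- sim_surv_table(300, c(x1 = 0.4), seed = 8L, censor_rate = 0.1)
  fit <- fit_cox(tab[c("x1", "x2")], tab$time_months, tab$event)
  expect_equal(fit$terms$hr, exp(fit$terms$coefficient))
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  expect_true(all(fit$terms$hr_lo < fit$terms$hr &
                    fit$terms$hr < fit$terms$hr_hi))
  expect_error(fit_cox(data.frame(k = rep(1, 300)), tab$time_months,
                       tab$event), "constant")
})

test_that("univariable screening reports and flags candidates", {
  tab <- sim_surv_table(400, c(x1 = 0.6), seed = 13L)
  feats <- data.frame(x1 = tab$x1, x1_copy = tab$x1,
                      noise = rnorm(400))
  scr <- univariable_screen(feats, tab$time_months, tab$event)
  expect_equal(nrow(scr$report), 3)
  # a duplicated feature screens identically
  expect_equal(scr$report$wald_p[1], scr$report$wald_p[2])
  expect_true("x1" %in% scr$candidates)

  # a failing feature is excluded with a warning, not an error
  feats$broken <- 1
  expect_warning(scr2 <- univariable_screen(feats, tab$time_months,
                                            tab$event), "broken")
  expect_false("broken" %in% scr2$report$feature)
})

test_that("clinical design matrices encode the published covariates", {
  clin <- data.frame(ecog = c(0, 2, 1), crp_mg_dl = c(exp(2), 1, 3),
                     bilirubin_mg_dl = c(exp(1), 0.5, 1),
                     ca19_9_u_ml = c(500, 1000, 2000))
  h <- haas_design(clin)
  expect_equal(h$ecog_1plus, c(0, 1, 1))
  expect_equal(h$log_crp[1], 2)
  expect_equal(h$log_bilirubin[1], 1)

  x <- xue_design(clin)
  expect_equal(x$ecog_2plus, c(0, 1, 0))
  expect_equal(x$ca19_9_ge_1000, c(0, 1, 1))   # >= is inclusive at 1000
  expect_equal(x$crp_ge_threshold, c(1, 0, 0))

  clin$crp_mg_dl[2] <- 0
  expect_warning(haas_design(clin), "nonpositive")
})

test_that("baseline models recover a log(CRP)-driven hazard", {
  n <- 600
  clin <- simulate_clinical(n, seed = 17L)
  cfg <- survival_sim_config(beta = c(log_crp = 0.4), censor_rate = 0,
                             seed = 17L)
  sv <- simulate_survival(clin, cfg)
  fit <- baseline_model_haas(clin, sv$time_months, sv$event)
  # log_crp is standardized inside the simulator; undo for comparison
  sd_lcrp <- sd(log(clin$crp_mg_dl))
  expect_lt(abs(fit$terms$coefficient[fit$terms$name == "log_crp"] *
                  sd_lcrp - 0.4), 0.1)
})

test_that("a degenerate all-zero indicator design is flagged", {
  clin <- data.frame(ecog = rep(0, 50), crp_mg_dl = rep(1, 50),
                     bilirubin_mg_dl = rep(1, 50),
                     ca19_9_u_ml = rep(10, 50))
  expect_error(baseline_model_xue(clin, rexp(50), rep(1L, 50)), "constant")
})

test_that("backward elimination returns the baseline for zero candidates", {
  tab <- sim_surv_table(200, c(x1 = 0.5), seed = 23L)
  base <- data.frame(clin = tab$x1)
  ext <- extend_model(base, tab[, integer(0), drop = FALSE],
                      tab$time_months, tab$event)
  ref <- fit_cox(base, tab$time_months, tab$event)
  expect_identical(ext$fit$terms, ref$terms)
  expect_equal(nrow(ext$trace), 0)
})

test_that("backward elimination drops pure noise and is locally optimal", {
  set.seed(29)
  tab <- sim_surv_table(400, c(x1 = 0.6), seed = 29L)
  base <- data.frame(clin = rnorm(400))
  cands <- data.frame(signal = tab$x1, noise1 = rnorm(400),
                      noise2 = rnorm(400))
  ext <- extend_model(base, cands, tab$time_months, tab$event)
  expect_true("signal" %in% ext$kept)
  expect_false(any(c("noise1", "noise2") %in% ext$kept))
  expect_true(all(ext$trace$aic_after < ext$trace$aic_before))

  # local optimality: removing any retained candidate raises the AIC
  for (f in ext$kept) {
    cols <- setdiff(c(names(base), ext$kept), f)
    sub <- cbind(base, cands)[cols]
    expect_gte(fit_cox(sub, tab$time_months, tab$event)$aic, ext$fit$aic)
  }
})

test_that("collinear candidates are dropped before elimination", {
  tab <- sim_surv_table(200, c(x1 = 0.5), seed = 31L)
  base <- data.frame(clin = tab$x2)
  cands <- data.frame(a = tab$x1, b = 2 * tab$x1 + 1)   # exactly collinear
  expect_warning(ext <- extend_model(base, cands, tab$time_months,
                                     tab$event), "collinear")
  expect_false("b" %in% ext$kept)
})

test_that("nested comparison computes the LR test and guards nesting", {
  tab <- sim_surv_table(300, c(x1 = 0.5), seed = 37L)
  base <- fit_cox(tab["x2"], tab$time_months, tab$event)
  ext <- fit_cox(tab[c("x2", "x1")], tab$time_months, tab$event)
  cmp <- compare_nested(base, ext)
  expect_equal(cmp$df, 1)
  expect_equal(cmp$lr_statistic, 2 * (ext$loglik - base$loglik))

  same <- compare_nested(base, base)
  expect_equal(same$lr_statistic, 0)
  expect_equal(same$p_value, 1)

  other <- fit_cox(tab["x1"], tab$time_months, tab$event)
  expect_error(compare_nested(base, other), "not nested")
  short <- fit_cox(tab["x2"][1:100, , drop = FALSE],
                   tab$time_months[1:100], tab$event[1:100])
  expect_error(compare_nested(short, ext), "different subjects")
})

test_that("median-split stratification matches two-group exponentials", {
  # groups with hazards lambda and 2*lambda, no censoring
  n <- 1200; lambda <- 0.08
  set.seed(41)
  grp <- rep(0:1, each = n / 2)
  time <- rexp(n, lambda * ifelse(grp == 1, 2, 1))
  event <- rep(1L, n)
  fit <- fit_cox(data.frame(grp = grp), time, event)
  strat <- stratify_risk(fit, data.frame(grp = grp), time, event)
  med <- strat$median_survival_months
  expect_equal(unname(med["low"]), log(2) / lambda, tolerance = 0.15)
  expect_equal(unname(med["high"]), log(2) / (2 * lambda), tolerance = 0.15)
  expect_lt(strat$logrank_p, 1e-6)
  expect_error(stratify_risk(fit, data.frame(grp = rep(1, n)), time, event),
               "non-informative")
})

test_that("correlation report is rank-invariant and masks constants", {
  set.seed(43)
  ft <- data.frame(a = rnorm(75), b = rnorm(75))
  ft$mono <- exp(ft$a)                       # monotone transform of a
  rep_ <- correlation_report(ft)
  expect_equal(diag(rep_$correlation), rep(1, 3), ignore_attr = TRUE)
  expect_equal(rep_$correlation["a", "mono"], 1)

  ft$k <- 1
  expect_warning(rep2 <- correlation_report(ft), "constant")
  expect_true(is.na(rep2$correlation["k", "a"]))

  # independent columns at n = 75: |rho| < 0.4 for >= 95% of pairs
  set.seed(47)
  ind <- as.data.frame(matrix(rnorm(75 * 12), 75))
  rho <- correlation_report(ind)$correlation
  off <- abs(rho[upper.tri(rho)])
  expect_gte(mean(off < 0.4), 0.95)
})

test_that("statistics are invariant to subject order", {
  tab <- sim_surv_table(200, c(x1 = 0.4), seed = 53L, censor_rate = 0.1)
  perm <- sample(nrow(tab))
  f1 <- fit_cox(tab[c("x1", "x2")], tab$time_months, tab$event)
  f2 <- fit_cox(tab[perm, c("x1", "x2")], tab$time_months[perm],
                tab$event[perm])
  expect_equal(f1$terms$coefficient, f2$terms$coefficient)
  expect_equal(f1$c_index, f2$c_index)
  expect_equal(f1$loglik, f2$loglik)
})
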