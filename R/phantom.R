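# Synthetic liver-phantom cohort: ellipsoidal liver split into two
# functional lobes, hypodense spherical lesions, Gaussian HU noise, and
# proportional-hazards survival simulation driven by extracted features.

#' Phantom generator settings
#'
#' Defaults emulate the cohort the analysis is designed for: lesion
#' counts from a zero-truncated negative binomial with median 7 and a
#' hard cap of 113 per subject; hypodense lesions (~65 HU) against portal
#' venous liver parenchyma (~105 HU); log-normal lesion radii with median
#' 5 mm.
#'
#' @param subjects number of subjects in the cohort.
#' @param seed integer root seed for the phantom stream.
#' @param grid_shape voxel grid, length-3 integer.
#' @param voxel_spacing mm per axis, length-3.
#' @param liver_semi_axes ellipsoid semi-axes in mm, length-3.
#' @param liver_size_sd relative standard deviation of the per-subject
#'   liver scale factor (log-normal); livers vary in size across
#'   subjects, which also keeps absolute and relative tumor volume from
#'   being collinear.
#' @param lesion_count_size,lesion_count_mu negative-binomial size and
#'   mean (before zero truncation).
#' @param lesion_count_max hard cap on lesions per subject.
#' @param lesion_radius_meanlog,lesion_radius_sdlog log-normal parameters
#'   of the lesion radius in mm.
#' @param liver_hu_mean,liver_hu_sd parenchyma HU distribution.
#' @param lesion_hu_mean,lesion_hu_sd lesion HU distribution; the lesion
#'   mean must be below the liver mean (hypodense metastases).
#' @param lobe_angle_deg in-plane angle of the lobe-splitting plane
#'   (sagittal-oblique, through the liver centroid).
#' @param texture_sigma_mm if > 0, the noise is augmented with a low-pass
#'   filtered random field of this correlation length so run-length
#'   texture is non-degenerate; 0 (default) = independent voxel noise.
#' @param max_place_attempts rejection-sampling attempts per lesion
#'   before its radius is redrawn.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(subjects = 75, seed = 1L,
                           grid_shape = c(96L, 96L, 48L),
                           voxel_spacing = c(2, 2, 3),
                           liver_semi_axes = c(80, 55, 45),
                           liver_size_sd = 0.08,
                           lesion_count_size = 0.8, lesion_count_mu = 9,
                           lesion_count_max = 113L,
                           lesion_radius_meanlog = log(5),
                           lesion_radius_sdlog = 0.45,
                           liver_hu_mean = 105, liver_hu_sd = 10,
                           lesion_hu_mean = 65, lesion_hu_sd = 10,
                           lobe_angle_deg = 20, texture_sigma_mm = 0,
                           max_place_attempts = 200L) {
  cfg <- list(subjects = as.integer(subjects), seed = as.integer(seed),
              grid_shape = as.integer(grid_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              liver_semi_axes = as.numeric(liver_semi_axes),
              liver_size_sd = liver_size_sd,
              lesion_count_size = lesion_count_size,
              lesion_count_mu = lesion_count_mu,
              lesion_count_max = as.integer(lesion_count_max),
              lesion_radius_meanlog = lesion_radius_meanlog,
              lesion_radius_sdlog = lesion_radius_sdlog,
              liver_hu_mean = liver_hu_mean, liver_hu_sd = liver_hu_sd,
              lesion_hu_mean = lesion_hu_mean, lesion_hu_sd = lesion_hu_sd,
              lobe_angle_deg = lobe_angle_deg,
              texture_sigma_mm = texture_sigma_mm,
              max_place_attempts = as.integer(max_place_attempts))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive")
    if (lesion_hu_mean >= liver_hu_mean)
      stop("lesions must be hypodense: lesion HU mean < liver HU mean")
    if (exp(lesion_radius_meanlog) <= max(voxel_spacing))
      stop("median lesion radius must exceed one voxel")
    phys <- grid_shape * voxel_spacing
    if (any(2 * liver_semi_axes > phys - 2 * voxel_spacing))
      stop("grid too small to contain the liver ellipsoid")
  })
  invisible(cfg)
}

# zero-truncated negative binomial, capped
rztnb <- function(n, size, mu, max_count) {
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- 0L
    while (x < 1L || x > max_count) x <- stats::rnbinom(1, size = size, mu = mu)
    out[i] <- x
  }
  out
}

#' Generate one phantom subject
#'
#' Deterministic in (config, subject_index): the subject's randomness
#' comes from a child seed of `config$seed`, so subjects can be generated
#' independently and in any order.
#'
#' @param config a [phantom_config()].
#' @param subject_index 1-based subject index (`<= config$subjects`).
#' @return list with `image` ([image_volume()]) and `seg`
#'   ([segmentation_set()]); attribute `n_lesions_generated` records the
#'   number of generative lesions before overlap merging.
#' @export
generate_phantom <- function(config, subject_index) {
  validate_phantom_config(config)
  stopifnot(subject_index >= 1L, subject_index <= config$subjects)
  with_seed(child_seed(config$seed, paste0("phantom/", subject_index)), {
    d <- config$grid_shape
    sp <- config$voxel_spacing
    ctr <- d * sp / 2
    co <- arrayInd(seq_len(prod(d)), d)
    mm <- voxel_centers_mm(co, sp)
    rel <- sweep(mm, 2L, ctr)

    scale_f <- exp(stats::rnorm(1, 0, config$liver_size_sd))
    ax <- pmin(config$liver_semi_axes * scale_f,
               d * sp / 2 - config$voxel_spacing)
    liver <- array(rowSums(sweep(rel, 2L, ax, `/`)^2) <= 1, dim = d)

    th <- config$lobe_angle_deg * pi / 180
    side <- rel[, 1] * cos(th) + rel[, 2] * sin(th)
    lobes <- array(0L, dim = d)
    lobes[liver & array(side < 0, dim = d)] <- 1L   # left
    lobes[liver & array(side >= 0, dim = d)] <- 2L  # right

    n_lesions <- rztnb(1, config$lesion_count_size, config$lesion_count_mu,
                       config$lesion_count_max)
    lesion_union <- array(FALSE, dim = d)
    min_r <- 1.05 * max(sp)
    for (k in seq_len(n_lesions)) {
      r <- draw_radius(config, min_r)
      placed <- FALSE
      for (retry in 1:5) {
        shrink <- ax - r
        if (all(shrink > 0)) {
          for (att in seq_len(config$max_place_attempts)) {
            cand <- (stats::runif(3) * 2 - 1) * shrink
            if (sum((cand / shrink)^2) <= 1) {   # inside shrunken ellipsoid
              cmm <- ctr + cand
              lesion_union <- lesion_union |
                sphere_mask(d, sp, cmm, r)
              placed <- TRUE
              break
            }
          }
        }
        if (placed) break
        r <- draw_radius(config, min_r)          # resample radius, retry
      }
      if (!placed)
        stop("could not place lesion ", k, " for subject ", subject_index)
    }
    lesion_labels <- label_components_26(lesion_union)

    img <- array(-1000, dim = d)
    img[liver] <- stats::rnorm(sum(liver), config$liver_hu_mean,
                               config$liver_hu_sd)
    img[lesion_union] <- stats::rnorm(sum(lesion_union),
                                      config$lesion_hu_mean,
                                      config$lesion_hu_sd)
    if (config$texture_sigma_mm > 0) {
      field <- gaussian_smooth_3d(array(stats::rnorm(prod(d)), dim = d),
                                  config$texture_sigma_mm, sp)
      # rescale the low-pass field to carry half the nominal noise power
      fsd <- stats::sd(field)
      inliv <- liver
      img[inliv] <- img[inliv] +
        field[inliv] / fsd * (config$liver_hu_sd / 2)
    }

    structure(list(image = image_volume(img, sp),
                   seg = segmentation_set(liver, lobes, lesion_labels, sp,
                                          relabel = FALSE)),
              n_lesions_generated = n_lesions)
  })
}

draw_radius <- function(config, min_r) {
  max_r <- min(config$liver_semi_axes) / 2
  for (i in 1:100) {
    r <- stats::rlnorm(1, config$lesion_radius_meanlog,
                       config$lesion_radius_sdlog)
    if (r >= min_r && r <= max_r) return(r)
  }
  min_r
}

sphere_mask <- function(d, sp, center_mm, r_mm) {
  lo <- pmax(1L, floor((center_mm - r_mm) / sp))
  hi <- pmin(d, ceiling((center_mm + r_mm) / sp))
  out <- array(FALSE, dim = d)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  sub <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  mm <- voxel_centers_mm(sub, sp)
  keep <- rowSums(sweep(mm, 2L, center_mm)^2) <= r_mm^2
  out[sub[keep, , drop = FALSE]] <- TRUE
  out
}

#' Simulate baseline clinical covariates
#'
#' Distributions are anchored to published baseline characteristics of
#' metastatic pancreatic cancer cohorts: ECOG 0/1/2/3 with probabilities
#' 0.44/0.507/0.04/0.013, and log-normal CRP (median 1.0 mg/dl),
#' bilirubin (median 0.6 mg/dl) and CA19-9 (median 463 U/ml, heavy tail).
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @return data.frame with `subject_id`, `ecog`, `crp_mg_dl`,
#'   `bilirubin_mg_dl`, `ca19_9_u_ml`.
#' @export
simulate_clinical <- function(n, seed = 1L) {
  with_seed(child_seed(seed, "clinical"), {
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      ecog = sample(0:3, n, replace = TRUE,
                    prob = c(0.44, 0.507, 0.04, 0.013)),
      crp_mg_dl = stats::rlnorm(n, log(1.0), 1.0),
      bilirubin_mg_dl = stats::rlnorm(n, log(0.6), 0.6),
      ca19_9_u_ml = stats::rlnorm(n, log(463), 2.0)
    )
  })
}

#' Survival simulation settings
#'
#' @param beta named numeric vector of log-hazard coefficients; names
#'   refer to columns of the feature/clinical table passed to
#'   [simulate_survival()]. Continuous covariates are standardized before
#'   the coefficients are applied.
#' @param baseline list: `dist` `"exponential"` (field `rate`, per month)
#'   or `"weibull"` (fields `shape`, `scale`). The default rate
#'   log(2)/10 gives a median survival of 10 months.
#' @param censor_rate target fraction of administratively right-censored
#'   subjects, in `[0, 1)`.
#' @param seed integer seed for the survival stream.
#' @return a `survival_sim_config` list.
#' @export
survival_sim_config <- function(beta = c(tbs = 0.5, bilobar = 0.6,
                                         log_crp = 0.4),
                                baseline = list(dist = "exponential",
                                                rate = log(2) / 10),
                                censor_rate = 0.08, seed = 1L) {
  stopifnot(censor_rate >= 0, censor_rate < 1,
            baseline$dist %in% c("exponential", "weibull"))
  if (baseline$dist == "exponential") stopifnot(baseline$rate > 0)
  else stopifnot(baseline$shape > 0, baseline$scale > 0)
  structure(list(beta = beta, baseline = baseline,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Simulate survival times under a proportional-hazards model
#'
#' Event times are drawn from the Cox model with linear predictor
#' `beta . x` over the named covariates, standardized before the
#' coefficients are applied: continuous covariates are centered and
#' scaled to unit variance, binary/logical covariates are centered only
#' (so a coefficient is the log hazard ratio between the two levels and
#' the cohort-average linear predictor stays near zero, keeping the
#' baseline's median survival interpretable for the whole cohort).
#' Censoring is administrative: censoring times are uniform on
#' `(0, tau)` with `tau` calibrated so the realized censoring fraction
#' matches `config$censor_rate`.
#'
#' @param features data.frame holding every covariate named in
#'   `config$beta`. The derived column `log_crp` is computed from
#'   `crp_mg_dl` automatically when requested.
#' @param config a [survival_sim_config()].
#' @return data.frame with `time_months` and `event` (1 = death
#'   observed).
#' @export
simulate_survival <- function(features, config) {
  beta <- config$beta
  if ("log_crp" %in% names(beta) && !"log_crp" %in% names(features))
    features$log_crp <- log(pmax(features$crp_mg_dl, 1e-6))
  missing_cov <- setdiff(names(beta), names(features))
  if (length(missing_cov))
    stop("covariates not found: ", paste(missing_cov, collapse = ", "))
  n <- nrow(features)
  lp <- rep(0, n)
  for (nm in names(beta)) {
    x <- features[[nm]]
    if (is.logical(x)) x <- as.numeric(x)
    x <- if (length(unique(x)) > 2L) as.numeric(scale(x)) else x - mean(x)
    lp <- lp + beta[[nm]] * x
  }
  if (any(!is.finite(lp))) stop("non-finite linear predictor")

  with_seed(child_seed(config$seed, "survival"), {
    u <- stats::runif(n)
    h <- -log(u) * exp(-lp)            # cumulative baseline hazard at T
    bl <- config$baseline
    T_ev <- if (bl$dist == "exponential") h / bl$rate
            else bl$scale * h^(1 / bl$shape)
    if (config$censor_rate <= 0)
      return(data.frame(time_months = T_ev, event = 1L))
    uc <- stats::runif(n)
    frac_cens <- function(tau) mean(uc * tau < T_ev) - config$censor_rate
    hi <- max(T_ev) * 4
    tau <- if (frac_cens(hi) > 0) hi
           else stats::uniroot(frac_cens, c(1e-9, hi))$root
    C <- uc * tau
    data.frame(time_months = pmin(T_ev, C), event = as.integer(T_ev <= C))
  })
}
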