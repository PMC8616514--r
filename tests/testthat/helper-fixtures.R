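# Shared fixtures and independent oracles. Everything here is built in
# code at test time; the oracles deliberately use naive algorithms
# (explicit loops, all-pairs scans) so they stay independent of the
# implementation they check.

# digital sphere mask on an isotropic grid, radius in mm
digital_sphere <- function(r_mm, sp, pad_mm = 6) {
  n <- ceiling(2 * (r_mm + pad_mm) / sp)
  d <- rep(as.integer(n), 3)
  ctr <- d / 2 * sp
  co <- arrayInd(seq_len(prod(d)), d)
  mm <- sweep(co - 0.5, 2, rep(sp, 3), `*`)
  array(sqrt(rowSums(sweep(mm, 2, ctr)^2)) <= r_mm, dim = d)
}

# build a segmentation_set from a lesion mask inside a box-shaped liver
# that fills the grid; lobes split at the mid-x plane (left = low x)
seg_from_lesions <- function(lesion_mask, sp = c(1, 1, 1),
                             relabel = TRUE) {
  d <- dim(lesion_mask)
  liver <- array(TRUE, dim = d)
  lob <- array(2L, dim = d)
  lob[1:(d[1] %/% 2), , ] <- 1L
  segmentation_set(liver, lob, lesion_mask * 1L, sp, relabel = relabel)
}

# brute-force maximum pairwise distance between voxel centers (mm)
bf_max_diameter_mm <- function(mask, sp) {
  co <- arrayInd(which(mask), dim(mask))
  mm <- sweep(co - 0.5, 2, sp, `*`)
  best <- 0
  n <- nrow(mm)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    best <- max(best, sum((mm[i, ] - mm[j, ])^2))
  sqrt(best)
}

# brute-force GLRLM gray-level nonuniformity: walk every line start in
# every direction, counting maximal same-bin runs voxel by voxel
bf_gln <- function(bins, directions, aggregation = "merge") {
  d <- dim(bins)
  scan_direction <- function(dir) {
    runs <- list()
    inb <- function(p) all(p >= 1) && all(p <= d)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      p <- c(x, y, z)
      # only start at the first voxel of each line
      if (inb(p - dir)) next
      q <- p
      cur <- NA; len <- 0
      while (inb(q)) {
        v <- bins[q[1], q[2], q[3]]
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1
        } else {
          if (!is.na(cur)) runs[[length(runs) + 1]] <- c(cur, len)
          cur <- v; len <- if (is.na(v)) 0 else 1
        }
        q <- q + dir
      }
      if (!is.na(cur)) runs[[length(runs) + 1]] <- c(cur, len)
    }
    do.call(rbind, runs)
  }
  glns <- numeric(0); all_runs <- NULL
  for (i in seq_len(nrow(directions))) {
    r <- scan_direction(directions[i, ])
    all_runs <- rbind(all_runs, r)
    tot <- nrow(r)
    glns <- c(glns, sum(table(r[, 1])^2) / tot)
  }
  if (aggregation == "merge")
    sum(table(all_runs[, 1])^2) / nrow(all_runs)
  else mean(glns)
}

# small phantom configuration used throughout the suite (coarser grid
# than the package default to keep the suite fast; same structure)
test_phantom_cfg <- function(subjects = 10, seed = 1L, ...) {
  args <- utils::modifyList(
    list(subjects = subjects, seed = seed,
         grid_shape = c(64L, 64L, 36L),
         voxel_spacing = c(2.5, 2.5, 3.5),
         liver_semi_axes = c(70, 48, 40)),
    list(...))
  do.call(phantom_config, args)
}

# simulate a plain covariate table + survival for model-level tests
sim_surv_table <- function(n, beta, seed, censor_rate = 0,
                           rate = log(2) / 10) {
  set.seed(seed)
  x <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  cfg <- survival_sim_config(beta = beta, censor_rate = censor_rate,
                             baseline = list(dist = "exponential",
                                             rate = rate),
                             seed = seed)
  cbind(x, simulate_survival(x, cfg))
}
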