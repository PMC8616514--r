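# Four-feature radiomics signature: energy, compactness, GLRLM GLN,
# wavelet GLN.

test_that("energy is the sum of squared raw intensities", {
  img <- array(3, c(4, 4, 4))
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, 1:2, 1:2] <- TRUE
  expect_equal(first_order_energy(img, mask), 8 * 9)

  img2 <- array(0, c(3, 1, 1)); img2[] <- c(1, 2, 3)
  expect_equal(first_order_energy(img2, array(TRUE, c(3, 1, 1))), 14)

  # brute-force summation oracle on a random ROI
  set.seed(4)
  img3 <- array(rnorm(5^3, 70, 15), c(5, 5, 5))
  mask3 <- array(runif(5^3) < 0.5, c(5, 5, 5))
  acc <- 0
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    if (mask3[i, j, k]) acc <- acc + img3[i, j, k]^2
  expect_equal(first_order_energy(img3, mask3), acc)

  expect_warning(out <- first_order_energy(img3, mask3 & FALSE), "empty")
  expect_true(is.na(out))
})

test_that("energy is additive over disjoint mask partitions", {
  set.seed(5)
  img <- array(rnorm(6^3, 60, 20), c(6, 6, 6))
  mask <- array(runif(6^3) < 0.6, c(6, 6, 6))
  part <- array(runif(6^3) < 0.5, c(6, 6, 6))
  expect_equal(first_order_energy(img, mask),
               first_order_energy(img, mask & part) +
                 first_order_energy(img, mask & !part))
})

test_that("compactness is maximal for spheres and scale invariant", {
  sph <- digital_sphere(15, 1)
  c_sph <- shape_compactness(sph, c(1, 1, 1))
  expect_equal(c_sph, 1 / (6 * pi), tolerance = 0.05)

  # elongated ellipsoid (a = 4r): strictly less compact than the sphere
  d <- c(90, 26, 26)
  co <- arrayInd(seq_len(prod(d)), d)
  mm <- sweep(co - 0.5, 2, c(1, 1, 1), `*`)
  ell <- array(((mm[, 1] - 45) / 40)^2 + ((mm[, 2] - 13) / 10)^2 +
                 ((mm[, 3] - 13) / 10)^2 <= 1, dim = d)
  expect_lt(shape_compactness(ell, c(1, 1, 1)), c_sph)

  # same shape at twice the size: equal within mesh error
  c_big <- shape_compactness(digital_sphere(30, 1), c(1, 1, 1))
  expect_equal(c_big, c_sph, tolerance = 0.03)
})

test_that("GLN reproduces hand-enumerated 1D fixtures", {
  # row [1,1,2,2,2], single direction: runs {(1,2),(2,3)} -> GLN 1.0
  vals <- array(NA_real_, c(5, 1, 1))
  vals[, 1, 1] <- c(1, 1, 2, 2, 2) * 10
  mask <- array(TRUE, c(5, 1, 1))
  gln <- glrlm_gray_level_nonuniformity(
    vals, mask, discretization_config(bin_width = 10),
    directions = rbind(c(1, 0, 0)))
  expect_equal(gln, 1.0)

  # constant row of length 5: one run, GLN = 1
  vals2 <- array(7, c(5, 1, 1))
  expect_equal(glrlm_gray_level_nonuniformity(
    vals2, mask, discretization_config(25),
    directions = rbind(c(1, 0, 0))), 1.0)
})

test_that("GLN equals the exhaustive run-scanner oracle on random ROIs", {
  dirs <- wltb:::glrlm_directions()
  for (seed in 1:3) {
    set.seed(seed)
    vals <- array(sample(1:4, 5^3, replace = TRUE) * 25 - 12, c(5, 5, 5))
    mask <- array(runif(5^3) < 0.8, c(5, 5, 5))
    mask[1, 1, 1] <- TRUE; mask[2, 1, 1] <- TRUE
    bins <- wltb:::discretize_fbw(vals, mask, 25)
    expect_equal(
      glrlm_gray_level_nonuniformity(vals, mask, discretization_config(25)),
      bf_gln(bins, dirs, "merge"))
    expect_equal(
      glrlm_gray_level_nonuniformity(vals, mask,
                                     discretization_config(25, "average")),
      bf_gln(bins, dirs, "average"))
  }
})

test_that("GLN is invariant to bin-label permutation and direction order", {
  set.seed(9)
  vals <- array(sample(c(0, 30, 60, 90), 6^3, replace = TRUE), c(6, 6, 6))
  mask <- array(runif(6^3) < 0.7, c(6, 6, 6))
  mask[1:2, 1, 1] <- TRUE
  disc <- discretization_config(30)
  g1 <- glrlm_gray_level_nonuniformity(vals, mask, disc)
  # permute gray levels: swap lowest and highest bands (bijective on bins)
  vals2 <- vals
  vals2[vals == 0] <- 90; vals2[vals == 90] <- 0
  expect_equal(glrlm_gray_level_nonuniformity(vals2, mask, disc), g1)
  # reverse the direction set
  dirs <- wltb:::glrlm_directions()
  expect_equal(glrlm_gray_level_nonuniformity(vals, mask, disc,
                                              directions = dirs[13:1, ]), g1)
})

test_that("wavelet GLN degenerates for constant images and composes", {
  img <- array(100, c(8, 8, 8))
  mask <- array(TRUE, c(8, 8, 8))
  # high-pass of a constant is ~0: single bin, GLN = run count
  sub <- wavelet_subband(img, wavelet_config())
  expect_lt(max(abs(sub)), 1e-8)
  wg <- wavelet_gln(img, mask)
  bins <- wltb:::discretize_fbw(sub, mask, 25)
  mats <- glrlm_matrices(bins)
  expect_equal(wg, sum(Reduce(`+`, mats)))

  # composition: wavelet_gln == GLN applied to the filtered volume
  set.seed(12)
  img2 <- array(rnorm(8^3, 80, 20), c(8, 8, 8))
  mask2 <- array(runif(8^3) < 0.8, c(8, 8, 8))
  mask2[1:2, 1, 1] <- TRUE
  expect_equal(
    wavelet_gln(img2, mask2),
    glrlm_gray_level_nonuniformity(wavelet_subband(img2, wavelet_config()),
                                   mask2, discretization_config()))
})

test_that("per-subject features do not depend on batch order", {
  cfg <- test_phantom_cfg(subjects = 3, seed = 41L)
  phs <- lapply(1:3, function(i) generate_phantom(cfg, i))
  fwd <- lapply(phs, function(p) extract_qib(p$image, p$seg))
  rev_ <- lapply(rev(phs), function(p) extract_qib(p$image, p$seg))
  expect_equal(fwd[[1]], rev_[[3]])
  expect_equal(fwd[[3]], rev_[[1]])
})
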