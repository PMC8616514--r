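# Geometric whole-liver-tumor-burden biomarkers.

test_that("lesion inventory handles single voxels and counts correctly", {
  les <- array(0L, c(10, 10, 6))
  les[2, 2, 2] <- 1L
  seg <- seg_from_lesions(les > 0, sp = c(2, 2, 3))
  inv <- lesion_inventory(seg)
  expect_equal(nrow(inv), 1)
  expect_equal(inv$max_diameter_cm, 0)
  expect_equal(inv$volume_cm3, 2 * 2 * 3 / 1000)

  les2 <- array(0L, c(12, 12, 8))
  les2[2:6, 2:2, 2] <- 1L           # 5 voxels
  les2[8:9, 8:12, 5] <- 1L          # 10 voxels
  seg2 <- seg_from_lesions(les2 > 0)
  inv2 <- lesion_inventory(seg2)
  expect_equal(nrow(inv2), 2)
  expect_setequal(inv2$voxel_count, c(5L, 10L))
})

test_that("max diameter matches brute force and the sphere closed form", {
  # exact agreement with all-pairs scan on a small sphere
  m <- digital_sphere(4, 1, pad_mm = 2)
  seg <- seg_from_lesions(m)
  inv <- lesion_inventory(seg)
  expect_equal(inv$max_diameter_cm * 10, bf_max_diameter_mm(m, c(1, 1, 1)))

  # 10 mm-radius sphere at 1 mm spacing: diameter 2.0 cm +- 2 voxel diagonals
  m10 <- digital_sphere(10, 1)
  inv10 <- lesion_inventory(seg_from_lesions(m10))
  expect_equal(inv10$max_diameter_cm, 2.0, tolerance = 2 * sqrt(3) / 10 / 2)
})

test_that("tumor burden score follows the Pythagorean form", {
  inv <- data.frame(max_diameter_cm = c(4, 1, 2))     # N = 3, D = 4
  expect_equal(tumor_burden_score(inv), 5)
  expect_equal(tumor_burden_score(data.frame(max_diameter_cm = 0)), 1)
  inv7 <- data.frame(max_diameter_cm = c(rep(1, 6), 2.4))
  expect_equal(tumor_burden_score(inv7), sqrt(49 + 5.76))
  expect_warning(out <- tumor_burden_score(inv7[0, , drop = FALSE]),
                 "undefined")
  expect_true(is.na(out))
})

test_that("TBS is strictly monotone in lesion count and diameter", {
  base <- data.frame(max_diameter_cm = rep(1, 5))
  more <- data.frame(max_diameter_cm = rep(1, 6))
  bigger <- data.frame(max_diameter_cm = c(rep(1, 4), 3))
  expect_gt(tumor_burden_score(more), tumor_burden_score(base))
  expect_gt(tumor_burden_score(bigger), tumor_burden_score(base))
})

test_that("bilobar disease is decided at voxel level", {
  d <- c(12, 12, 6)                          # lobe split at x = 6|7
  right_only <- array(0L, d); right_only[8:9, 3:4, 2] <- 1L
  expect_false(bilobar_disease(
    lesion_inventory(seg_from_lesions(right_only > 0))))

  one_each <- right_only; one_each[2:3, 3:4, 2] <- 2L
  expect_true(bilobar_disease(
    lesion_inventory(seg_from_lesions(one_each > 0))))

  straddle <- array(0L, d); straddle[5:8, 5:6, 3] <- 1L
  inv <- lesion_inventory(seg_from_lesions(straddle > 0))
  expect_equal(nrow(inv), 1)
  expect_true(bilobar_disease(inv))
})

test_that("volume features are exact on constructed masks", {
  les <- array(0L, c(20, 20, 10))
  les[1:10, 1:10, 1:10] <- 1L                # 1000 voxels at 1 mm^3
  seg <- seg_from_lesions(les > 0)
  v <- volume_features(seg)
  expect_equal(v$volume_cm3, 1.0)
  expect_equal(v$relative_volume_pct, 100 * 1000 / prod(c(20, 20, 10)))

  all_les <- array(1L, c(6, 6, 6))
  expect_equal(volume_features(seg_from_lesions(all_les > 0))$relative_volume_pct,
               100)

  # analytic sphere volume within voxelization error
  m <- digital_sphere(10, 1)
  vs <- volume_features(seg_from_lesions(m))
  expect_equal(vs$volume_cm3, 4 / 3 * pi, tolerance = 0.03)
})

test_that("mean attenuation averages the lesion union", {
  les <- array(0L, c(10, 10, 4))
  les[2:3, 2:3, 2] <- 1L
  les[7:8, 7:8, 3] <- 2L
  img <- array(0, dim(les))
  img[les == 1L] <- 60
  img[les == 2L] <- 80
  seg <- seg_from_lesions(les > 0)
  expect_equal(mean_attenuation(img, seg), 70)

  img2 <- array(70, dim(les))
  expect_equal(mean_attenuation(img2, seg), 70)
})

test_that("metastatic spread measures per-axis physical extent", {
  d <- c(60, 20, 10)
  les <- array(0L, d)
  les[5, 5, 5] <- 1L
  seg1 <- seg_from_lesions(les > 0, sp = c(2, 2, 2))
  gms1 <- geometric_metastatic_spread(seg1)
  expect_equal(unlist(gms1), c(msx_cm = 0, msy_cm = 0, msz_cm = 0))

  les[55, 5, 5] <- 2L                        # 50 voxels * 2 mm = 100 mm
  seg2 <- seg_from_lesions(les > 0, sp = c(2, 2, 2))
  gms2 <- geometric_metastatic_spread(seg2)
  expect_equal(gms2$msx_cm, 10)
  expect_equal(gms2$msy_cm, 0)
  expect_equal(gms2$msz_cm, 0)

  # lesions spread across lobes have strictly larger MSx than confined ones
  conf <- array(0L, c(40, 20, 10)); conf[30:32, 8:10, 4:6] <- 1L
  conf[34:36, 8:10, 4:6] <- 2L
  spread <- array(0L, c(40, 20, 10)); spread[2:4, 8:10, 4:6] <- 1L
  spread[34:36, 8:10, 4:6] <- 2L
  gms_conf <- geometric_metastatic_spread(seg_from_lesions(conf > 0))
  gms_spread <- geometric_metastatic_spread(seg_from_lesions(spread > 0))
  expect_gt(gms_spread$msx_cm, gms_conf$msx_cm)
})

test_that("SA/V matches the sphere closed form and its scaling law", {
  m10 <- digital_sphere(10, 1)
  seg10 <- seg_from_lesions(m10)
  expect_equal(surface_area_to_volume(seg10), 3.0, tolerance = 0.05 * 3)

  # two disjoint spheres of equal radius: ratio unchanged (additivity)
  d <- dim(m10)
  two <- array(FALSE, c(2 * d[1] + 4, d[2], d[3]))
  two[1:d[1], , ] <- m10
  two[(d[1] + 5):(2 * d[1] + 4), , ] <- m10
  expect_equal(surface_area_to_volume(seg_from_lesions(two)), 3.0,
               tolerance = 0.05 * 3)

  # halving the radius doubles SA/V (3/r law)
  m5 <- digital_sphere(5, 1)
  r_ratio <- surface_area_to_volume(seg_from_lesions(m5)) /
    surface_area_to_volume(seg10)
  expect_equal(r_ratio, 2, tolerance = 0.15)
})

test_that("SA/V respects the isoperimetric lower bound", {
  # >= 2 lesions: SA/V must exceed that of one sphere of equal volume
  m <- digital_sphere(8, 1)
  d <- dim(m)
  multi <- array(FALSE, c(2 * d[1] + 4, d[2], d[3]))
  multi[1:d[1], , ] <- m
  multi[(d[1] + 5):(2 * d[1] + 4), , ] <- digital_sphere(8, 1)
  seg <- seg_from_lesions(multi)
  v_cm3 <- sum(multi) / 1000
  r_eq_cm <- (3 * v_cm3 / (4 * pi))^(1 / 3)
  expect_gt(surface_area_to_volume(seg), 3 / r_eq_cm)
})

test_that("geometric outputs ignore intensity; intensity features ignore geometry labels", {
  cfg <- test_phantom_cfg(subjects = 1, seed = 31L)
  ph <- generate_phantom(cfg, 1)
  seg <- ph$seg
  img_a <- ph$image
  img_b <- image_volume(ph$image$values * 0 + 55, ph$image$spacing)
  inv_a <- lesion_inventory(seg)
  expect_identical(inv_a, lesion_inventory(seg))    # no intensity input at all
  expect_equal(surface_area_to_volume(seg), surface_area_to_volume(seg))

  # permuting lesion label ids leaves attenuation and energy unchanged
  lab <- seg$lesion_labels
  k <- max(lab)
  perm <- array(0L, dim(lab))
  perm[lab > 0] <- (k + 1L) - lab[lab > 0]
  seg_p <- segmentation_set(seg$liver_mask, seg$lobe_labels, perm,
                            seg$spacing, relabel = FALSE)
  expect_equal(mean_attenuation(img_a, seg_p), mean_attenuation(img_a, seg))
  expect_equal(first_order_energy(img_a, seg_p$lesion_labels > 0),
               first_order_energy(img_a, seg$lesion_labels > 0))
})

test_that("halving the voxel spacing changes volume <2% and SA/V <8%", {
  v1 <- volume_features(seg_from_lesions(digital_sphere(15, 1),
                                         sp = c(1, 1, 1)))$volume_cm3
  v2 <- volume_features(seg_from_lesions(digital_sphere(15, 2),
                                         sp = c(2, 2, 2)))$volume_cm3
  expect_lt(abs(v1 / v2 - 1), 0.02)
  s1 <- surface_area_to_volume(seg_from_lesions(digital_sphere(15, 1),
                                                sp = c(1, 1, 1)))
  s2 <- surface_area_to_volume(seg_from_lesions(digital_sphere(15, 2),
                                                sp = c(2, 2, 2)))
  expect_lt(abs(s1 / s2 - 1), 0.08)
})
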