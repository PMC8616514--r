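# Geometric and first-order biomarkers of the whole liver tumor burden
# (WLTB): per-lesion inventory, tumor burden score, bilobar disease,
# absolute/relative volume, mean attenuation, geometric metastatic spread
# and surface-area-to-volume ratio.

#' Per-lesion inventory
#'
#' Bookkeeping behind all geometric biomarkers: per lesion the voxel
#' count, physical volume, centroid, maximum diameter and the functional
#' lobes it intersects.
#'
#' The maximum diameter is the largest Euclidean distance between any two
#' voxel centers of the lesion in physical mm (3D, not restricted to an
#' axial plane; set `axial_only = TRUE` for the in-plane variant). The
#' maximizing pair always lies on the lesion boundary, so only boundary
#' voxels are searched.
#'
#' @param seg a [segmentation_set()].
#' @param spacing voxel spacing in mm; defaults to `seg$spacing`.
#' @param axial_only if `TRUE`, diameters are measured within single
#'   axial (z) slices only.
#' @return data.frame with one row per lesion: `id`, `voxel_count`,
#'   `volume_cm3`, `cx_mm`, `cy_mm`, `cz_mm`, `max_diameter_cm`,
#'   `in_left`, `in_right`. Zero lesions give a zero-row frame.
#' @export
lesion_inventory <- function(seg, spacing = seg$spacing, axial_only = FALSE) {
  lab <- seg$lesion_labels
  d <- dim(lab)
  ids <- sort(unique(lab[lab > 0L]))
  voxvol <- prod(spacing)
  out <- data.frame(id = integer(0), voxel_count = integer(0),
                    volume_cm3 = numeric(0), cx_mm = numeric(0),
                    cy_mm = numeric(0), cz_mm = numeric(0),
                    max_diameter_cm = numeric(0),
                    in_left = logical(0), in_right = logical(0))
  for (id in ids) {
    idx <- which(lab == id)
    co <- arrayInd(idx, d)
    mm <- voxel_centers_mm(co, spacing)
    ctr <- colMeans(mm)
    diam <- max_pairwise_mm(co, mm, d, lab == id, axial_only) / 10
    lob <- seg$lobe_labels[idx]
    out <- rbind(out, data.frame(
      id = id, voxel_count = length(idx),
      volume_cm3 = length(idx) * voxvol / 1000,
      cx_mm = ctr[1], cy_mm = ctr[2], cz_mm = ctr[3],
      max_diameter_cm = diam,
      in_left = any(lob == 1L), in_right = any(lob == 2L)))
  }
  rownames(out) <- NULL
  out
}

# maximum pairwise distance (mm) between voxel centers of one lesion;
# restricted to 6-boundary voxels, chunked to bound memory
max_pairwise_mm <- function(co, mm, d, lesion_mask, axial_only = FALSE) {
  if (nrow(co) == 1L) return(0)
  on_boundary <- rep(FALSE, nrow(co))
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    nx <- co[, 1] + s[1]; ny <- co[, 2] + s[2]; nz <- co[, 3] + s[3]
    outside <- nx < 1L | nx > d[1] | ny < 1L | ny > d[2] | nz < 1L | nz > d[3]
    inside <- !outside
    val <- rep(FALSE, nrow(co))
    lin <- (nz[inside] - 1L) * d[1] * d[2] + (ny[inside] - 1L) * d[1] + nx[inside]
    val[inside] <- !lesion_mask[lin]
    on_boundary <- on_boundary | outside | val
  }
  p <- mm[on_boundary, , drop = FALSE]
  z <- co[on_boundary, 3]
  best <- 0
  chunk <- 512L
  for (i0 in seq(1L, nrow(p), by = chunk)) {
    i1 <- min(nrow(p), i0 + chunk - 1L)
    dx <- outer(p[i0:i1, 1], p[, 1], `-`)
    dy <- outer(p[i0:i1, 2], p[, 2], `-`)
    dz <- outer(p[i0:i1, 3], p[, 3], `-`)
    d2 <- dx^2 + dy^2 + dz^2
    if (axial_only) d2[outer(z[i0:i1], z, `!=`)] <- 0
    best <- max(best, max(d2))
  }
  sqrt(best)
}

#' Tumor burden score
#'
#' Pythagorean combination of lesion number and the diameter of the
#' largest lesion: TBS = sqrt(N^2 + D^2), D in cm. With at least one
#' lesion TBS >= 1.
#'
#' @param inventory a [lesion_inventory()] data.frame.
#' @return TBS; `NA` with a warning when there are no lesions.
#' @export
tumor_burden_score <- function(inventory) {
  if (nrow(inventory) == 0L) {
    warning("no lesions: tumor burden score undefined")
    return(NA_real_)
  }
  sqrt(nrow(inventory)^2 + max(inventory$max_diameter_cm)^2)
}

#' Bilobar disease
#'
#' `TRUE` iff at least one lesion voxel lies in the left functional lobe
#' and at least one in the right. Decided at voxel level, so a single
#' lesion straddling the lobe plane counts as bilobar.
#'
#' @param inventory a [lesion_inventory()] data.frame.
#' @return logical.
#' @export
bilobar_disease <- function(inventory) {
  if (nrow(inventory) == 0L) return(FALSE)
  any(inventory$in_left) && any(inventory$in_right)
}

#' Absolute and relative tumor volume
#'
#' Lesion volume as voxel count times voxel volume (cm^3) and as a
#' percentage of the liver volume; the liver volume includes the lesion
#' voxels.
#'
#' @param seg a [segmentation_set()].
#' @param spacing voxel spacing in mm.
#' @return list with `volume_cm3` and `relative_volume_pct`.
#' @export
volume_features <- function(seg, spacing = seg$spacing) {
  n_liver <- sum(seg$liver_mask)
  if (n_liver == 0L) stop("empty liver mask")
  voxvol <- prod(spacing) / 1000        # cm^3
  n_les <- sum(seg$lesion_labels > 0L)
  list(volume_cm3 = n_les * voxvol,
       relative_volume_pct = 100 * n_les / n_liver)
}

#' Mean attenuation of the tumor burden
#'
#' Arithmetic mean of the HU values over the union of all lesion voxels.
#'
#' @param image `image_volume` or 3D numeric array.
#' @param seg a [segmentation_set()].
#' @return mean HU; `NA` with a warning for an empty lesion union.
#' @export
mean_attenuation <- function(image, seg) {
  values <- if (inherits(image, "image_volume")) image$values else image
  sel <- seg$lesion_labels > 0L
  if (!any(sel)) {
    warning("no lesion voxels: attenuation undefined")
    return(NA_real_)
  }
  mean(values[sel])
}

#' Geometric metastatic spread (MSx, MSy, MSz)
#'
#' Maximum physical extent of the metastases along each scanner axis:
#' per axis, max minus min coordinate (cm) over the union of lesion voxel
#' centers (default) or over lesion centroids (`mode = "centroid"`).
#' Axis convention: x = left-right, y = anterior-posterior,
#' z = cranio-caudal.
#'
#' @param seg a [segmentation_set()].
#' @param spacing voxel spacing in mm.
#' @param mode `"voxel"` (default) or `"centroid"`.
#' @return list with `msx_cm`, `msy_cm`, `msz_cm`; zeros with a warning
#'   when there are no lesions.
#' @export
geometric_metastatic_spread <- function(seg, spacing = seg$spacing,
                                        mode = c("voxel", "centroid")) {
  mode <- match.arg(mode)
  idx <- which(seg$lesion_labels > 0L)
  if (!length(idx)) {
    warning("no lesions: metastatic spread set to zero")
    return(list(msx_cm = 0, msy_cm = 0, msz_cm = 0))
  }
  if (mode == "voxel") {
    mm <- voxel_centers_mm(arrayInd(idx, dim(seg$lesion_labels)), spacing)
  } else {
    inv <- lesion_inventory(seg, spacing)
    mm <- as.matrix(inv[, c("cx_mm", "cy_mm", "cz_mm")])
  }
  ext <- (apply(mm, 2, max) - apply(mm, 2, min)) / 10
  list(msx_cm = ext[[1]], msy_cm = ext[[2]], msz_cm = ext[[3]])
}

#' Surface-area-to-volume ratio of the tumor burden
#'
#' Iso-surface area of the union of all lesions divided by its volume,
#' in 1/cm. Quantifies dispersion: many small lesions have a much higher
#' SA/V than one large lesion of equal total volume (for a single sphere
#' of radius r cm, SA/V = 3/r).
#'
#' @param seg a [segmentation_set()].
#' @param spacing voxel spacing in mm.
#' @param method surface estimation method, see [surface_area_mm2()].
#' @return SA/V in 1/cm; `NA` with a warning when the lesion volume is 0.
#' @export
surface_area_to_volume <- function(seg, spacing = seg$spacing,
                                   method = "mesh") {
  sel <- seg$lesion_labels > 0L
  if (!any(sel)) {
    warning("no lesion voxels: SA/V undefined")
    return(NA_real_)
  }
  A <- surface_area_mm2(sel, spacing, method = method)   # mm^2
  V <- sum(sel) * prod(spacing)                          # mm^3
  10 * A / V                                             # 1/cm
}

#' Extract the full 13-feature QIB vector for one subject
#'
#' Computes all whole-liver-tumor-burden biomarkers from one image +
#' segmentation pair: mean attenuation, absolute and relative volume,
#' tumor burden score, bilobar disease, the four-feature radiomics
#' signature (energy, compactness, GLRLM nonuniformity, wavelet
#' nonuniformity), the per-axis metastatic spread and SA/V.
#'
#' @param image an [image_volume()].
#' @param seg a [segmentation_set()] on the same grid.
#' @param disc a [discretization_config()].
#' @param wcfg a [wavelet_config()].
#' @return one-row data.frame with columns `attenuation_hu`, `volume_cm3`,
#'   `relative_volume_pct`, `tbs`, `bilobar`, `energy`, `compactness`,
#'   `glrlm_nonuniformity`, `wavelet_nonuniformity`, `msx_cm`, `msy_cm`,
#'   `msz_cm`, `sa_v_per_cm`.
#' @export
extract_qib <- function(image, seg, disc = discretization_config(),
                        wcfg = wavelet_config()) {
  stopifnot(identical(dim(image$values), dim(seg$liver_mask)))
  spacing <- image$spacing
  inv <- lesion_inventory(seg, spacing)
  vol <- volume_features(seg, spacing)
  gms <- geometric_metastatic_spread(seg, spacing)
  wltb <- seg$lesion_labels > 0L
  has_lesion <- any(wltb)
  data.frame(
    attenuation_hu = if (has_lesion) mean_attenuation(image, seg) else NA_real_,
    volume_cm3 = vol$volume_cm3,
    relative_volume_pct = vol$relative_volume_pct,
    tbs = if (has_lesion) tumor_burden_score(inv) else NA_real_,
    bilobar = bilobar_disease(inv),
    energy = if (has_lesion) first_order_energy(image, wltb) else NA_real_,
    compactness = if (has_lesion) shape_compactness(wltb, spacing) else NA_real_,
    glrlm_nonuniformity =
      if (sum(wltb) >= 2L)
        glrlm_gray_level_nonuniformity(image, wltb, disc) else NA_real_,
    wavelet_nonuniformity =
      if (sum(wltb) >= 2L) wavelet_gln(image, wltb, wcfg, disc) else NA_real_,
    msx_cm = gms$msx_cm, msy_cm = gms$msy_cm, msz_cm = gms$msz_cm,
    sa_v_per_cm = if (has_lesion) surface_area_to_volume(seg, spacing) else NA_real_
  )
}

#' Names of the 13 QIB feature columns
#' @return character vector of column names in canonical order.
#' @export
qib_feature_names <- function() {
  c("attenuation_hu", "volume_cm3", "relative_volume_pct", "tbs", "bilobar",
    "energy", "compactness", "glrlm_nonuniformity", "wavelet_nonuniformity",
    "msx_cm", "msy_cm", "msz_cm", "sa_v_per_cm")
}
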