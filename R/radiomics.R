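# The four-feature prognostic radiomics signature on the whole liver
# tumor burden: first-order energy, shape compactness, GLRLM gray-level
# nonuniformity, and the same nonuniformity on a wavelet sub-band.

#' First-order energy of a region
#'
#' Sum of squared raw intensities (HU) over the mask. No intensity shift
#' is applied; some toolkits add a constant offset before squaring, which
#' changes values by orders of magnitude, so the convention matters and is
#' fixed here.
#'
#' @param image `image_volume` or 3D numeric array.
#' @param mask logical array of the same shape.
#' @return energy (HU^2); `NA` for an empty mask (with a warning).
#' @export
first_order_energy <- function(image, mask) {
  values <- if (inherits(image, "image_volume")) image$values else image
  stopifnot(identical(dim(values), dim(mask)))
  if (!any(mask)) {
    warning("empty mask: energy undefined")
    return(NA_real_)
  }
  sum(values[mask]^2)
}

#' Shape compactness of a region
#'
#' compactness1 = V / (sqrt(pi) * A^(3/2)) with volume V in mm^3 and
#' surface area A in mm^2 from the same iso-surface mesh used for the
#' surface-area-to-volume ratio. Dimensionless and scale invariant;
#' maximal for a sphere at 1/(6*pi) ~ 0.05305.
#'
#' @param mask logical 3D array with at least one voxel.
#' @param spacing voxel spacing in mm.
#' @param method surface estimation method, see [surface_area_mm2()].
#' @return compactness (dimensionless).
#' @export
shape_compactness <- function(mask, spacing, method = "mesh") {
  if (!any(mask)) stop("empty mask: compactness undefined")
  V <- sum(mask) * prod(spacing)
  A <- surface_area_mm2(mask, spacing, method = method)
  if (!is.finite(A) || A <= 0)
    stop("degenerate surface mesh (area ", A, ")")
  V / (sqrt(pi) * A^1.5)
}

#' Wavelet sub-band settings
#'
#' A single-level undecimated (stationary) separable 3D wavelet transform
#' is applied so that the sub-band stays voxel-aligned with the mask. The
#' sub-band code gives the filter per axis in (x, y, z) order, `H` =
#' high-pass, `L` = low-pass. Default: Coiflet-1, sub-band HLH.
#'
#' @param family wavelet family; `"coif1"` (default) or `"haar"`.
#' @param subband 3-letter code over (x, y, z), letters in {L, H}.
#' @return a `wavelet_config` list.
#' @export
wavelet_config <- function(family = c("coif1", "haar"), subband = "HLH") {
  family <- match.arg(family)
  stopifnot(nchar(subband) == 3L,
            all(strsplit(subband, "")[[1]] %in% c("L", "H")))
  structure(list(family = family, subband = subband),
            class = "wavelet_config")
}

# orthonormal decomposition filter taps
wavelet_filters <- function(family) {
  switch(family,
    haar = list(lo = c(1, 1) / sqrt(2), hi = c(1, -1) / sqrt(2)),
    coif1 = list(
      lo = c(-0.0156557281357920, -0.0727326195125265, 0.3848648468648578,
              0.8525720202116004,  0.3378976624574818, -0.0727326195125265),
      hi = c( 0.0727326195125265,  0.3378976624574818, -0.8525720202116004,
              0.3848648468648578,  0.0727326195125265, -0.0156557281357920)),
    stop("unknown wavelet family: ", family))
}

#' Single-level undecimated 3D wavelet sub-band
#'
#' Separable convolution with the low/high-pass decomposition filters
#' along x, y, z as given by the sub-band code; no downsampling, symmetric
#' boundary extension, so the output grid equals the input grid.
#'
#' @param values 3D numeric array.
#' @param wcfg a [wavelet_config()].
#' @return 3D array of sub-band coefficients, same shape as the input.
#' @export
wavelet_subband <- function(values, wcfg = wavelet_config()) {
  f <- wavelet_filters(wcfg$family)
  letters3 <- strsplit(wcfg$subband, "")[[1]]
  out <- values
  for (ax in 1:3) {
    k <- if (letters3[ax] == "L") f$lo else f$hi
    out <- conv_axis(out, k, ax, pad = "reflect")
  }
  out
}

#' Wavelet gray-level nonuniformity
#'
#' Applies the configured wavelet sub-band filter to the image and
#' computes [glrlm_gray_level_nonuniformity()] on the filtered values
#' inside the mask. For a constant image the high-pass sub-band is ~0
#' everywhere, giving the single-bin degenerate GLN (= run count).
#'
#' @inheritParams glrlm_gray_level_nonuniformity
#' @param wcfg a [wavelet_config()].
#' @return wavelet nonuniformity (dimensionless).
#' @export
wavelet_gln <- function(image, mask, wcfg = wavelet_config(),
                        disc = discretization_config()) {
  values <- if (inherits(image, "image_volume")) image$values else image
  if (!any(mask)) {
    warning("empty mask: wavelet nonuniformity undefined")
    return(NA_real_)
  }
  sub <- wavelet_subband(values, wcfg)
  glrlm_gray_level_nonuniformity(sub, mask, disc = disc)
}
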