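#' Image volume with physical voxel spacing
#'
#' A light container for a 3D scalar grid of CT attenuation values
#' (Hounsfield units) together with its anisotropic voxel spacing in mm.
#' The axis order is fixed throughout the package:
#' axis 1 = x (left-right), axis 2 = y (anterior-posterior),
#' axis 3 = z (cranio-caudal). The geometric-spread features MSx/MSy/MSz
#' are defined against this order.
#'
#' @param values 3D numeric array of attenuation (HU).
#' @param spacing numeric length-3, voxel spacing in mm per axis, all > 0.
#' @return an object of class `image_volume` with elements `values` and
#'   `spacing`.
#' @export
image_volume <- function(values, spacing) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            is.numeric(spacing), length(spacing) == 3L, all(spacing > 0))
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$values), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm\n", sep = "")
  invisible(x)
}

#' Segmentation set sharing an image grid
#'
#' Holds the liver mask, the left/right functional-lobe labels and the
#' per-lesion label map on the same grid as the image volume. Lesion labels
#' are positive integers, one per 26-connected component; 0 is background.
#' Lobe labels use 1 = left, 2 = right, 0 = outside the liver.
#'
#' @param liver_mask logical or 0/1 3D array.
#' @param lobe_labels integer 3D array (0 background, 1 left, 2 right).
#' @param lesion_labels integer 3D array (0 background, k = lesion k).
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param relabel if `TRUE` (default) the lesion map is relabeled as the
#'   26-connected components of its support, so the lesion-count invariant
#'   holds even if the input labels merged or split regions.
#' @return an object of class `segmentation_set`.
#' @export
segmentation_set <- function(liver_mask, lobe_labels, lesion_labels, spacing,
                             relabel = TRUE) {
  liver_mask <- array(as.logical(liver_mask), dim = dim(liver_mask))
  stopifnot(length(dim(liver_mask)) == 3L,
            identical(dim(liver_mask), dim(lobe_labels)),
            identical(dim(liver_mask), dim(lesion_labels)),
            length(spacing) == 3L, all(spacing > 0))
  if (any(lesion_labels[!liver_mask] != 0))
    stop("lesion voxels found outside the liver mask")
  if (any((lobe_labels != 0) != liver_mask))
    stop("lobe labels must partition the liver mask")
  if (relabel)
    lesion_labels <- label_components_26(lesion_labels > 0)
  structure(list(liver_mask = liver_mask,
                 lobe_labels = lobe_labels,
                 lesion_labels = lesion_labels,
                 spacing = as.numeric(spacing)),
            class = "segmentation_set")
}

#' @export
print.segmentation_set <- function(x, ...) {
  cat("<segmentation_set> ", paste(dim(x$liver_mask), collapse = "x"),
      " voxels, ", max(x$lesion_labels), " lesion(s), liver ",
      sum(x$liver_mask), " voxels\n", sep = "")
  invisible(x)
}

#' Label 26-connected components of a 3D binary mask
#'
#' Breadth-first flood fill over the 26-neighborhood (face, edge and corner
#' adjacency). Components are numbered 1..K in order of their smallest
#' linear index, so labeling is deterministic.
#'
#' @param mask logical 3D array.
#' @return integer array of the same shape; 0 = background.
#' @export
label_components_26 <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)

  co <- arrayInd(idx, d)
  # map from linear index to row of co for O(1) neighbor lookup
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)

  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]

  comp <- integer(length(idx))
  k <- 0L
  for (start in seq_along(idx)) {
    if (comp[start] != 0L) next
    k <- k + 1L
    frontier <- start
    comp[start] <- k
    while (length(frontier)) {
      p <- co[frontier, , drop = FALSE]
      # all 26 neighbors of the whole frontier at once
      nx <- rep(p[, 1], times = nrow(nb)) + rep(nb[, 1], each = nrow(p))
      ny <- rep(p[, 2], times = nrow(nb)) + rep(nb[, 2], each = nrow(p))
      nz <- rep(p[, 3], times = nrow(nb)) + rep(nb[, 3], each = nrow(p))
      ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] & nz >= 1L & nz <= d[3]
      lin <- (nz[ok] - 1L) * (d[1] * d[2]) + (ny[ok] - 1L) * d[1] + nx[ok]
      r <- pos[lin]
      r <- unique(r[r > 0L])
      r <- r[comp[r] == 0L]
      comp[r] <- k
      frontier <- r
    }
  }
  lab[idx] <- comp
  lab
}

# voxel-center physical coordinates (mm) for rows of an arrayInd matrix
voxel_centers_mm <- function(ind, spacing) {
  sweep(ind - 0.5, 2L, spacing, `*`)
}
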