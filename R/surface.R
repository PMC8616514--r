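#' Surface area of a binary 3D region in physical units
#'
#' Default method `"mesh"`: the binary mask is lightly Gaussian-smoothed
#' (anti-aliasing) and the 0.5 iso-surface is triangulated by marching
#' tetrahedra with linear interpolation along tetrahedron edges; the result
#' is the total triangle area in mm^2. This tracks the smooth boundary of
#' the region instead of its voxelized staircase, which is essential because
#' naive voxel-face counting overestimates the area of a sphere by up to
#' 50%. Method `"voxel"` (exposed for comparison) counts exposed voxel
#' faces weighted by their physical face area.
#'
#' @param mask logical 3D array.
#' @param spacing numeric length-3 voxel spacing (mm).
#' @param method `"mesh"` (iso-surface triangulation, default) or
#'   `"voxel"` (face counting).
#' @param smooth_sigma_mm Gaussian sigma for the anti-aliasing step of the
#'   mesh method, in mm per axis; default 0.75 voxels per axis, the value
#'   that balances staircase overestimation (no smoothing) against
#'   curvature shrinkage (heavy smoothing). Regions so small that
#'   smoothing drops them below the iso-level fall back to the unsmoothed
#'   binary surface.
#' @return surface area in mm^2 (0 for an empty mask).
#' @export
surface_area_mm2 <- function(mask, spacing, method = c("mesh", "voxel"),
                             smooth_sigma_mm = 0.75 * spacing) {
  method <- match.arg(method)
  stopifnot(length(dim(mask)) == 3L, length(spacing) == 3L)
  if (!any(mask)) return(0)
  if (method == "voxel") return(voxel_face_area(mask, spacing))

  smooth_sigma_mm <- rep_len(smooth_sigma_mm, 3L)
  cr <- crop_to_bbox(mask, margin = ceiling(3 * smooth_sigma_mm / spacing) + 2L)
  field <- gaussian_smooth_3d(cr * 1.0, smooth_sigma_mm, spacing, pad = "zero")
  if (max(field) < 0.5)                      # region thinner than the kernel
    field <- cr * 1.0
  marching_tetrahedra_area(field, spacing, level = 0.5)
}

# Crop a mask to its bounding box plus a margin (clamped to the grid).
crop_to_bbox <- function(mask, margin = 2L) {
  d <- dim(mask)
  ind <- which(mask)
  co <- arrayInd(ind, d)
  margin <- rep_len(margin, 3L)
  lo <- pmax(1L, apply(co, 2, min) - margin)
  hi <- pmin(d, apply(co, 2, max) + margin)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

# Total iso-surface area by marching tetrahedra.
#
# Each grid cell (cube of 8 voxel centers) is split into six tetrahedra
# around the main diagonal; inside a tetrahedron the level set of the
# linear interpolant is a single triangle (one corner separated) or a quad
# (two-vs-two), so no case tables are required. The field is zero-padded
# by one layer so surfaces touching the array boundary are closed.
marching_tetrahedra_area <- function(field, spacing, level = 0.5) {
  d <- dim(field)
  fp <- array(0, d + 2L)
  fp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- field
  d <- dim(fp)
  nc <- d - 1L                       # cubes per axis

  # corner offsets, base corner 1 = (0,0,0), corner 8 = (1,1,1)
  off <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  corner_vals <- lapply(1:8, function(c8) {
    as.vector(fp[(1:nc[1]) + off[c8, 1],
                 (1:nc[2]) + off[c8, 2],
                 (1:nc[3]) + off[c8, 3]])
  })
  # cube base coordinates in mm (arbitrary origin; only areas matter)
  base <- arrayInd(seq_len(prod(nc)), nc)
  basemm <- voxel_centers_mm(base, spacing)
  corner_pos <- lapply(1:8, function(c8) {
    sweep(basemm, 2L, off[c8, ] * spacing, `+`)
  })

  # six tetrahedra sharing the 1-8 diagonal (a valid cube decomposition)
  tets <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))

  total <- 0
  for (t in seq_len(nrow(tets))) {
    v <- corner_vals[tets[t, ]]
    # skip cubes where the tet cannot intersect the level set
    vmin <- pmin(v[[1]], v[[2]], v[[3]], v[[4]])
    vmax <- pmax(v[[1]], v[[2]], v[[3]], v[[4]])
    act <- which(vmin < level & vmax >= level)
    if (!length(act)) next
    va <- lapply(v, `[`, act)
    pa <- lapply(corner_pos[tets[t, ]], function(m) m[act, , drop = FALSE])
    total <- total + tet_patch_area(va, pa, level)
  }
  total
}

# Area contributed by one tetrahedron family over a vector of cells.
tet_patch_area <- function(v, p, level) {
  above <- lapply(v, function(x) x >= level)
  id <- above[[1]] + 2L * above[[2]] + 4L * above[[3]] + 8L * above[[4]]

  interp <- function(ia, ib, sel) {
    w <- (level - v[[ia]][sel]) / (v[[ib]][sel] - v[[ia]][sel])
    p[[ia]][sel, , drop = FALSE] +
      w * (p[[ib]][sel, , drop = FALSE] - p[[ia]][sel, , drop = FALSE])
  }
  tri_area <- function(q1, q2, q3) {
    u <- q2 - q1; w <- q3 - q1
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
  }

  total <- 0
  for (code in 1:14) {                      # 0 and 15 contribute nothing
    sel <- which(id == code)
    if (!length(sel)) next
    A <- which(as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L))))
    B <- setdiff(1:4, A)
    if (length(A) == 1L || length(B) == 1L) {
      lone <- if (length(A) == 1L) A else B
      rest <- setdiff(1:4, lone)
      q1 <- interp(lone, rest[1], sel)
      q2 <- interp(lone, rest[2], sel)
      q3 <- interp(lone, rest[3], sel)
      total <- total + tri_area(q1, q2, q3)
    } else {
      # two above, two below: quad split into two triangles
      q1 <- interp(A[1], B[1], sel)
      q2 <- interp(A[1], B[2], sel)
      q3 <- interp(A[2], B[2], sel)
      q4 <- interp(A[2], B[1], sel)
      total <- total + tri_area(q1, q2, q3) + tri_area(q1, q3, q4)
    }
  }
  total
}

# Exposed-face count weighted by physical face areas.
voxel_face_area <- function(mask, spacing) {
  d <- dim(mask)
  mp <- array(FALSE, d + 2L)
  mp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  total <- 0
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  dp <- dim(mp)
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ]
    neigh <- mp[(2:(d[1] + 1L)) + sh[1],
                (2:(d[2] + 1L)) + sh[2],
                (2:(d[3] + 1L)) + sh[3]]
    total <- total + sum(mask & !neigh) * face[which(sh != 0)]
  }
  total
}
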