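#' Discretization settings for run-length texture features
#'
#' CT intensities inside the region of interest are discretized with a
#' fixed bin width before run-length analysis, the recommended practice
#' for calibrated units such as HU. Bin 1 starts at the minimum intensity
#' found in the region.
#'
#' @param bin_width bin width in intensity units (HU); default 25.
#' @param aggregation `"merge"` (default): run counts are pooled over all
#'   13 directions before computing the statistic; `"average"`: the
#'   statistic is computed per direction and averaged.
#' @return a `discretization_config` list.
#' @export
discretization_config <- function(bin_width = 25, aggregation = c("merge", "average")) {
  stopifnot(is.numeric(bin_width), bin_width > 0)
  structure(list(bin_width = bin_width, aggregation = match.arg(aggregation)),
            class = "discretization_config")
}

# the 13 unique (non-collinear up to sign) 3D directions of the
# 26-neighborhood, the canonical direction set for 3D run-length matrices
glrlm_directions <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# Fixed-bin-width discretization over the mask; returns an integer array
# with NA outside the mask. A constant region maps to a single bin.
discretize_fbw <- function(values, mask, bin_width) {
  out <- array(NA_integer_, dim = dim(values))
  v <- values[mask]
  out[mask] <- as.integer(floor((v - min(v)) / bin_width)) + 1L
  out
}

#' Gray-level run-length matrix over the 13 3D directions
#'
#' Runs are maximal sequences of voxels sharing the same discretized gray
#' level along a direction, restricted to the mask (a gap in the mask ends
#' a run). Returns one run-count matrix per direction with rows = gray
#' bins, columns = run lengths.
#'
#' @param bins integer array of discretized gray levels, NA outside the
#'   region of interest (as produced by the fixed-bin-width discretizer).
#' @param directions integer matrix of direction offsets (default the
#'   canonical 13).
#' @return list of integer matrices, one per direction, all with identical
#'   dimensions (max gray bin x max run length over directions).
#' @export
glrlm_matrices <- function(bins, directions = glrlm_directions()) {
  d <- dim(bins)
  stopifnot(length(d) == 3L)
  idx <- which(!is.na(bins))
  if (!length(idx)) stop("empty region of interest")
  ng <- max(bins, na.rm = TRUE)

  co <- arrayInd(seq_len(prod(d)), d)
  v_all <- as.integer(bins)
  v_all[is.na(v_all)] <- 0L             # 0 = outside mask, breaks runs

  runs <- vector("list", nrow(directions))
  for (di in seq_len(nrow(directions))) {
    dir <- directions[di, ]
    a <- which(dir != 0)[1]
    t <- co[, a] * dir[a]               # position along the direction
    k1 <- co[, 1] - t * dir[1]
    k2 <- co[, 2] - t * dir[2]
    k3 <- co[, 3] - t * dir[3]
    ord <- order(k1, k2, k3, t)
    line_change <- c(TRUE, diff(k1[ord]) != 0 | diff(k2[ord]) != 0 |
                           diff(k3[ord]) != 0)
    g <- cumsum(line_change)
    code <- g * (ng + 1) + v_all[ord]   # distinct per (line, gray level)
    r <- rle(code)
    gray <- r$values %% (ng + 1)
    keep <- gray > 0
    runs[[di]] <- cbind(gray = gray[keep], len = r$lengths[keep])
  }

  maxlen <- max(vapply(runs, function(r) max(r[, "len"]), 0))
  lapply(runs, function(r) {
    m <- matrix(0L, nrow = ng, ncol = maxlen)
    tab <- table(factor(r[, "gray"], levels = 1:ng),
                 factor(r[, "len"], levels = 1:maxlen))
    m[] <- as.integer(tab)
    m
  })
}

#' Gray-level nonuniformity of the run-length matrix (GLRLM GLN)
#'
#' GLN = sum_i (sum_j R(i,j))^2 / sum_ij R(i,j); low when runs are spread
#' evenly over gray levels, high when few gray levels dominate. With the
#' default `"merge"` aggregation the run matrices of all 13 directions are
#' pooled first; with `"average"` the statistic is averaged over
#' directions. A single-bin region degenerates to the total run count.
#'
#' @param image `image_volume` or 3D numeric array.
#' @param mask logical array, the region of interest (>= 2 voxels).
#' @param disc a [discretization_config()].
#' @param directions direction set (default canonical 13).
#' @return GLN (dimensionless).
#' @export
glrlm_gray_level_nonuniformity <- function(image, mask,
                                           disc = discretization_config(),
                                           directions = glrlm_directions()) {
  values <- if (inherits(image, "image_volume")) image$values else image
  if (sum(mask) < 2L) stop("mask must contain at least 2 voxels")
  cr <- bbox_pair(values, mask)
  bins <- discretize_fbw(cr$values, cr$mask, disc$bin_width)
  mats <- glrlm_matrices(bins, directions)
  if (disc$aggregation == "merge") {
    R <- Reduce(`+`, mats)
    gln_of(R)
  } else {
    mean(vapply(mats, gln_of, 0))
  }
}

gln_of <- function(R) {
  n_runs <- sum(R)
  if (n_runs == 0) return(NA_real_)
  sum(rowSums(R)^2) / n_runs
}

# crop values+mask jointly to the mask bounding box (1-voxel margin)
bbox_pair <- function(values, mask, margin = 1L) {
  d <- dim(mask)
  co <- arrayInd(which(mask), d)
  lo <- pmax(1L, apply(co, 2, min) - margin)
  hi <- pmin(d, apply(co, 2, max) + margin)
  list(values = values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}
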