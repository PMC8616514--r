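# Separable filtering along one axis of a 3D array.
#
# Shared by the Gaussian pre-smoothing of surface extraction, the optional
# low-pass noise texture of the phantom generator, and the undecimated
# wavelet transform. Padding: "zero" (outside = 0) or "reflect"
# (half-sample symmetric, the usual choice for wavelet sub-bands).

conv_axis <- function(arr, kernel, axis, pad = c("reflect", "zero"),
                      origin = NULL) {
  pad <- match.arg(pad)
  d <- dim(arr)
  stopifnot(length(d) == 3L, axis %in% 1:3)
  nk <- length(kernel)
  if (is.null(origin)) origin <- (nk + 1L) %/% 2L  # center tap

  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  n <- dp[1]
  m <- dp[2] * dp[3]
  dim(x) <- c(n, m)

  lpad <- origin - 1L
  rpad <- nk - origin
  if (pad == "zero") {
    xp <- rbind(matrix(0, lpad, m), x, matrix(0, rpad, m))
  } else {
    top <- x[pmin(n, pmax(1L, lpad:1)), , drop = FALSE]
    bot <- x[pmin(n, pmax(1L, n:(n - rpad + 1L))), , drop = FALSE]
    if (lpad == 0L) top <- x[integer(0), , drop = FALSE]
    if (rpad == 0L) bot <- x[integer(0), , drop = FALSE]
    xp <- rbind(top, x, bot)
  }
  out <- matrix(0, n, m)
  for (k in seq_len(nk)) {
    if (kernel[k] != 0)
      out <- out + kernel[k] * xp[k:(k + n - 1L), , drop = FALSE]
  }
  dim(out) <- dp
  aperm(out, order(perm))
}

# Truncated, renormalized Gaussian kernel; sigma in samples.
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with sigma given in mm per axis.
gaussian_smooth_3d <- function(arr, sigma_mm, spacing, pad = "reflect") {
  sigma_mm <- rep_len(sigma_mm, 3L)
  for (ax in 1:3) {
    s_vox <- sigma_mm[ax] / spacing[ax]
    if (s_vox > 1e-8)
      arr <- conv_axis(arr, gaussian_kernel(s_vox), ax, pad = pad)
  }
  arr
}
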