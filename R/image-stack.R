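#' Construct an image stack with physical voxel spacing
#'
#' An `image_stack` is the unit of axon quantification: a 3D grid of
#' non-negative intensities in `(z, y, x)` order plus the physical voxel
#' spacing in micrometers. Voxel indices are 0-based internally: the
#' physical position of the center of voxel `[i, j, k]` (1-based R index)
#' is `(i - 1, j - 1, k - 1) * spacing_um`.
#'
#' @param voxels 3D numeric array, dimensions `(nz, ny, nx)`, finite and
#'   non-negative.
#' @param spacing_um numeric length-3 `(dz, dy, dx)` in micrometers, all
#'   positive. Confocal stacks are typically anisotropic (axial step larger
#'   than the in-plane pixel size).
#' @return An object of class `image_stack`.
#' @examples
#' st <- image_stack(array(0, dim = c(4, 8, 8)), spacing_um = c(0.27, 0.2, 0.2))
#' dim(st$voxels)
#' @export
image_stack <- function(voxels, spacing_um) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array (z, y, x)", call. = FALSE)
  if (any(dim(voxels) < 1L))
    stop("all stack dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(voxels)))
    stop("stack intensities must be finite", call. = FALSE)
  if (any(voxels < 0))
    stop("stack intensities must be non-negative", call. = FALSE)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || !all(is.finite(spacing_um)) ||
      any(spacing_um <= 0))
    stop("'spacing_um' must be 3 positive numbers (dz, dy, dx)",
         call. = FALSE)
  structure(list(voxels = voxels, spacing_um = spacing_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3],
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Physical volume of the full stack extent
#'
#' Volume covered by all voxels, `prod(dim) * prod(spacing)`, in cubic
#' millimeters. Used as the analyzed volume when no explicit ROI
#' specification is supplied.
#'
#' @param stack an [image_stack()].
#' @return volume in mm^3.
#' @export
stack_extent_volume <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  prod(dim(stack$voxels)) * prod(stack$spacing_um) / 1e9
}

# shift a 3D array by k along one axis, zero-filling; helper for separable
# convolution and for counting adjacent voxel pairs
shift3 <- function(a, k, axis) {
  if (k == 0L) return(a)
  d <- dim(a)
  out <- array(0, dim = d)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  ix_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ix_dst <- ix_src
  ix_src[[axis]] <- src
  ix_dst[[axis]] <- dst
  out[ix_dst[[1]], ix_dst[[2]], ix_dst[[3]]] <-
    a[ix_src[[1]], ix_src[[2]], ix_src[[3]]]
  out
}

# separable Gaussian blur; sigma_vox is per-axis (z, y, x) in voxel units,
# zero entries skip the axis. Kernel weights are renormalized at the
# borders (no zero-padding darkening), so constant inputs stay constant.
gaussian_blur3 <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    acc <- array(0, dim = dim(a))
    wsum <- array(0, dim = dim(a))
    ones <- array(1, dim = dim(a))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift3(a, j - r - 1L, axis)
      wsum <- wsum + k[j] * shift3(ones, j - r - 1L, axis)
    }
    a <- acc / wsum
  }
  a
}
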