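#' Otsu threshold of an intensity sample
#'
#' Classic histogram threshold maximizing between-class variance, computed
#' on a fixed-width 256-bin histogram over the observed intensity range.
#' Returns the bin-edge threshold; voxels strictly above it are foreground.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins histogram resolution.
#' @return threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])     # constant input: see binarize_stack
  h <- tabulate(pmin(pmax(
    findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1L),
                 rightmost.closed = TRUE), 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  # between-class variance for a cut after each bin
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(bcv)
  rng[1] + k * diff(rng) / n_bins
}

#' Segment an image stack into a binary axon mask
#'
#' The segmentation step of the axon-length pipeline: optional in-plane
#' Gaussian pre-smoothing, global thresholding (Otsu by default, or a fixed
#' value), then removal of small 26-connected components (noise specks).
#' A constant-intensity stack yields an empty mask by convention (there is
#' nothing to segment), not an error. All parameters are recorded as
#' attributes for provenance.
#'
#' @param stack an [image_stack()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold (required when `method = "fixed"`);
#'   voxels strictly above it are foreground. A fixed threshold outside
#'   the intensity range produces an empty or full mask with a warning.
#' @param smooth_sigma in-plane pre-smoothing sigma in voxels (applied per
#'   z-slice); 0 disables.
#' @param min_object_vox connected components smaller than this many
#'   voxels are discarded.
#' @return An object of class `binary_mask`: list with logical array
#'   `mask` (same shape as the stack) and `spacing_um`.
#' @export
binarize_stack <- function(stack, method = c("otsu", "fixed"),
                           threshold = NULL, smooth_sigma = 1,
                           min_object_vox = 27L) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  v <- stack$voxels
  if (smooth_sigma > 0)
    v <- gaussian_blur3(v, c(0, smooth_sigma, smooth_sigma))
  rng <- range(v)
  if (method == "otsu") {
    if (diff(rng) == 0) {
      m <- array(FALSE, dim = dim(v))     # constant stack: empty foreground
      thr <- rng[1]
    } else {
      thr <- otsu_threshold(v)
      m <- v > thr
    }
  } else {
    if (is.null(threshold) || !is.numeric(threshold))
      stop("method = 'fixed' requires a numeric 'threshold'", call. = FALSE)
    thr <- threshold
    if (thr < rng[1]) {
      warning("fixed threshold below the intensity range: full mask")
    } else if (thr >= rng[2] && diff(rng) > 0) {
      warning("fixed threshold at/above the intensity range: empty mask")
    }
    m <- v > thr
  }
  dim(m) <- dim(v)
  if (min_object_vox > 1L && any(m)) {
    lab <- .cpp_label_components_26(m, dim(m))
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_vox)
    m <- array(lab %in% keep & lab > 0L, dim = dim(m))
  }
  structure(list(mask = m, spacing_um = stack$spacing_um),
            class = "binary_mask",
            method = method, threshold = thr,
            smooth_sigma = smooth_sigma, min_object_vox = min_object_vox)
}

# the 13 positive 26-neighborhood offsets (half of the 26, so each
# unordered adjacent voxel pair is visited exactly once)
.HALF_OFFSETS <- {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  as.matrix(g[g$dx > 0 | (g$dx == 0 & g$dy > 0) |
              (g$dx == 0 & g$dy == 0 & g$dz > 0), c("dz", "dy", "dx")])
}

#' Extract the centerline skeleton of a binary mask
#'
#' Thins the mask to a one-voxel-thick curve skeleton with a 3D
#' topology-preserving thinning (iterative directional removal of simple
#' border points, preserving line endpoints), then builds the skeleton
#' graph: nodes are skeleton voxels, edges connect every 26-adjacent
#' skeleton voxel pair exactly once, and each edge carries its anisotropic
#' physical length. Thinning runs on the native (anisotropic) grid; the
#' spacing enters only through the edge lengths.
#'
#' @param mask a [binarize_stack()] result (`binary_mask`).
#' @return An object of class `skeleton_graph`: list with `voxels`
#'   (logical skeleton array), `nodes` (n x 3 matrix of 1-based `(z, y, x)`
#'   voxel indices), `edges` (data.frame `from, to, length_um`) and
#'   `spacing_um`. An empty mask gives an empty graph.
#' @export
skeletonize_stack <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$mask)
  skel <- if (any(mask$mask)) .cpp_thin_3d(mask$mask, d)
          else array(FALSE, dim = d)
  nodes <- which(skel, arr.ind = TRUE)
  colnames(nodes) <- c("z", "y", "x")
  # map voxel -> node id, then read off adjacent pairs per offset
  id <- array(0L, dim = d)
  id[skel] <- seq_len(nrow(nodes))
  # reorder ids to match 'nodes' row order (which() is column-major, same
  # order as seq over skel TRUE positions, so this is already consistent)
  edges <- list()
  for (r in seq_len(nrow(.HALF_OFFSETS))) {
    off <- .HALF_OFFSETS[r, ]
    shifted <- shift3(id, off[1], 1L)
    shifted <- shift3(shifted, off[2], 2L)
    shifted <- shift3(shifted, off[3], 3L)
    hit <- id > 0L & shifted > 0L
    if (!any(hit)) next
    len <- sqrt(sum((off * mask$spacing_um)^2))
    edges[[length(edges) + 1L]] <-
      data.frame(from = shifted[hit], to = id[hit], length_um = len)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = integer(), to = integer(), length_um = numeric())
  structure(list(voxels = skel, nodes = nodes, edges = edges,
                 spacing_um = mask$spacing_um),
            class = "skeleton_graph")
}

#' Total skeleton length
#'
#' Sum of unique-edge lengths of a skeleton graph,
#' `sum over edges of sqrt((dz*sz)^2 + (dy*sy)^2 + (dx*sx)^2)`, reported
#' in millimeters. Each 26-adjacency contributes exactly once.
#'
#' @param skel a [skeletonize_stack()] result.
#' @param spacing_um optional spacing override `(dz, dy, dx)` um; default
#'   is the spacing stored in the graph.
#' @return total length in mm.
#' @export
skeleton_length <- function(skel, spacing_um = NULL) {
  stopifnot(inherits(skel, "skeleton_graph"))
  if (is.null(spacing_um)) spacing_um <- skel$spacing_um
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) ||
      any(spacing_um <= 0))
    stop("'spacing_um' must be 3 positive numbers", call. = FALSE)
  if (nrow(skel$edges) == 0L) return(0)
  dv <- skel$nodes[skel$edges$from, , drop = FALSE] -
        skel$nodes[skel$edges$to, , drop = FALSE]
  sum(sqrt((dv[, 1] * spacing_um[1])^2 +
           (dv[, 2] * spacing_um[2])^2 +
           (dv[, 3] * spacing_um[3])^2)) / 1000
}

#' Analyzed volume from an ROI specification
#'
#' `ROI area x number of slices x axial step`, in mm^3.
#'
#' @param roi an [roi_spec()].
#' @return volume in mm^3.
#' @examples
#' stack_volume(roi_spec(0.01, 100, 0.27))  # 0.00027 mm^3
#' @export
stack_volume <- function(roi) {
  stopifnot(inherits(roi, "roi_spec"))
  roi$roi_area_mm2 * roi$n_slices * (roi$step_um / 1000)
}

#' Measure one stack: axon length, volume, density
#'
#' Runs segmentation and skeletonization on a stack and reports total axon
#' length (mm), analyzed volume (mm^3) and density (mm/mm^3). When an
#' [roi_spec()] is supplied it defines the analyzed volume; otherwise the
#' full stack extent is used.
#'
#' @param stack an [image_stack()].
#' @param roi optional [roi_spec()].
#' @param ... passed to [binarize_stack()].
#' @return one-row data.frame `axon_length_mm, volume_mm3,
#'   density_mm_per_mm3`, with the segmentation parameters attached as the
#'   `"provenance"` attribute.
#' @export
quantify_stack <- function(stack, roi = NULL, ...) {
  mask <- binarize_stack(stack, ...)
  skel <- skeletonize_stack(mask)
  len <- skeleton_length(skel)
  vol <- if (is.null(roi)) stack_extent_volume(stack) else stack_volume(roi)
  out <- data.frame(axon_length_mm = len, volume_mm3 = vol,
                    density_mm_per_mm3 = len / vol)
  attr(out, "provenance") <- list(
    method = attr(mask, "method"), threshold = attr(mask, "threshold"),
    smooth_sigma = attr(mask, "smooth_sigma"),
    min_object_vox = attr(mask, "min_object_vox"),
    volume_source = if (is.null(roi)) "stack extent" else "roi_spec")
  out
}

#' Region-level relative axon density (RAD)
#'
#' Sums axon length and analyzed volume over all stacks captured in one
#' region of one animal; RAD is the density over the summed totals
#' (total length / total volume), not the mean of per-stack densities.
#'
#' @param measurements data.frame with columns `axon_length_mm` and
#'   `volume_mm3` (e.g. rows from [quantify_stack()]), one row per stack.
#' @param region optional region label.
#' @return An object of class `region_summary`: list with `region`,
#'   `total_length_mm`, `total_volume_mm3`, `rad`.
#' @export
region_rad <- function(measurements, region = NA_character_) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0L)
    stop("need at least one stack measurement", call. = FALSE)
  stopifnot(all(c("axon_length_mm", "volume_mm3") %in% names(measurements)))
  tl <- sum(measurements$axon_length_mm)
  tv <- sum(measurements$volume_mm3)
  if (tv <= 0) stop("total volume must be positive", call. = FALSE)
  structure(list(region = region, total_length_mm = tl,
                 total_volume_mm3 = tv, rad = tl / tv),
            class = "region_summary")
}

#' Per-animal density ratio between two target regions
#'
#' The ratio RAD_VTA / RAD_NAc: 1 means both regions are equally
#' innervated, values above 1 indicate VTA preference, below 1 NAc
#' preference.
#'
#' @param rad_vta,rad_nac [region_rad()] results (or bare densities).
#' @return the ratio, a single number.
#' @export
rad_ratio <- function(rad_vta, rad_nac) {
  g <- function(x) if (inherits(x, "region_summary")) x$rad else
    as.numeric(x)
  v <- g(rad_vta); n <- g(rad_nac)
  if (!is.finite(n) || n <= 0)
    stop("reference (NAc) density must be positive: ratio undefined",
         call. = FALSE)
  if (!is.finite(v) || v < 0)
    stop("VTA density must be non-negative", call. = FALSE)
  v / n
}
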