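# Independent oracles and small fixture builders shared across the suite.

# Brute-force skeleton length: visit every foreground voxel, sum the
# physical distance to each of its 26 neighbors that is also foreground,
# and halve (each unordered pair seen twice). Deliberately naive; use on
# small arrays only.
brute_force_skeleton_length_mm <- function(skel, spacing_um) {
  d <- dim(skel)
  total <- 0
  idx <- which(skel, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    z <- idx[r, 1]; y <- idx[r, 2]; x <- idx[r, 3]
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] ||
          xx < 1 || xx > d[3]) next
      if (skel[zz, yy, xx])
        total <- total + sqrt(sum((c(dz, dy, dx) * spacing_um)^2))
    }
  }
  total / 2 / 1000
}

# Exhaustive Otsu: try a cut after every histogram bin and maximize the
# between-class variance computed directly from the two class means.
otsu_exhaustive <- function(x, n_bins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  best <- -Inf
  best_thr <- rng[1]
  for (k in seq_len(n_bins - 1L)) {
    thr <- edges[k + 1L]
    lo <- x[x <= thr]; hi <- x[x > thr]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_thr <- thr }
  }
  best_thr
}

# degree sequence of a skeleton graph
skeleton_degrees <- function(sk) {
  tabulate(c(sk$edges$from, sk$edges$to), nrow(sk$nodes))
}

# noiseless, PSF-free phantom spec for analytic geometry checks
crisp_spec <- function(shape_vox, spacing_um = c(0.27, 0.2, 0.2),
                       tube_radius_um = 0.4) {
  axon_phantom_spec(noise_model = "none", psf_sigma_um = c(0, 0, 0),
                    background_level = 0, peak_intensity = 100,
                    tube_radius_um = tube_radius_um,
                    spacing_um = spacing_um, shape_vox = shape_vox,
                    seed = 1L)
}

# segment a crisp phantom without smoothing or small-object removal
crisp_binarize <- function(stack) {
  binarize_stack(stack, method = "fixed", threshold = 50,
                 smooth_sigma = 0, min_object_vox = 1L)
}

# cell table reproducing given per-animal counts for one population/axis
cells_from_counts <- function(strata, counts_by_animal, axis = "layer",
                              population = "nac") {
  rows <- list()
  for (a in seq_along(counts_by_animal)) {
    cnt <- counts_by_animal[[a]]
    for (s in seq_along(strata)) {
      n <- cnt[s]
      if (n == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        animal = sprintf("A%02d", a),
        bregma_mm = 2.0,
        subregion = if (axis == "subregion") strata[s] else "PrL",
        layer = if (axis == "layer") strata[s] else "L5a",
        tracer_nac = as.integer(population == "nac"),
        tracer_vta = as.integer(population == "vta"),
        calb1 = NA_integer_, ctip2 = NA_integer_,
        foxp2 = NA_integer_)[rep(1L, n), ]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
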