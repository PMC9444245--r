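test_that("Otsu threshold matches an exhaustive between-class search", {
  set.seed(42)
  x <- c(rnorm(4000, 10, 2), rnorm(1000, 100, 5))
  x <- pmax(x, 0)
  expect_equal(otsu_threshold(x), otsu_exhaustive(x), tolerance = 1e-9)
  # and it separates the two populations
  thr <- otsu_threshold(x)
  expect_gt(thr, 12)
  expect_lt(thr, 95)
})

test_that("fixed-threshold binarization is idempotent on binary stacks", {
  v <- array(sample(0:1, 4 * 8 * 8, replace = TRUE), dim = c(4, 8, 8))
  st <- image_stack(v, c(0.27, 0.2, 0.2))
  m <- binarize_stack(st, method = "fixed", threshold = 0.5,
                      smooth_sigma = 0, min_object_vox = 1L)
  expect_equal(m$mask, v == 1)
})

test_that("constant stacks give an empty mask and zero length downstream", {
  st <- image_stack(array(7, dim = c(4, 8, 8)), c(0.27, 0.2, 0.2))
  m <- binarize_stack(st)
  expect_false(any(m$mask))
  expect_equal(skeleton_length(skeletonize_stack(m)), 0)
})

test_that("out-of-range fixed thresholds warn and saturate", {
  v <- array(runif(4 * 8 * 8, 10, 20), dim = c(4, 8, 8))
  st <- image_stack(v, c(1, 1, 1))
  expect_warning(m1 <- binarize_stack(st, method = "fixed", threshold = 5,
                                      smooth_sigma = 0,
                                      min_object_vox = 1L), "full")
  expect_true(all(m1$mask))
  expect_warning(m2 <- binarize_stack(st, method = "fixed", threshold = 50,
                                      smooth_sigma = 0,
                                      min_object_vox = 1L), "empty")
  expect_false(any(m2$mask))
})

test_that("components below the size threshold are removed", {
  v <- array(0, dim = c(8, 16, 16))
  v[2:7, 2:4, 2:4] <- 100       # 54 voxels, kept
  v[2, 10, 10] <- 100           # isolated speck, removed
  st <- image_stack(v, c(0.27, 0.2, 0.2))
  m <- binarize_stack(st, method = "fixed", threshold = 50,
                      smooth_sigma = 0, min_object_vox = 27L)
  expect_equal(sum(m$mask), 54)
  expect_false(m$mask[2, 10, 10])
})

test_that("single-voxel masks skeletonize to one node and no edges", {
  v <- array(0, dim = c(5, 5, 5)); v[3, 3, 3] <- 1
  st <- image_stack(v * 100, c(0.27, 0.2, 0.2))
  sk <- skeletonize_stack(crisp_binarize(st))
  expect_equal(nrow(sk$nodes), 1L)
  expect_equal(nrow(sk$edges), 0L)
})

test_that("a solid axial tube thins to a single path of exact length", {
  v <- array(0, dim = c(101, 9, 9)); v[, 4:6, 4:6] <- 100
  st <- image_stack(v, c(0.27, 0.2, 0.2))
  sk <- skeletonize_stack(crisp_binarize(st))
  expect_equal(nrow(sk$nodes), 101L)
  deg <- skeleton_degrees(sk)
  expect_equal(sum(deg == 1), 2L)          # two endpoints
  expect_equal(sum(deg > 2), 0L)           # no branches
  expect_equal(skeleton_length(sk), 100 * 0.27 / 1000)  # 27 um
})

test_that("an L-shaped tube thins to a simple unbranched path", {
  sp <- crisp_spec(c(9, 128, 128))
  arm1 <- cbind(1.08, 1.6, seq(2, 20, by = 1))
  arm2 <- cbind(1.08, seq(2.6, 18, by = 1), 20)
  sim <- synthetic_stack_from_centerlines(list(rbind(arm1, arm2)), sp)
  sk <- skeletonize_stack(crisp_binarize(sim$stack))
  deg <- skeleton_degrees(sk)
  expect_equal(sum(deg > 2), 0L)
  expect_equal(sum(deg == 1), 2L)
  expect_equal(skeleton_length(sk) * 1000, sim$truth$total_length_um,
               tolerance = 0.05)
})

test_that("thinning preserves the topology of a closed loop", {
  # square ring: the skeleton must stay a single connected cycle — no
  # endpoints, one 26-connected component, at least one independent cycle
  v <- array(0, dim = c(3, 32, 32))
  v[2, 8:24, 8:10] <- 1; v[2, 8:24, 22:24] <- 1
  v[2, 8:10, 8:24] <- 1; v[2, 22:24, 8:24] <- 1
  st <- image_stack(v * 100, c(0.27, 0.2, 0.2))
  sk <- skeletonize_stack(crisp_binarize(st))
  lab <- projdense:::.cpp_label_components_26(sk$voxels, dim(sk$voxels))
  expect_equal(max(lab), 1L)               # still one component
  # cycle rank E - V + C must stay >= 1: the ring was not broken open
  expect_gte(nrow(sk$edges) - nrow(sk$nodes) + 1L, 1L)
  # short corner spurs are tolerated, but the curve is 1 voxel thick
  deg <- skeleton_degrees(sk)
  expect_lte(sum(deg == 1), 2L)
  expect_lt(nrow(sk$nodes), sum(v) / 2)
})

test_that("skeleton length matches analytic values for diagonal paths", {
  # hand-built 45-degree diagonal skeleton in the xy-plane, 51 voxels
  v <- array(FALSE, dim = c(3, 60, 60))
  for (i in 0:50) v[2, 5 + i, 5 + i] <- TRUE
  st <- image_stack(v * 100, c(0.27, 0.2, 0.2))
  sk <- skeletonize_stack(crisp_binarize(st))
  expect_equal(skeleton_length(sk) * 1000, 50 * 0.2 * sqrt(2),
               tolerance = 1e-9)
})

test_that("skeleton length equals the brute-force 26-neighbor oracle", {
  for (seed in c(2, 9)) {
    sp <- axon_phantom_spec(n_axons = 3, length_range_um = c(10, 25),
                            shape_vox = c(16, 80, 80), seed = seed)
    sim <- generate_axon_stack(sp)
    sk <- skeletonize_stack(binarize_stack(sim$stack))
    expect_equal(skeleton_length(sk),
                 brute_force_skeleton_length_mm(sk$voxels, sk$spacing_um),
                 tolerance = 1e-12)
  }
})

test_that("measured length respects voxel anisotropy", {
  # the same physical 20-um tube along z and along x must measure equally
  spz <- crisp_spec(c(80, 13, 13))
  tube_z <- cbind(seq(0.54, 20.54, by = 0.27), 1.2, 1.2)
  simz <- synthetic_stack_from_centerlines(list(tube_z), spz)
  lz <- skeleton_length(skeletonize_stack(crisp_binarize(simz$stack)))
  spx <- crisp_spec(c(9, 13, 120))
  tube_x <- cbind(1.08, 1.2, seq(1, 21, by = 0.2))
  simx <- synthetic_stack_from_centerlines(list(tube_x), spx)
  lx <- skeleton_length(skeletonize_stack(crisp_binarize(simx$stack)))
  expect_equal(lz * 1000, 20, tolerance = 0.05)
  expect_equal(lx * 1000, 20, tolerance = 0.05)
  # counting voxel steps alone would differ by the spacing ratio; the
  # physical lengths agree only because spacing enters the edge lengths
  expect_equal(lz, lx, tolerance = 0.05)
})

test_that("volume, density and ratio identities hold exactly", {
  expect_equal(stack_volume(roi_spec(0.01, 100, 0.27)), 0.00027)
  expect_equal(stack_volume(roi_spec(1, 1, 1000)), 1)
  m1 <- data.frame(axon_length_mm = 1, volume_mm3 = 0.001)
  expect_equal(region_rad(m1)$rad, 1000)
  m0 <- data.frame(axon_length_mm = 0, volume_mm3 = 0.002)
  expect_equal(region_rad(m0)$rad, 0)
  # additivity and linearity
  m2 <- data.frame(axon_length_mm = c(1, 3), volume_mm3 = c(0.001, 0.001))
  expect_equal(region_rad(m2)$total_volume_mm3, 0.002)
  expect_equal(region_rad(transform(m2, axon_length_mm =
                                         2 * axon_length_mm))$rad,
               2 * region_rad(m2)$rad)
  expect_error(region_rad(data.frame(axon_length_mm = 1, volume_mm3 = 0)),
               "positive")
})

test_that("density ratios reproduce reference per-animal values", {
  expect_equal(signif(rad_ratio(4539.63, 49215.43), 2), 0.092)
  expect_equal(round(rad_ratio(29542.50, 7578.49), 2), 3.90)
  expect_equal(rad_ratio(5, 5), 1)
  expect_error(rad_ratio(5, 0), "positive")
})

test_that("quantify_stack reports the exact density identity", {
  sp <- axon_phantom_spec(n_axons = 2, length_range_um = c(10, 20),
                          shape_vox = c(16, 64, 64), seed = 4)
  sim <- generate_axon_stack(sp)
  m <- quantify_stack(sim$stack)
  expect_equal(m$density_mm_per_mm3, m$axon_length_mm / m$volume_mm3)
  expect_equal(m$volume_mm3, stack_extent_volume(sim$stack))
  roi <- roi_spec(0.001, 16, 0.27)
  m2 <- quantify_stack(sim$stack, roi = roi)
  expect_equal(m2$volume_mm3, stack_volume(roi))
  expect_equal(m2$axon_length_mm, m$axon_length_mm)
  prov <- attr(m2, "provenance")
  expect_equal(prov$volume_source, "roi_spec")
})
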