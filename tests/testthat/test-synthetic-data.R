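test_that("empty phantom gives a background-only stack with zero truth", {
  sp <- axon_phantom_spec(n_axons = 0, shape_vox = c(8, 16, 16),
                          noise_model = "none", psf_sigma_um = c(0, 0, 0),
                          background_level = 12, seed = 5)
  sim <- generate_axon_stack(sp)
  expect_equal(sim$truth$total_length_um, 0)
  expect_true(all(sim$stack$voxels == 12))
})

test_that("an explicit straight 50-um centerline has exact analytic truth", {
  sp <- crisp_spec(c(9, 16, 320))
  line <- cbind(1.08, 1.6, seq(5, 55, by = 1))
  sim <- synthetic_stack_from_centerlines(list(line), sp)
  expect_equal(sim$truth$total_length_um, 50)
})

test_that("ground-truth length equals an independent segment-sum oracle", {
  sp <- axon_phantom_spec(n_axons = 20, length_range_um = c(10, 30),
                          shape_vox = c(24, 128, 128), seed = 7)
  sim <- generate_axon_stack(sp)
  resum <- sum(vapply(sim$truth$centerlines, function(pts) {
    if (nrow(pts) < 2) return(0)
    acc <- 0
    for (i in seq_len(nrow(pts) - 1))
      acc <- acc + sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
    acc
  }, numeric(1)))
  expect_equal(sim$truth$total_length_um, resum, tolerance = 1e-9)
  # all centerlines stay inside the physical extent
  ext <- (sp$shape_vox - 1) * sp$spacing_um
  for (pts in sim$truth$centerlines) {
    expect_true(all(pts >= -1e-9))
    expect_true(all(sweep(pts, 2, ext) <= 1e-9))
  }
})

test_that("phantom generation is seed-deterministic and seed-sensitive", {
  sp <- axon_phantom_spec(n_axons = 3, length_range_um = c(10, 20),
                          shape_vox = c(12, 64, 64), seed = 11)
  a <- generate_axon_stack(sp)
  b <- generate_axon_stack(sp)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth, b$truth)
  sp2 <- axon_phantom_spec(n_axons = 3, length_range_um = c(10, 20),
                           shape_vox = c(12, 64, 64), seed = 12)
  expect_false(identical(generate_axon_stack(sp2)$stack$voxels,
                         a$stack$voxels))
})

test_that("adding axons extends the phantom without altering earlier ones", {
  mk <- function(n) axon_phantom_spec(n_axons = n,
                                      length_range_um = c(10, 20),
                                      shape_vox = c(12, 64, 64), seed = 3)
  s5 <- generate_axon_stack(mk(5))
  s8 <- generate_axon_stack(mk(8))
  expect_gte(s8$truth$total_length_um, s5$truth$total_length_um)
  for (i in 1:5)
    expect_equal(s8$truth$centerlines[[i]], s5$truth$centerlines[[i]])
})

test_that("impossible phantom specifications are rejected", {
  expect_error(axon_phantom_spec(length_range_um = c(500, 600),
                                 shape_vox = c(8, 16, 16)),
               "cannot fit")
  expect_error(axon_phantom_spec(tube_radius_um = 0.01),
               "tube diameter")
  expect_error(axon_phantom_spec(spacing_um = c(0, 0.2, 0.2)), "positive")
  expect_error(axon_phantom_spec(n_axons = -1), "non-negative")
})

test_that("cell tables are deterministic and carry valid categories", {
  sp <- cell_table_spec(n_animals = 2, seed = 9)
  a <- generate_cell_table(sp)
  b <- generate_cell_table(sp)
  expect_identical(a, b)
  expect_true(all(a$subregion %in% c("Cg1", "Cg2", "PrL", "IL", "MO",
                                     "DP", "DTT", "other")))
  expect_true(all(a$layer %in% c("L1", "L2/3", "L5a", "L5b", "L6")))
  expect_true(all(a$tracer_nac == 1 | a$tracer_vta == 1))
  expect_silent(validate_cell_table(a))
  expect_error(cell_table_spec(expected_counts = data.frame(
    population = "nac", subregion = "XX", layer = "L1", mean_count = 5)),
    "unknown subregion")
})

test_that("degenerate colabel probabilities propagate to the summaries", {
  sp1 <- cell_table_spec(n_animals = 3, colabel_prob = 1,
                         marker_tested_prob = 1, seed = 21)
  cells <- generate_cell_table(sp1)
  cp <- colabel_proportions(cells, "nac", "calb1")
  kept <- cp[!cp$suppressed, ]
  expect_true(all(abs(kept$mean_pct - 100) < 1e-9))
  expect_true(all(kept$sd_pct < 1e-9))

  sp0 <- cell_table_spec(n_animals = 3, double_projection_prob = 0,
                         seed = 22)
  ov <- overlap_statistics(generate_cell_table(sp0))
  expect_equal(ov$summary$mean_pct, c(0, 0, 0))
  expect_equal(ov$summary$sd_pct, c(0, 0, 0))
})

test_that("recovered colabel proportion sits in the exact binomial band", {
  # ~300 cells/animal, 3 animals, generative probability 0.7
  ec <- data.frame(population = "nac", subregion = "PrL", layer = "L2/3",
                   mean_count = 300)
  sp <- cell_table_spec(n_animals = 3, expected_counts = ec,
                        colabel_prob = 0.7, marker_tested_prob = 1,
                        double_projection_prob = 0, seed = 33)
  cells <- generate_cell_table(sp)
  cp <- colabel_proportions(cells, "nac", "calb1",
                            layer_groups = list("L2/3" = "L2/3"))
  tot <- cp[cp$group == "Total", ]
  n <- tot$pooled_den
  lo <- 100 * qbinom(0.005, n, 0.7) / n
  hi <- 100 * qbinom(0.995, n, 0.7) / n
  pooled_pct <- 100 * tot$pooled_num / tot$pooled_den
  expect_gte(pooled_pct, lo)
  expect_lte(pooled_pct, hi)
})

test_that("ground truth survives a round trip through delimited text", {
  sp <- axon_phantom_spec(n_axons = 2, length_range_um = c(10, 15),
                          shape_vox = c(12, 64, 64), seed = 13)
  sim <- generate_axon_stack(sp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, path)
  seg <- read.csv(path)
  relen <- sum(sqrt((seg$z1 - seg$z0)^2 + (seg$y1 - seg$y0)^2 +
                    (seg$x1 - seg$x0)^2))
  expect_equal(relen, sim$truth$total_length_um, tolerance = 1e-9)
  summ <- read.csv(paste0(path, ".summary.csv"))
  expect_equal(summ$total_length_um, sim$truth$total_length_um)
})
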