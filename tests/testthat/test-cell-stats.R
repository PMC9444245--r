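test_that("anteroposterior bins follow the printed 2-decimal boundaries", {
  expect_equal(as.character(assign_ap_bin(3.05)), ">2.80 mm")
  expect_equal(as.character(assign_ap_bin(2.80)), "2.80-2.35 mm")
  expect_equal(as.character(assign_ap_bin(2.35)), "2.80-2.35 mm")
  expect_equal(as.character(assign_ap_bin(2.00)), "2.34-1.99 mm")
  expect_equal(as.character(assign_ap_bin(1.98)), "1.98-1.71 mm")
  expect_equal(as.character(assign_ap_bin(1.42)), "1.70-1.42 mm")
  expect_equal(as.character(assign_ap_bin(1.41)), "<1.42 mm")
  expect_error(assign_ap_bin(NaN), "finite")
})

test_that("distribution summaries reproduce reference subregion values", {
  counts <- load_reference_counts("table1_distribution.csv")
  sub <- counts[counts$population == "nac" & counts$axis == "subregion", ]
  strata <- unique(sub$stratum)
  per_animal <- split(sub$count, sub$animal)
  cells <- cells_from_counts(strata, per_animal, axis = "subregion",
                             population = "nac")
  dt <- distribution_table(cells, "nac", "subregion")
  expect_equal(dt$pooled_total, 1042L)
  mo <- dt$summary[dt$summary$stratum == "MO", ]
  expect_equal(round(mo$mean_pct, 2), 59.99)
  expect_equal(round(mo$sd_pct, 2), 7.57)
  expect_equal(mo$pooled_count, 621L)
  # per-animal percentages sum to 100 across strata
  sums <- tapply(dt$per_animal$pct, dt$per_animal$animal, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("distribution summaries reproduce reference laminar values", {
  counts <- load_reference_counts("table1_distribution.csv")
  sub <- counts[counts$population == "vta" & counts$axis == "layer", ]
  cells <- cells_from_counts(unique(sub$stratum),
                             split(sub$count, sub$animal),
                             axis = "layer", population = "vta")
  dt <- distribution_table(cells, "vta", "layer")
  expect_equal(dt$pooled_total, 1878L)
  l5b <- dt$summary[dt$summary$stratum == "L5b", ]
  expect_equal(round(l5b$mean_pct, 2), 56.82)
  expect_equal(round(l5b$sd_pct, 2), 6.91)
  expect_equal(l5b$pooled_count, 1094L)
})

test_that("a one-stratum population is reported as 100 +/- 0", {
  cells <- cells_from_counts("MO", list(A01 = 10L, A02 = 25L),
                             axis = "subregion")
  dt <- distribution_table(cells, "nac", "subregion")
  mo <- dt$summary[dt$summary$stratum == "MO", ]
  expect_equal(mo$mean_pct, 100)
  expect_equal(mo$sd_pct, 0)
})

test_that("animals absent from a population are excluded with a warning", {
  cells <- rbind(
    cells_from_counts("MO", list(A01 = 5L), axis = "subregion",
                      population = "nac"),
    cells_from_counts("MO", list(A01 = 0L, A02 = 4L), axis = "subregion",
                      population = "vta"))
  expect_warning(dt <- distribution_table(cells, "nac", "subregion"),
                 "A02")
  expect_equal(dt$n_animals, 1L)
})

test_that("colabel proportions reproduce printed values and suppressions", {
  rep <- reproduce_printed_results()
  calb_nac <- rep$colabel$nac$calb1
  l23 <- calb_nac[calb_nac$group == "L2/3", ]
  expect_equal(round(l23$mean_pct, 2), 68.64)
  expect_equal(round(l23$sd_pct, 2), 2.62)
  expect_equal(l23$pooled_num, 197L)
  expect_equal(l23$pooled_den, 289L)
  expect_false(l23$suppressed)
  # all four printed dashes, and only those, are suppressed
  suppressed <- list(
    c("nac", "foxp2", "L6"),
    c("vta", "calb1", "L2/3"),
    c("vta", "calb1", "L5a-5b-6"),
    c("vta", "ctip2", "L2/3-5a"))
  for (pop in c("nac", "vta")) for (mk in c("calb1", "ctip2", "foxp2")) {
    tab <- rep$colabel[[pop]][[mk]]
    for (i in seq_len(nrow(tab))) {
      should <- any(vapply(suppressed, function(s)
        all(s == c(pop, mk, tab$group[i])), logical(1)))
      expect_equal(tab$suppressed[i], should,
                   label = paste(pop, mk, tab$group[i]))
      expect_equal(is.na(tab$mean_pct[i]), should)
    }
  }
  # totals row sums the layer groups
  tot <- calb_nac[calb_nac$group == "Total", ]
  expect_equal(tot$pooled_den, 944L)
  expect_equal(round(tot$mean_pct, 2), 22.78)
})

test_that("untested cells enter neither numerator nor denominator", {
  cells <- cells_from_counts("L2/3", list(A01 = 30L, A02 = 30L))
  cells$calb1 <- rep(c(1L, 0L, NA_integer_), 20)
  cp <- colabel_proportions(cells, "nac", "calb1",
                            layer_groups = list("L2/3" = "L2/3"))
  tot <- cp[cp$group == "Total", ]
  expect_equal(tot$pooled_den, 40L)
  expect_equal(tot$pooled_num, 20L)
  expect_equal(tot$mean_pct, 50)
  cells$calb1 <- NA_integer_
  expect_error(colabel_proportions(cells, "nac", "calb1"),
               "entirely untested")
})

test_that("overlap ratios reproduce the printed double-tracing values", {
  cnt <- load_reference_counts("overlap_counts.csv")
  ov <- overlap_from_counts(
    nac_single = cnt$nac_incl_double - cnt$double,
    vta_single = cnt$vta_incl_double - cnt$double,
    double = cnt$double, total = cnt$total_reported)
  s <- ov$summary
  expect_equal(round(s$mean_pct, 2), c(6.78, 1.54, 1.26))
  expect_equal(round(s$sd_pct, 2), c(5.97, 1.40, 1.12))
  # totals conserved per animal
  expect_equal(ov$per_animal$nac_single + ov$per_animal$double,
               cnt$nac_incl_double)
})

test_that("overlap edge cases: zero doubles, undefined denominators", {
  ov0 <- overlap_from_counts(c(10, 20), c(5, 8), c(0, 0))
  expect_equal(ov0$summary$mean_pct, c(0, 0, 0))
  expect_equal(ov0$summary$sd_pct, c(0, 0, 0))
  # default total is singles + doubles
  expect_equal(ov0$per_animal$total, c(15, 28))
  expect_warning(
    ov <- overlap_from_counts(c(10, 10), c(0, 10), c(2, 1)),
    "excluded")
  s <- ov$summary
  expect_equal(s$mean_pct[s$ratio == "double/vta_single"], 10)
})

test_that("overlap_statistics splits single and double labeled cells", {
  cells <- data.frame(
    animal = rep(c("A01", "A02"), each = 10),
    bregma_mm = 2, subregion = "PrL", layer = "L5a",
    tracer_nac = rep(c(1, 1, 0, 1, 1, 1, 1, 0, 0, 1), 2),
    tracer_vta = rep(c(0, 1, 1, 0, 0, 0, 0, 1, 1, 1), 2),
    calb1 = NA_integer_, ctip2 = NA_integer_, foxp2 = NA_integer_)
  ov <- overlap_statistics(cells)
  expect_equal(ov$per_animal$nac_single, c(5L, 5L))
  expect_equal(ov$per_animal$vta_single, c(3L, 3L))
  expect_equal(ov$per_animal$double, c(2L, 2L))
  expect_equal(ov$per_animal$total, c(10L, 10L))
})
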