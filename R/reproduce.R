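#' Load a packaged reference-count fixture
#'
#' The package ships the per-animal counts and densities of the reference
#' retrograde-tracing and axon-density dataset as plain CSV fixtures:
#' `"table1_distribution.csv"` (per-animal distribution counts),
#' `"colabel_counts.csv"` (marker colabeling numerators/denominators),
#' `"overlap_counts.csv"` (double retrograde tracing counts) and
#' `"axon_density.csv"` (per-animal axon lengths, volumes, densities and
#' relative densities for the four tracing groups).
#'
#' @param name fixture file name.
#' @return data.frame.
#' @export
load_reference_counts <- function(name = c("table1_distribution.csv",
                                           "colabel_counts.csv",
                                           "overlap_counts.csv",
                                           "axon_density.csv")) {
  name <- match.arg(name)
  path <- system.file("extdata", name, package = "projdense")
  if (!nzchar(path)) stop("fixture not found: ", name, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# layer-group label -> member layers, as used in the colabeling tables
.LAYER_GROUPS <- list(
  "L2/3" = "L2/3",
  "L5a-5b-6" = c("L5a", "L5b", "L6"),
  "L2/3-5a" = c("L2/3", "L5a"),
  "L5b-6" = c("L5b", "L6"),
  "L2/3-5a-5b" = c("L2/3", "L5a", "L5b"),
  "L6" = "L6")

# expand per-animal stratum counts into one cell-table row per counted
# cell, so the regular analysis functions can run on published counts
.expand_distribution_counts <- function(counts, population, axis) {
  sub <- counts[counts$population == population & counts$axis == axis, ]
  ap_rep <- c(">2.80 mm" = 3.0, "2.80-2.35 mm" = 2.5, "2.34-1.99 mm" = 2.2,
              "1.98-1.71 mm" = 1.8, "1.70-1.42 mm" = 1.5, "<1.42 mm" = 1.3)
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    n <- sub$count[i]
    if (n == 0L) return(NULL)
    data.frame(
      animal = sub$animal[i],
      bregma_mm = if (axis == "ap_bin") ap_rep[[sub$stratum[i]]] else 2.0,
      subregion = if (axis == "subregion") sub$stratum[i] else "PrL",
      layer = if (axis == "layer") sub$stratum[i] else "L5a",
      tracer_nac = as.integer(population == "nac"),
      tracer_vta = as.integer(population == "vta"),
      calb1 = NA_integer_, ctip2 = NA_integer_, foxp2 = NA_integer_)[
        rep(1L, n), ]
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

.expand_colabel_counts <- function(counts, population, marker) {
  sub <- counts[counts$population == population & counts$marker == marker, ]
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    n <- sub$n_tracer[i]
    if (n == 0L) return(NULL)
    df <- data.frame(
      animal = sub$animal[i], bregma_mm = 2.0, subregion = "PrL",
      layer = .LAYER_GROUPS[[sub$layer_group[i]]][1],
      tracer_nac = as.integer(population == "nac"),
      tracer_vta = as.integer(population == "vta"),
      calb1 = NA_integer_, ctip2 = NA_integer_,
      foxp2 = NA_integer_)[rep(1L, n), ]
    df[[marker]] <- as.integer(seq_len(n) <= sub$n_marker_pos[i])
    df
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Recompute the reference dataset's published statistics
#'
#' Runs the package's own analysis functions on the packaged per-animal
#' count and density fixtures: distribution summaries (anteroposterior,
#' subregional, laminar, for both tracer populations), marker-colabeling
#' proportions with the small-count suppression rule, double-labeling
#' overlap ratios, per-group relative-density summaries, Levene's
#' homogeneity check, one-way ANOVA and Fisher LSD pairwise comparisons.
#' Every reported number is computed at call time from the counts; nothing
#' is hard-coded downstream of the fixtures.
#'
#' @return A nested list: `distribution[[population]][[axis]]`
#'   ([distribution_table()]), `colabel[[population]][[marker]]`
#'   ([colabel_proportions()]), `overlap` ([overlap_from_counts()]),
#'   `rad` (list with `group_stats`, `levene`, `anova`, `lsd`).
#' @export
reproduce_printed_results <- function() {
  dist_counts <- load_reference_counts("table1_distribution.csv")
  colab_counts <- load_reference_counts("colabel_counts.csv")
  over_counts <- load_reference_counts("overlap_counts.csv")
  dens <- load_reference_counts("axon_density.csv")

  distribution <- lapply(stats::setNames(nm = c("nac", "vta")),
    function(pop) {
      lapply(stats::setNames(nm = c("ap_bin", "subregion", "layer")),
        function(axis) {
          cells <- .expand_distribution_counts(dist_counts, pop, axis)
          distribution_table(cells, population = pop, axis = axis)
        })
    })

  colabel <- lapply(stats::setNames(nm = c("nac", "vta")), function(pop) {
    lapply(stats::setNames(nm = c("calb1", "ctip2", "foxp2")),
      function(mk) {
        sub <- colab_counts[colab_counts$population == pop &
                            colab_counts$marker == mk, ]
        groups <- .LAYER_GROUPS[unique(sub$layer_group)]
        cells <- .expand_colabel_counts(colab_counts, pop, mk)
        colabel_proportions(cells, population = pop, marker = mk,
                            layer_groups = groups)
      })
  })

  overlap <- overlap_from_counts(
    nac_single = over_counts$nac_incl_double - over_counts$double,
    vta_single = over_counts$vta_incl_double - over_counts$double,
    double = over_counts$double,
    total = over_counts$total_reported,
    animal = over_counts$animal)

  glev <- factor(dens$group, levels = unique(dens$group))
  groups <- split(dens$relative_density, glev)
  group_stats <- t(vapply(groups, mean_sd, numeric(2)))
  # the same ratios recomputed from the per-animal densities (the printed
  # ratio column is rounded to 2 significant figures; recomputing through
  # rad_ratio retains full precision)
  ratio <- mapply(rad_ratio, dens$density_vta_mm_per_mm3,
                  dens$density_nac_mm_per_mm3)
  ratio_stats <- t(vapply(split(ratio, glev), mean_sd, numeric(2)))
  av <- one_way_anova(groups)
  rad <- list(group_stats = group_stats,
              ratio_stats_from_densities = ratio_stats,
              levene = homogeneity_test(groups),
              anova = av,
              lsd = lsd_posthoc(groups, anova = av))

  list(distribution = distribution, colabel = colabel, overlap = overlap,
       rad = rad)
}
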