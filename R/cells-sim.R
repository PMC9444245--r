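#' Default expected cell counts for the cell-table simulator
#'
#' Per-animal expected counts of tracer-labeled cells per
#' `(population, subregion, layer)` cell, built as the product of the
#' subregional and laminar marginal proportions observed in mouse
#' retrograde-tracing studies of the mPFC-to-NAc and mPFC-to-VTA pathways
#' (NAc-projecting cells concentrated in MO/PrL and layers 2/3-5a;
#' VTA-projecting cells in PrL/MO/DP/DTT and layers 5b-6), scaled to
#' roughly 350 (NAc) and 630 (VTA) cells per animal.
#'
#' @return data.frame with columns `population`, `subregion`, `layer`,
#'   `mean_count`.
#' @export
default_expected_counts <- function() {
  sub_p <- list(
    nac = c(Cg1 = 32, Cg2 = 0, PrL = 297, IL = 59, MO = 621, DP = 18,
            DTT = 15) / 1042,
    vta = c(Cg1 = 168, Cg2 = 64, PrL = 505, IL = 175, MO = 398, DP = 309,
            DTT = 259) / 1878)
  lay_p <- list(
    nac = c("L1" = 6, "L2/3" = 324, "L5a" = 571, "L5b" = 109,
            "L6" = 32) / 1042,
    vta = c("L1" = 1, "L2/3" = 48, "L5a" = 22, "L5b" = 1094,
            "L6" = 713) / 1878)
  totals <- c(nac = 347, vta = 626)
  out <- do.call(rbind, lapply(c("nac", "vta"), function(pop) {
    g <- expand.grid(subregion = names(sub_p[[pop]]),
                     layer = names(lay_p[[pop]]),
                     stringsAsFactors = FALSE)
    g$population <- pop
    g$mean_count <- totals[[pop]] * sub_p[[pop]][g$subregion] *
      lay_p[[pop]][g$layer]
    g[, c("population", "subregion", "layer", "mean_count")]
  }))
  rownames(out) <- NULL
  out
}

#' Default marker colabeling probabilities for the cell-table simulator
#'
#' Probability that a tracer-labeled cell of a given population and layer
#' expresses each molecular marker (Calb1, Ctip2, FoxP2). Values mirror
#' the layer-dependent expression pattern of these markers in prefrontal
#' projection neurons: Calb1 high in L2/3 of NAc-projecting cells, Ctip2
#' high in deep layers (near-universal in VTA-projecting cells), FoxP2
#' largely confined to L6.
#'
#' @return data.frame with columns `population`, `marker`, `layer`, `prob`.
#' @export
default_colabel_prob <- function() {
  probs <- list(
    nac = list(
      calb1 = c("L1" = 0.05, "L2/3" = 0.69, "L5a" = 0.03, "L5b" = 0.03,
                "L6" = 0.03),
      ctip2 = c("L1" = 0.05, "L2/3" = 0.08, "L5a" = 0.08, "L5b" = 0.64,
                "L6" = 0.64),
      foxp2 = c("L1" = 0.01, "L2/3" = 0.015, "L5a" = 0.015, "L5b" = 0.015,
                "L6" = 0.15)),
    vta = list(
      calb1 = c("L1" = 0.05, "L2/3" = 0.7, "L5a" = 0.01, "L5b" = 0.005,
                "L6" = 0.005),
      ctip2 = c("L1" = 0.1, "L2/3" = 0.25, "L5a" = 0.25, "L5b" = 0.96,
                "L6" = 0.96),
      foxp2 = c("L1" = 0.05, "L2/3" = 0.09, "L5a" = 0.09, "L5b" = 0.09,
                "L6" = 0.79)))
  out <- do.call(rbind, lapply(names(probs), function(pop) {
    do.call(rbind, lapply(names(probs[[pop]]), function(mk) {
      data.frame(population = pop, marker = mk,
                 layer = names(probs[[pop]][[mk]]),
                 prob = unname(probs[[pop]][[mk]]))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Specification for a synthetic cell-count table
#'
#' Describes the generative model for tables of retrogradely labeled cells:
#' per-animal counts are Poisson around the expected count for each
#' `(population, subregion, layer)` stratum, anteroposterior positions are
#' uniform over the sampled Bregma range, marker status is Bernoulli with a
#' layer- and population-specific colabeling probability (markers are
#' assessed only on a `marker_tested_prob` fraction of cells, emulating
#' per-marker section subsets; untested cells carry `NA`), and each cell
#' carries both retrograde tracers with probability
#' `double_projection_prob`.
#'
#' @param n_animals number of simulated animals.
#' @param expected_counts data.frame `population, subregion, layer,
#'   mean_count` (per-animal expectations); default
#'   [default_expected_counts()].
#' @param colabel_prob data.frame `population, marker, layer, prob`;
#'   default [default_colabel_prob()]. May be a single number to use one
#'   probability everywhere.
#' @param marker_tested_prob probability that a given marker was assessed
#'   on a given cell.
#' @param double_projection_prob probability that a labeled cell projects
#'   to both targets.
#' @param bregma_range_mm sampled anteroposterior range, mm anterior to
#'   Bregma.
#' @param seed integer; fully determines the output.
#' @return An object of class `cell_table_spec`.
#' @seealso [generate_cell_table()]
#' @export
cell_table_spec <- function(n_animals = 3,
                            expected_counts = default_expected_counts(),
                            colabel_prob = default_colabel_prob(),
                            marker_tested_prob = 0.5,
                            double_projection_prob = 0.0126,
                            bregma_range_mm = c(1.10, 3.10),
                            seed = 1L) {
  if (n_animals < 1 || n_animals != round(n_animals))
    stop("'n_animals' must be a positive integer", call. = FALSE)
  req <- c("population", "subregion", "layer", "mean_count")
  if (!is.data.frame(expected_counts) ||
      !all(req %in% names(expected_counts)))
    stop("'expected_counts' needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(expected_counts$subregion), .SUBREGIONS)
  if (length(bad))
    stop("unknown subregion label(s) in spec: ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(expected_counts$layer), .LAYERS)
  if (length(bad))
    stop("unknown layer label(s) in spec: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(expected_counts$mean_count < 0))
    stop("expected counts must be >= 0", call. = FALSE)
  if (is.numeric(colabel_prob) && length(colabel_prob) == 1L) {
    p <- colabel_prob
    colabel_prob <- expand.grid(population = c("nac", "vta"),
                                marker = c("calb1", "ctip2", "foxp2"),
                                layer = .LAYERS, stringsAsFactors = FALSE)
    colabel_prob$prob <- p
  }
  if (any(colabel_prob$prob < 0 | colabel_prob$prob > 1))
    stop("colabeling probabilities must be in [0, 1]", call. = FALSE)
  bad <- setdiff(unique(colabel_prob$layer), .LAYERS)
  if (length(bad))
    stop("unknown layer label(s) in colabel_prob: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (marker_tested_prob < 0 || marker_tested_prob > 1 ||
      double_projection_prob < 0 || double_projection_prob > 1)
    stop("probabilities must be in [0, 1]", call. = FALSE)
  if (length(bregma_range_mm) != 2L || diff(bregma_range_mm) < 0)
    stop("'bregma_range_mm' must be an increasing (lo, hi) pair",
         call. = FALSE)
  structure(list(n_animals = as.integer(n_animals),
                 expected_counts = expected_counts,
                 colabel_prob = colabel_prob,
                 marker_tested_prob = marker_tested_prob,
                 double_projection_prob = double_projection_prob,
                 bregma_range_mm = as.numeric(bregma_range_mm),
                 seed = as.integer(seed)),
            class = "cell_table_spec")
}

#' Generate a synthetic cell-count table
#'
#' Simulates one row per labeled neuron under the generative model in
#' [cell_table_spec()]. Columns follow the interchange format consumed by
#' [read_cell_table()]: `animal, bregma_mm, subregion, layer, tracer_nac,
#' tracer_vta, calb1, ctip2, foxp2`, with marker columns in {1, 0, NA}.
#'
#' @param spec a [cell_table_spec()].
#' @return data.frame, one row per simulated cell.
#' @examples
#' cells <- generate_cell_table(cell_table_spec(n_animals = 2, seed = 3))
#' table(cells$animal, cells$tracer_nac)
#' @export
generate_cell_table <- function(spec) {
  stopifnot(inherits(spec, "cell_table_spec"))
  markers <- c("calb1", "ctip2", "foxp2")
  with_seed(spec$seed, function() {
    per_animal <- lapply(seq_len(spec$n_animals), function(a) {
      rows <- lapply(seq_len(nrow(spec$expected_counts)), function(i) {
        e <- spec$expected_counts[i, ]
        n <- rpois(1, e$mean_count)
        if (n == 0L) return(NULL)
        df <- data.frame(
          animal = sprintf("A%02d", a),
          bregma_mm = runif(n, spec$bregma_range_mm[1],
                            spec$bregma_range_mm[2]),
          subregion = e$subregion,
          layer = e$layer,
          tracer_nac = as.integer(e$population == "nac"),
          tracer_vta = as.integer(e$population == "vta"))
        dbl <- rbinom(n, 1, spec$double_projection_prob) == 1L
        df$tracer_nac[dbl] <- 1L
        df$tracer_vta[dbl] <- 1L
        for (mk in markers) {
          p <- spec$colabel_prob$prob[
            spec$colabel_prob$population == e$population &
            spec$colabel_prob$marker == mk &
            spec$colabel_prob$layer == e$layer]
          p <- if (length(p)) p[1] else 0
          status <- ifelse(rbinom(n, 1, spec$marker_tested_prob) == 1L,
                           rbinom(n, 1, p), NA_integer_)
          df[[mk]] <- as.integer(status)
        }
        df
      })
      do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    })
    out <- do.call(rbind, per_animal)
    if (is.null(out))
      out <- data.frame(animal = character(), bregma_mm = numeric(),
                        subregion = character(), layer = character(),
                        tracer_nac = integer(), tracer_vta = integer(),
                        calb1 = integer(), ctip2 = integer(),
                        foxp2 = integer())
    rownames(out) <- NULL
    out
  })
}
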