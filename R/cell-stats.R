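#' Anteroposterior bin of a Bregma level
#'
#' Maps an anteroposterior coordinate (mm anterior to Bregma) to the six
#' standard reporting bins. Bins are printed to 2 decimals with both
#' endpoints inclusive; the value is rounded to 2 decimals first, so
#' coordinates falling between adjacent printed endpoints are assigned to
#' the bin whose printed range contains the rounded value.
#'
#' @param bregma_mm numeric vector of AP coordinates, mm.
#' @return factor with levels `">2.80 mm"`, `"2.80-2.35 mm"`,
#'   `"2.34-1.99 mm"`, `"1.98-1.71 mm"`, `"1.70-1.42 mm"`, `"<1.42 mm"`.
#' @examples
#' assign_ap_bin(c(3.05, 2.00, 1.98))
#' @export
assign_ap_bin <- function(bregma_mm) {
  if (!all(is.finite(bregma_mm)))
    stop("'bregma_mm' must be finite", call. = FALSE)
  b <- round(bregma_mm, 2)
  lev <- c(">2.80 mm", "2.80-2.35 mm", "2.34-1.99 mm", "1.98-1.71 mm",
           "1.70-1.42 mm", "<1.42 mm")
  lab <- ifelse(b > 2.80, lev[1],
         ifelse(b >= 2.35, lev[2],
         ifelse(b >= 1.99, lev[3],
         ifelse(b >= 1.71, lev[4],
         ifelse(b >= 1.42, lev[5], lev[6])))))
  factor(lab, levels = lev)
}

# subset a cell table to one tracer population
.population_cells <- function(cells, population = c("nac", "vta")) {
  population <- match.arg(population)
  flag <- if (population == "nac") cells$tracer_nac else cells$tracer_vta
  cells[flag == 1L, , drop = FALSE]
}

# stratum factor for a distribution axis
.axis_factor <- function(cells, axis) {
  switch(axis,
         ap_bin = assign_ap_bin(cells$bregma_mm),
         subregion = factor(cells$subregion, levels = .SUBREGIONS),
         layer = factor(cells$layer, levels = .LAYERS),
         stop("unknown axis: ", axis, call. = FALSE))
}

#' Distribution of a tracer population along an anatomical axis
#'
#' Per-animal stratum counts and percentages (of that animal's population
#' total), pooled counts, and across-animal mean +/- SD percentages, for
#' one of three axes: anteroposterior bin, mPFC subregion, or cortical
#' layer. Animals with zero cells in the population are excluded with a
#' warning. Per-animal percentages sum to 100 across strata.
#'
#' @param cells cell table (see [read_cell_table()]).
#' @param population `"nac"` or `"vta"`.
#' @param axis `"ap_bin"`, `"subregion"` or `"layer"`.
#' @return list of class `distribution_table` with
#'   `per_animal` (long data.frame `animal, stratum, count, pct`) and
#'   `summary` (data.frame `stratum, pooled_count, mean_pct, sd_pct`).
#' @export
distribution_table <- function(cells, population = c("nac", "vta"),
                               axis = c("ap_bin", "subregion", "layer")) {
  population <- match.arg(population)
  axis <- match.arg(axis)
  sub <- .population_cells(cells, population)
  animals <- sort(unique(as.character(cells$animal)))
  if (length(animals) == 0L) stop("need at least one animal", call. = FALSE)
  present <- animals %in% sub$animal
  if (any(!present)) {
    warning("excluding animal(s) with zero cells in population '",
            population, "': ", paste(animals[!present], collapse = ", "))
    animals <- animals[present]
  }
  strat <- .axis_factor(sub, axis)
  counts <- table(factor(as.character(sub$animal), levels = animals), strat)
  totals <- rowSums(counts)
  pct <- sweep(counts, 1, totals, "/") * 100
  per_animal <- data.frame(
    animal = rep(animals, times = ncol(counts)),
    stratum = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts),
    pct = as.vector(pct))
  summary <- data.frame(
    stratum = colnames(counts),
    pooled_count = as.vector(colSums(counts)),
    mean_pct = as.vector(colMeans(pct)),
    sd_pct = if (nrow(pct) >= 2) as.vector(apply(pct, 2, sd))
             else rep(NA_real_, ncol(pct)))
  structure(list(per_animal = per_animal, summary = summary,
                 population = population, axis = axis,
                 n_animals = length(animals),
                 pooled_total = sum(totals)),
            class = "distribution_table")
}

#' @export
print.distribution_table <- function(x, ...) {
  cat(sprintf("<distribution_table> population=%s axis=%s (%d animals, %d cells)\n",
              x$population, x$axis, x$n_animals, x$pooled_total))
  print(transform(x$summary, mean_pct = round(mean_pct, 2),
                  sd_pct = round(sd_pct, 2)), row.names = FALSE)
  invisible(x)
}

#' Marker colabeling proportions with small-count suppression
#'
#' For each layer group (and for the total over all groups): per animal,
#' the percentage of tracer-labeled cells that are positive for the marker
#' among cells on which the marker was assessed, summarized as mean +/- SD
#' across animals together with pooled numerator/denominator. Cells with
#' the marker untested (`NA`) enter neither numerator nor denominator.
#'
#' A summary row is suppressed (percentages reported as `NA` with
#' `suppressed = TRUE`) when the pooled marker-positive count is below 10
#' or any contributing per-animal denominator is below 10 — the convention
#' of not reporting percentages from very small counts.
#'
#' @param cells cell table.
#' @param population `"nac"` or `"vta"`.
#' @param marker `"calb1"`, `"ctip2"` or `"foxp2"`.
#' @param layer_groups named list of character vectors partitioning the
#'   layers, e.g. `list("L2/3" = "L2/3", "L5a-5b-6" = c("L5a","L5b","L6"))`.
#'   A `"Total"` group over all listed layers is appended automatically.
#' @param suppress_below pooled-count threshold for suppression.
#' @return data.frame of class `proportion_summary`, one row per group:
#'   `group, pooled_num, pooled_den, mean_pct, sd_pct, suppressed`, with
#'   the per-animal numerators/denominators in the `"per_animal"`
#'   attribute.
#' @export
colabel_proportions <- function(cells, population = c("nac", "vta"),
                                marker = c("calb1", "ctip2", "foxp2"),
                                layer_groups = list(
                                  "L2/3" = "L2/3",
                                  "L5a-5b-6" = c("L5a", "L5b", "L6")),
                                suppress_below = 10L) {
  population <- match.arg(population)
  marker <- match.arg(marker)
  sub <- .population_cells(cells, population)
  status <- sub[[marker]]
  if (all(is.na(status)))
    stop("marker '", marker, "' entirely untested in population '",
         population, "'", call. = FALSE)
  tested <- sub[!is.na(status), , drop = FALSE]
  animals <- sort(unique(as.character(tested$animal)))
  groups <- c(layer_groups,
              list(Total = unique(unlist(layer_groups, use.names = FALSE))))
  per_animal <- list()
  rows <- lapply(names(groups), function(gn) {
    in_g <- tested[tested$layer %in% groups[[gn]], , drop = FALSE]
    den <- vapply(animals, function(a)
      sum(in_g$animal == a), integer(1))
    num <- vapply(animals, function(a)
      sum(in_g$animal == a & in_g[[marker]] == 1L), integer(1))
    pct <- ifelse(den > 0, 100 * num / den, NA_real_)
    suppressed <- sum(num) < suppress_below || any(den < suppress_below)
    per_animal[[gn]] <<- data.frame(group = gn, animal = animals,
                                    numerator = num, denominator = den,
                                    pct = if (suppressed) NA_real_ else pct)
    data.frame(group = gn,
               pooled_num = sum(num), pooled_den = sum(den),
               mean_pct = if (suppressed) NA_real_ else mean(pct),
               sd_pct = if (suppressed || length(pct) < 2) NA_real_
                        else sd(pct),
               suppressed = suppressed)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_animal") <- do.call(rbind, per_animal)
  class(out) <- c("proportion_summary", class(out))
  out
}

#' Double retrograde labeling overlap statistics
#'
#' Per animal, splits labeled cells into single NAc-projecting, single
#' VTA-projecting, and double-labeled (both tracers), then summarizes the
#' three overlap ratios as mean +/- SD across animals:
#' `double / vta_single`, `double / nac_single`, and `double / total`
#' (total = single NAc + single VTA + double), each as a percentage.
#' Animals where a ratio's denominator is zero while the double count is
#' nonzero are excluded from that ratio with a warning; zero doubles over
#' a zero denominator counts as 0.
#'
#' @param cells cell table containing both tracer flags.
#' @return list of class `overlap_summary` with `per_animal` (data.frame
#'   `animal, nac_single, vta_single, double, total, pct_of_nac,
#'   pct_of_vta, pct_of_total`) and `summary` (data.frame `ratio,
#'   mean_pct, sd_pct`).
#' @export
overlap_statistics <- function(cells) {
  if (!any(cells$tracer_nac == 1L) || !any(cells$tracer_vta == 1L))
    stop("table must contain both tracer populations", call. = FALSE)
  animals <- sort(unique(as.character(cells$animal)))
  nac_s <- vapply(animals, function(a) sum(
    cells$animal == a & cells$tracer_nac == 1L & cells$tracer_vta == 0L),
    integer(1))
  vta_s <- vapply(animals, function(a) sum(
    cells$animal == a & cells$tracer_vta == 1L & cells$tracer_nac == 0L),
    integer(1))
  dbl <- vapply(animals, function(a) sum(
    cells$animal == a & cells$tracer_nac == 1L & cells$tracer_vta == 1L),
    integer(1))
  overlap_from_counts(nac_single = nac_s, vta_single = vta_s,
                      double = dbl, animal = animals)
}

#' Overlap statistics from per-animal counts
#'
#' The counts-level backend of [overlap_statistics()], for use when only
#' tabulated per-animal counts are available (e.g. published tables).
#' `total` defaults to `nac_single + vta_single + double` (each labeled
#' cell counted once) but may be supplied explicitly when a table reports
#' its own totals.
#'
#' @param nac_single,vta_single,double per-animal counts (equal lengths).
#' @param total optional explicit per-animal totals.
#' @param animal optional animal ids.
#' @return see [overlap_statistics()].
#' @export
overlap_from_counts <- function(nac_single, vta_single, double,
                                total = NULL, animal = NULL) {
  n <- length(double)
  stopifnot(length(nac_single) == n, length(vta_single) == n)
  if (is.null(animal)) animal <- sprintf("A%02d", seq_len(n))
  if (is.null(total)) total <- nac_single + vta_single + double
  ratio_pct <- function(num, den, label) {
    ok <- den > 0 | num == 0
    if (any(!ok))
      warning("animal(s) with zero '", label,
              "' denominator and nonzero doubles excluded: ",
              paste(animal[!ok], collapse = ", "))
    ifelse(den > 0, 100 * num / den, ifelse(num == 0, 0, NA_real_))
  }
  p_nac <- ratio_pct(double, nac_single, "nac_single")
  p_vta <- ratio_pct(double, vta_single, "vta_single")
  p_tot <- ratio_pct(double, total, "total")
  per_animal <- data.frame(animal = animal, nac_single = nac_single,
                           vta_single = vta_single, double = double,
                           total = total, pct_of_nac = p_nac,
                           pct_of_vta = p_vta, pct_of_total = p_tot)
  msd <- function(p) {
    p <- p[!is.na(p)]
    c(mean = mean(p), sd = if (length(p) >= 2) sd(p) else NA_real_)
  }
  sm <- rbind(msd(p_vta), msd(p_nac), msd(p_tot))
  summary <- data.frame(ratio = c("double/vta_single", "double/nac_single",
                                  "double/total"),
                        mean_pct = sm[, "mean"], sd_pct = sm[, "sd"])
  structure(list(per_animal = per_animal, summary = summary),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary>\n")
  print(transform(x$summary, mean_pct = round(mean_pct, 2),
                  sd_pct = round(sd_pct, 2)), row.names = FALSE)
  invisible(x)
}
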