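#' Write an image stack to multi-page TIFF with a metadata sidecar
#'
#' One TIFF page per z-slice. Because baseline TIFF tags cannot carry the
#' axial step, the voxel spacing (and the intensity scale used for 16-bit
#' encoding) is recorded in a YAML sidecar at `paste0(path, ".yml")`;
#' [read_stack()] restores both. Integer stacks within the 16-bit range
#' round-trip exactly; other stacks are stored as 32-bit float after
#' normalization by the recorded `intensity_scale`.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  integral <- max(abs(v - round(v))) == 0 && max(v) <= 65535
  if (integral) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- max(v, 1)
    bits <- 32L
  }
  pages <- lapply(seq_len(dim(v)[1]), function(z)
    matrix(v[z, , ] / scale, nrow = dim(v)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  yaml::write_yaml(list(spacing_um = as.numeric(stack$spacing_um),
                        intensity_scale = scale,
                        sample_mode = if (integral) "uint16" else "float32",
                        axis_order = "zyx"),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' Pages become z-slices in `(z, y, x)` order. Spacing resolution order:
#' explicit `spacing_um` argument, then the YAML sidecar written by
#' [write_stack()], then TIFF X/Y resolution tags (which cannot supply the
#' z step). If no source provides a full `(dz, dy, dx)` spacing the read
#' fails rather than silently assuming isotropy.
#'
#' @param path TIFF path.
#' @param spacing_um optional explicit `(dz, dy, dx)` spacing override, um.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, spacing_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("empty TIFF: ", path, call. = FALSE)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("expected single-channel grayscale pages", call. = FALSE)

  sidecar_path <- paste0(path, ".yml")
  sidecar <- if (file.exists(sidecar_path)) yaml::read_yaml(sidecar_path)

  if (is.null(spacing_um)) {
    if (!is.null(sidecar$spacing_um)) {
      spacing_um <- as.numeric(sidecar$spacing_um)
    } else {
      info <- attributes(pages[[1]])
      if (!is.null(info$x.resolution) && !is.null(info$y.resolution) &&
          identical(info$resolution.unit, "cm")) {
        # pixels per cm -> um per pixel; TIFF has no z resolution tag
        stop("TIFF carries only in-plane resolution; supply the full ",
             "(dz, dy, dx) via 'spacing_um' or a sidecar", call. = FALSE)
      }
      stop("voxel spacing unavailable: no 'spacing_um' override, no ",
           "sidecar ", basename(sidecar_path), ", no usable TIFF tags ",
           "(refusing to assume isotropic voxels)", call. = FALSE)
    }
  }

  # readTIFF scales integer samples into [0, 1]; the sidecar records the
  # factor (and sample mode) needed to restore the original intensities
  scale <- if (!is.null(sidecar$intensity_scale)) sidecar$intensity_scale
           else 1
  d <- c(length(pages), dim(pages[[1]]))
  v <- array(0, dim = d)
  for (z in seq_along(pages)) v[z, , ] <- pages[[z]] * scale
  if (identical(sidecar$sample_mode, "uint16")) v <- round(v)
  image_stack(pmax(v, 0), spacing_um)
}

#' Region-of-interest volume specification
#'
#' The analyzed tissue volume of a confocal acquisition expressed as
#' ROI area x number of optical slices x axial step.
#'
#' @param roi_area_mm2 in-plane ROI area, mm^2.
#' @param n_slices number of z-slices.
#' @param step_um axial step, um.
#' @return An object of class `roi_spec`.
#' @seealso [stack_volume()]
#' @export
roi_spec <- function(roi_area_mm2, n_slices, step_um) {
  .stopifnot_scalar_pos(roi_area_mm2, "roi_area_mm2")
  .stopifnot_scalar_pos(n_slices, "n_slices")
  .stopifnot_scalar_pos(step_um, "step_um")
  structure(list(roi_area_mm2 = roi_area_mm2,
                 n_slices = as.integer(n_slices),
                 step_um = step_um),
            class = "roi_spec")
}

#' Read an ROI specification from a YAML/JSON-style key-value file
#'
#' Expects keys `roi_area_mm2`, `n_slices`, `step_um`.
#'
#' @param path YAML file path.
#' @return An [roi_spec()].
#' @export
read_roi_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  missing <- setdiff(c("roi_area_mm2", "n_slices", "step_um"), names(cfg))
  if (length(missing))
    stop("ROI config is missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  roi_spec(cfg$roi_area_mm2, cfg$n_slices, cfg$step_um)
}

.CELL_COLUMNS <- c("animal", "bregma_mm", "subregion", "layer",
                   "tracer_nac", "tracer_vta", "calb1", "ctip2", "foxp2")

#' Read and validate a cell-count table
#'
#' Comma-separated UTF-8 text with header `animal, bregma_mm, subregion,
#' layer, tracer_nac, tracer_vta, calb1, ctip2, foxp2`. Subregions are
#' restricted to Cg1, Cg2, PrL, IL, MO, DP, DTT, other; layers to L1,
#' L2/3, L5a, L5b, L6. Marker columns are tri-state: 1 (positive),
#' 0 (negative), NA (not assessed for that marker). Each row is one
#' counted neuron; identical rows may repeat (cells are not unique by
#' their attributes). Every cell must carry at least one tracer flag.
#'
#' The table is the product of manual counting on serial sections; the
#' input contract assumes each counted cell was confirmed with a visible
#' nucleus across sections, which this reader cannot re-verify.
#'
#' @param path CSV path.
#' @return data.frame with typed columns.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.CELL_COLUMNS, names(df))
  if (length(missing))
    stop("cell table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[, .CELL_COLUMNS]
  validate_cell_table(df)
}

#' Validate an in-memory cell table
#'
#' Applies the same category and flag checks as [read_cell_table()];
#' errors name the first offending row and value.
#'
#' @param df data.frame in the cell-table layout.
#' @return the validated data.frame, invisibly classed as before.
#' @export
validate_cell_table <- function(df) {
  fail_row <- function(col, ok) {
    bad <- which(!ok)
    if (length(bad))
      stop(sprintf("cell table row %d: invalid %s '%s'", bad[1], col,
                   as.character(df[[col]][bad[1]])), call. = FALSE)
  }
  if (nrow(df) == 0L) return(df)
  fail_row("subregion", df$subregion %in% .SUBREGIONS)
  fail_row("layer", df$layer %in% .LAYERS)
  if (!is.numeric(df$bregma_mm) || !all(is.finite(df$bregma_mm)))
    stop("'bregma_mm' must be finite numeric", call. = FALSE)
  for (col in c("tracer_nac", "tracer_vta")) {
    df[[col]] <- as.integer(df[[col]])
    fail_row(col, df[[col]] %in% c(0L, 1L))
  }
  fail_row("animal", !is.na(df$animal) & nzchar(as.character(df$animal)))
  no_tracer <- df$tracer_nac == 0L & df$tracer_vta == 0L
  if (any(no_tracer))
    stop(sprintf("cell table row %d: cell carries no tracer flag",
                 which(no_tracer)[1]), call. = FALSE)
  for (col in c("calb1", "ctip2", "foxp2")) {
    df[[col]] <- as.integer(df[[col]])
    fail_row(col, is.na(df[[col]]) | df[[col]] %in% c(0L, 1L))
  }
  df
}

#' Write a cell table as CSV
#'
#' @param df cell table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(df, path) {
  write.csv(df[, .CELL_COLUMNS], path, row.names = FALSE, na = "NA")
  invisible(path)
}
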