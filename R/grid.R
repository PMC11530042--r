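#' Describe one layer of a layered 1-D domain
#'
#' @param name label (e.g. "cortical", "cancellous", "tissue").
#' @param length layer thickness, mm (> 0).
#' @param D diffusivity inside the layer, mm^2/h (> 0).
#' @param porosity optional porosity recorded as metadata (not used by the
#'   solver itself; the porosity's effect enters through `D`).
#' @return object of class `layer_spec`.
#' @export
layer_spec <- function(name, length, D, porosity = NA_real_) {
  .check_scalar(length, "length", lower = 0, strict = TRUE)
  .check_scalar(D, "D", lower = 0, strict = TRUE)
  structure(list(name = as.character(name), length = length, D = D,
                 porosity = porosity),
            class = "layer_spec")
}

#' Build a cell-centered 1-D layered grid
#'
#' Cells are uniform of size `dx`; index 1 (position `dx/2`) sits at the
#' release surface. Each layer length must hold an integer number of cells.
#' Per-cell diffusivities come from the owning layer; the solver combines
#' adjacent cells with a harmonic mean on faces so flux is continuous across
#' layer interfaces.
#'
#' @param layers list of [layer_spec()] objects, ordered from the release
#'   surface outward (a single `layer_spec` is accepted).
#' @param dx cell size, mm.
#' @param cross_section_area cross-sectional area A, mm^2.
#' @return object of class `grid1d` with fields `dx`, `n`, `cell_D`,
#'   `cell_layer`, `positions` (cell centers, mm), `A`,
#'   `cell_volume_mL`, `layers`.
#' @export
grid_1d <- function(layers, dx, cross_section_area = 1) {
  if (inherits(layers, "layer_spec")) layers <- list(layers)
  stopifnot(length(layers) >= 1)
  .check_scalar(dx, "dx", lower = 0, strict = TRUE)
  .check_scalar(cross_section_area, "cross_section_area", lower = 0, strict = TRUE)
  cell_D <- numeric(0)
  cell_layer <- character(0)
  for (ly in layers) {
    if (!inherits(ly, "layer_spec")) stop("layers must be layer_spec objects")
    ncells <- ly$length / dx
    if (abs(ncells - round(ncells)) > 1e-8) {
      stop("layer '", ly$name, "' length ", ly$length,
           " mm is not an integer number of cells of dx = ", dx, " mm",
           call. = FALSE)
    }
    ncells <- round(ncells)
    cell_D <- c(cell_D, rep(ly$D, ncells))
    cell_layer <- c(cell_layer, rep(ly$name, ncells))
  }
  n <- length(cell_D)
  structure(list(
    dx = dx, n = n, cell_D = cell_D, cell_layer = cell_layer,
    positions = (seq_len(n) - 0.5) * dx,
    A = cross_section_area,
    cell_volume_mL = cross_section_area * dx * ML_PER_MM3,
    layers = layers
  ), class = "grid1d")
}

#' @export
print.grid1d <- function(x, ...) {
  cat("1-D grid:", x$n, "cells of", x$dx, "mm (total",
      format(x$n * x$dx), "mm), A =", x$A, "mm^2\n")
  for (ly in x$layers) {
    cat("  layer", ly$name, ":", ly$length, "mm, D =", format(ly$D), "mm^2/h\n")
  }
  invisible(x)
}

#' Build a uniform 2-D rectangular grid with a releasing source mask
#'
#' Used for the agar inhibition-zone scenario: a thin layer of medium
#' (thickness `thickness` mm) discretized in the plane, with a centered
#' square of source cells representing the coated substrate footprint.
#'
#' @param nx,ny number of cells in x and y.
#' @param dx cell size, mm (same in both directions).
#' @param D diffusivity in the medium, mm^2/h.
#' @param thickness medium depth, mm; released mass is diluted into
#'   `dx^2 * thickness` per source cell.
#' @param source_mask logical `nx` by `ny` matrix marking releasing cells,
#'   or `NULL` for none; see [centered_square_mask()].
#' @return object of class `grid2d`.
#' @export
grid_2d <- function(nx, ny, dx, D, thickness = 4, source_mask = NULL) {
  .check_scalar(dx, "dx", lower = 0, strict = TRUE)
  .check_scalar(D, "D", lower = 0, strict = TRUE)
  .check_scalar(thickness, "thickness", lower = 0, strict = TRUE)
  if (is.null(source_mask)) {
    source_mask <- matrix(FALSE, nx, ny)
  }
  stopifnot(is.logical(source_mask), nrow(source_mask) == nx,
            ncol(source_mask) == ny)
  structure(list(nx = nx, ny = ny, dx = dx, D = D, thickness = thickness,
                 source_mask = source_mask,
                 cell_volume_mL = dx^2 * thickness * ML_PER_MM3),
            class = "grid2d")
}

#' Centered square source mask
#'
#' @param nx,ny grid dimensions.
#' @param side_cells side of the square in cells.
#' @return logical matrix with a centered `side_cells` x `side_cells` block
#'   of `TRUE`.
#' @export
centered_square_mask <- function(nx, ny, side_cells) {
  if (side_cells > nx || side_cells > ny) stop("square larger than domain")
  m <- matrix(FALSE, nx, ny)
  i0 <- floor((nx - side_cells) / 2)
  j0 <- floor((ny - side_cells) / 2)
  m[i0 + seq_len(side_cells), j0 + seq_len(side_cells)] <- TRUE
  m
}
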