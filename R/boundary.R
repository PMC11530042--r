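#' Boundary conditions for the 1-D solver
#'
#' Four kinds are available:
#' \describe{
#'   \item{`bc_flux_in(flux_fn)`}{prescribed mass influx through the boundary
#'     face; `flux_fn(t)` returns J_in in ug mm^-2 h^-1 (must be >= 0).}
#'   \item{`bc_no_flux()` / `bc_symmetric()`}{zero-gradient wall (synonymous
#'     in 1-D): the one-sided stencil is used at the boundary cell.}
#'   \item{`bc_sink()`}{perfect sink: the boundary cell is pinned to
#'     concentration 0 after each stencil update.}
#'   \item{`bc_dirichlet(value)`}{generalized pin at an arbitrary held
#'     concentration (ug/mL); `bc_sink()` is `bc_dirichlet(0)`.}
#' }
#' Mass added or removed by a pin is tracked in the simulation ledger.
#'
#' @param flux_fn function of time (h) returning a non-negative flux
#'   (ug mm^-2 h^-1).
#' @param value held concentration, ug/mL.
#' @return object of class `boundary_condition`.
#' @name boundary_condition
NULL

#' @rdname boundary_condition
#' @export
bc_flux_in <- function(flux_fn) {
  stopifnot(is.function(flux_fn))
  structure(list(kind = "flux_in", flux_fn = flux_fn),
            class = "boundary_condition")
}

#' @rdname boundary_condition
#' @export
bc_no_flux <- function() {
  structure(list(kind = "no_flux"), class = "boundary_condition")
}

#' @rdname boundary_condition
#' @export
bc_symmetric <- bc_no_flux

#' @rdname boundary_condition
#' @export
bc_sink <- function() bc_dirichlet(0)

#' @rdname boundary_condition
#' @export
bc_dirichlet <- function(value) {
  .check_scalar(value, "value", lower = 0)
  structure(list(kind = "dirichlet", value = value),
            class = "boundary_condition")
}

#' First-order clearance specification
#'
#' Clearance removes drug from every cell at a rate set by the elimination
#' half-life t1/2. Two discretizations are provided:
#' \describe{
#'   \item{`"increment"` (default)}{per-step additive increment
#'     `dt * ln(0.5)/t_half * C * 0.5^(dt/t_half)`, the form used by the
#'     per-element mass-balance update.}
#'   \item{`"exact"`}{multiplicative `C * 0.5^(dt/t_half)` applied after the
#'     diffusion update; exact for pure decay at any dt.}
#' }
#' Both converge to the same continuous dynamics as dt -> 0.
#'
#' @param half_life elimination half-life in hours (> 0), or the string
#'   `"disabled"`.
#' @param mode `"increment"` or `"exact"`.
#' @return object of class `clearance_spec`.
#' @export
clearance_spec <- function(half_life, mode = c("increment", "exact")) {
  mode <- match.arg(mode)
  if (identical(half_life, "disabled") || is.null(half_life)) {
    return(structure(list(enabled = FALSE, half_life = NA_real_, mode = mode),
                     class = "clearance_spec"))
  }
  .check_scalar(half_life, "half_life", lower = 0, strict = TRUE)
  structure(list(enabled = TRUE, half_life = half_life, mode = mode),
            class = "clearance_spec")
}

#' @rdname clearance_spec
#' @export
clearance_disabled <- function() clearance_spec("disabled")

#' @export
print.clearance_spec <- function(x, ...) {
  if (x$enabled) {
    cat("Clearance: half-life", x$half_life, "h (", x$mode, "mode )\n")
  } else {
    cat("Clearance: disabled\n")
  }
  invisible(x)
}
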