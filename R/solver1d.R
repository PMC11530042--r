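# Explicit finite-difference stepping of Fick's second law with first-order
# half-life clearance. Concentrations are ug/mL, lengths mm, times h; the
# diffusion update D*dt/dx^2 * (C[i-1] - 2C[i] + C[i+1]) is unit-free so only
# flux and mass bookkeeping need the mL <-> mm^3 factor.

.stability_error <- function(dt, bound) {
  stop(structure(
    class = c("vanco_stability_error", "error", "condition"),
    list(message = paste0(
      "time step dt = ", format(dt), " h violates the explicit stability ",
      "bound dx^2/(6 D) = ", format(bound), " h; reduce dt"),
      call = NULL)))
}

.negative_error <- function(t, idx, value) {
  stop(structure(
    class = c("vanco_solver_fault", "error", "condition"),
    list(message = paste0(
      "negative concentration ", format(value), " ug/mL in cell ", idx,
      " at t = ", format(t), " h; solver fault"),
      call = NULL)))
}

#' Per-step clearance increment
#'
#' Concentration change removed from one cell over one explicit step by
#' first-order elimination with half-life t1/2:
#' `dt * ln(0.5)/t_half * C * 0.5^(dt/t_half)` (a non-positive number).
#' Returns 0 when clearance is disabled. Repeated application converges to
#' exact exponential halving as dt -> 0.
#'
#' @param C concentration, ug/mL (vectorized).
#' @param dt time step, h (> 0).
#' @param clearance a [clearance_spec()].
#' @return concentration increment (<= 0), ug/mL.
#' @examples
#' decay_increment(100, 0.01, clearance_spec(4)) # -0.17299
#' @export
decay_increment <- function(C, dt, clearance) {
  stopifnot(inherits(clearance, "clearance_spec"))
  .check_scalar(dt, "dt", lower = 0, strict = TRUE)
  if (!clearance$enabled) return(C * 0)
  th <- clearance$half_life
  dt * log(0.5) / th * C * 0.5^(dt / th)
}

.new_ledger <- function(stored0) {
  list(influx = 0, cleared = 0, boundary_net = 0,
       stored_initial = stored0, stored = stored0)
}

.stored_mass_1d <- function(C, grid) sum(C) * grid$cell_volume_mL

# One or more explicit steps on a 1-D grid; shared by step_1d/simulate_1d.
# Returns list(C, t, ledger).
.advance_1d <- function(C, t, grid, left, right, clearance, dt, nsteps,
                        ledger) {
  dx <- grid$dx
  n <- grid$n
  D <- grid$cell_D
  volML <- grid$cell_volume_mL
  faceD <- if (n > 1) 2 / (1 / D[-n] + 1 / D[-1]) else numeric(0)
  coef <- dt / dx^2
  th <- if (clearance$enabled) clearance$half_life else NA_real_
  kdec <- if (clearance$enabled && clearance$mode == "increment") {
    dt * log(0.5) / th * 0.5^(dt / th)
  } else 0
  fexact <- if (clearance$enabled && clearance$mode == "exact") {
    0.5^(dt / th)
  } else 1
  left_flux <- identical(left$kind, "flux_in")
  right_flux <- identical(right$kind, "flux_in")
  neg_tol <- -1e-10

  for (s in seq_len(nsteps)) {
    g <- if (n > 1) faceD * (C[-1] - C[-n]) else numeric(0)
    dC <- coef * (c(g, 0) - c(0, g))
    if (left_flux) {
      J <- left$flux_fn(t)
      dC[1] <- dC[1] + dt * J / (dx * ML_PER_MM3)
      ledger$influx <- ledger$influx + grid$A * J * dt
    }
    if (right_flux) {
      J <- right$flux_fn(t)
      dC[n] <- dC[n] + dt * J / (dx * ML_PER_MM3)
      ledger$influx <- ledger$influx + grid$A * J * dt
    }
    if (kdec != 0) {
      dec <- kdec * C
      ledger$cleared <- ledger$cleared - sum(dec) * volML
      C <- C + dC + dec
    } else {
      C <- C + dC
    }
    if (fexact != 1) {
      ledger$cleared <- ledger$cleared + sum(C) * (1 - fexact) * volML
      C <- C * fexact
    }
    if (identical(left$kind, "dirichlet")) {
      ledger$boundary_net <- ledger$boundary_net + (left$value - C[1]) * volML
      C[1] <- left$value
    }
    if (identical(right$kind, "dirichlet")) {
      ledger$boundary_net <- ledger$boundary_net + (right$value - C[n]) * volML
      C[n] <- right$value
    }
    t <- t + dt
    m <- min(C)
    if (m < 0) {
      scale <- max(abs(C), 1)
      if (m < neg_tol * scale) .negative_error(t, which.min(C), m)
      C[C < 0] <- 0
    }
  }
  ledger$stored <- .stored_mass_1d(C, grid)
  list(C = C, t = t, ledger = ledger)
}

.check_dt_1d <- function(dt, grid) {
  bound <- grid$dx^2 / (6 * max(grid$cell_D))
  if (dt > bound * (1 + 1e-12)) .stability_error(dt, bound)
  bound
}

#' Advance a 1-D state by one explicit step
#'
#' Interior cells follow the standard three-point stencil
#' `C_i + D dt/dx^2 (C_{i-1} - 2 C_i + C_{i+1})` plus the clearance term;
#' a flux boundary adds `dt/dx * J_in(t)` (in consistent units) to its cell;
#' a no-flux end uses the one-sided stencil; Dirichlet/sink cells are pinned
#' after the stencil. The step is rejected if `dt` violates the stability
#' bound `dx^2/(6 D)`.
#'
#' @param state list with `t` (h) and `C` (ug/mL, length `grid$n`).
#' @param grid a [grid_1d()].
#' @param left,right [boundary_condition] objects.
#' @param clearance a [clearance_spec()].
#' @param dt time step, h.
#' @return updated state (class `sim_state`).
#' @export
step_1d <- function(state, grid, left, right, clearance = clearance_disabled(),
                    dt) {
  stopifnot(length(state$C) == grid$n)
  .check_dt_1d(dt, grid)
  out <- .advance_1d(state$C, state$t, grid, left, right, clearance, dt, 1L,
                     .new_ledger(.stored_mass_1d(state$C, grid)))
  structure(list(t = out$t, C = out$C), class = "sim_state")
}

#' Run a 1-D diffusion-clearance simulation
#'
#' Explicit time stepping from `t = 0` to `t_end`, recording concentration
#' snapshots every `record_every` hours and maintaining a mass ledger
#' (cumulative influx, cumulative cleared, net mass added/removed by pinned
#' boundaries, stored mass). Deterministic for fixed inputs.
#'
#' @param grid a [grid_1d()].
#' @param left,right [boundary_condition] objects (defaults: no-flux).
#' @param clearance a [clearance_spec()].
#' @param t_end simulation horizon, h.
#' @param dt time step, h; `NULL` picks `cfl_safety` times the stability
#'   bound. The step actually used divides each recording interval exactly
#'   and never exceeds the requested value.
#' @param record_every snapshot interval, h (default: 20 snapshots).
#' @param C0 initial concentration, ug/mL: scalar or length-`n` vector.
#' @param cfl_safety fraction of the stability bound used when `dt` is NULL.
#' @return object of class `sim_result`: `times`, `states` (matrix, one row
#'   per recorded time), `ledger`, `grid`, `clearance`, `dt_used`.
#' @export
simulate_1d <- function(grid, left = bc_no_flux(), right = bc_no_flux(),
                        clearance = clearance_disabled(), t_end,
                        dt = NULL, record_every = NULL, C0 = 0,
                        cfl_safety = 0.9) {
  .check_scalar(t_end, "t_end", lower = 0, strict = TRUE)
  bound <- grid$dx^2 / (6 * max(grid$cell_D))
  if (is.null(dt)) dt <- cfl_safety * bound
  .check_dt_1d(dt, grid)
  if (is.null(record_every)) record_every <- t_end / 20
  C <- rep_len(as.numeric(C0), grid$n)
  if (any(C < 0)) stop("initial concentrations must be non-negative")
  rec <- seq(0, t_end, by = record_every)
  if (rec[length(rec)] < t_end - 1e-12) rec <- c(rec, t_end)
  states <- matrix(NA_real_, nrow = length(rec), ncol = grid$n)
  states[1, ] <- C
  ledger <- .new_ledger(.stored_mass_1d(C, grid))
  t <- 0
  for (k in seq_along(rec)[-1]) {
    span <- rec[k] - rec[k - 1]
    nsteps <- max(1L, as.integer(ceiling(span / dt - 1e-9)))
    out <- .advance_1d(C, t, grid, left, right, clearance, span / nsteps,
                       nsteps, ledger)
    C <- out$C; t <- rec[k]; ledger <- out$ledger
    states[k, ] <- C
  }
  structure(list(times = rec, states = states, ledger = ledger, grid = grid,
                 clearance = clearance, dt_used = dt),
            class = "sim_result")
}

#' Mass-ledger report
#'
#' Verifies the discrete bookkeeping: cumulative boundary influx plus the net
#' mass injected by pinned (Dirichlet/sink) boundaries must equal cleared
#' mass plus the change in stored mass. The relative closure error is
#' reported against the total mass turnover.
#'
#' @param result a `sim_result` from [simulate_1d()] or [simulate_2d()].
#' @return list with `influx`, `cleared`, `boundary_net`, `stored_initial`,
#'   `stored`, and non-negative `closure_error` (relative).
#' @export
mass_balance <- function(result) {
  led <- result$ledger
  imbalance <- led$influx + led$boundary_net - led$cleared -
    (led$stored - led$stored_initial)
  turnover <- led$influx + abs(led$boundary_net) + led$cleared +
    abs(led$stored - led$stored_initial) + led$stored_initial
  closure <- if (turnover > 0) abs(imbalance) / turnover else 0
  c(led[c("influx", "cleared", "boundary_net", "stored_initial", "stored")],
    list(closure_error = closure))
}

#' @export
print.sim_result <- function(x, ...) {
  d <- if (!is.null(x$grid$n)) "1-D" else "2-D"
  cat("Simulation result (", d, "): ", length(x$times), " snapshots to t = ",
      max(x$times), " h, dt = ", format(x$dt_used), " h\n", sep = "")
  mb <- mass_balance(x)
  cat("  mass ledger (ug): influx ", format(mb$influx),
      ", cleared ", format(mb$cleared),
      ", stored ", format(mb$stored),
      ", closure ", format(mb$closure_error), "\n", sep = "")
  invisible(x)
}
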