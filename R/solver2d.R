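# 2-D extension of the explicit scheme (five-point Laplacian) for the agar
# inhibition-zone scenario. Outer boundaries are zero-gradient (symmetric /
# no-slip); source-mask cells receive the release flux diluted over the
# medium depth.

.stored_mass_2d <- function(C, grid) sum(C) * grid$cell_volume_mL

.advance_2d <- function(C, t, grid, source_flux_fn, clearance, dt, nsteps,
                        ledger) {
  nx <- grid$nx; ny <- grid$ny
  coef <- grid$D * dt / grid$dx^2
  mask <- grid$source_mask
  any_src <- any(mask)
  src_area <- sum(mask) * grid$dx^2 # mm^2 footprint
  volML <- grid$cell_volume_mL
  th <- if (clearance$enabled) clearance$half_life else NA_real_
  kdec <- if (clearance$enabled && clearance$mode == "increment") {
    dt * log(0.5) / th * 0.5^(dt / th)
  } else 0
  fexact <- if (clearance$enabled && clearance$mode == "exact") {
    0.5^(dt / th)
  } else 1
  iu <- c(1L, seq_len(nx - 1L)); id <- c(seq_len(nx - 1L) + 1L, nx)
  jl <- c(1L, seq_len(ny - 1L)); jr <- c(seq_len(ny - 1L) + 1L, ny)

  for (s in seq_len(nsteps)) {
    lap <- C[iu, , drop = FALSE] + C[id, , drop = FALSE] +
      C[, jl, drop = FALSE] + C[, jr, drop = FALSE] - 4 * C
    dC <- coef * lap
    if (any_src) {
      J <- source_flux_fn(t)
      if (J > 0) {
        dC[mask] <- dC[mask] + dt * J / (grid$thickness * ML_PER_MM3)
        ledger$influx <- ledger$influx + J * src_area * dt
      }
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
    t <- t + dt
    m <- min(C)
    if (m < 0) {
      if (m < -1e-10 * max(abs(C), 1)) .negative_error(t, which.min(C), m)
      C[C < 0] <- 0
    }
  }
  ledger$stored <- .stored_mass_2d(C, grid)
  list(C = C, t = t, ledger = ledger)
}

.check_dt_2d <- function(dt, grid) {
  # dx^2/(6D) retained in 2-D as well (stricter than the 2-D requirement
  # dx^2/(4D)), matching the 1-D rule.
  bound <- grid$dx^2 / (6 * grid$D)
  if (dt > bound * (1 + 1e-12)) .stability_error(dt, bound)
  bound
}

#' Advance a 2-D field by one explicit step
#'
#' @param state list with `t` (h) and `C` (`nx` by `ny` matrix, ug/mL).
#' @param grid a [grid_2d()].
#' @param source_flux_fn function of time returning the release flux
#'   (ug mm^-2 h^-1) applied over the source-mask footprint.
#' @param clearance a [clearance_spec()].
#' @param dt time step, h.
#' @return updated state.
#' @export
step_2d <- function(state, grid, source_flux_fn = function(t) 0,
                    clearance = clearance_disabled(), dt) {
  stopifnot(all(dim(state$C) == c(grid$nx, grid$ny)))
  .check_dt_2d(dt, grid)
  out <- .advance_2d(state$C, state$t, grid, source_flux_fn, clearance, dt,
                     1L, .new_ledger(.stored_mass_2d(state$C, grid)))
  structure(list(t = out$t, C = out$C), class = "sim_state")
}

#' Run a 2-D diffusion simulation with a releasing source mask
#'
#' @inheritParams step_2d
#' @param t_end horizon, h.
#' @param dt time step, h (`NULL`: `cfl_safety` times `dx^2/(6 D)`).
#' @param record_every snapshot interval, h.
#' @param C0 initial concentration (scalar or matrix), ug/mL.
#' @param cfl_safety fraction of the stability bound used when `dt` is NULL.
#' @return `sim_result` whose `states` is a list of matrices.
#' @export
simulate_2d <- function(grid, source_flux_fn = function(t) 0,
                        clearance = clearance_disabled(), t_end,
                        dt = NULL, record_every = NULL, C0 = 0,
                        cfl_safety = 0.9) {
  .check_scalar(t_end, "t_end", lower = 0, strict = TRUE)
  bound <- grid$dx^2 / (6 * grid$D)
  if (is.null(dt)) dt <- cfl_safety * bound
  .check_dt_2d(dt, grid)
  if (is.null(record_every)) record_every <- t_end / 10
  C <- if (is.matrix(C0)) C0 else matrix(C0, grid$nx, grid$ny)
  if (any(C < 0)) stop("initial concentrations must be non-negative")
  rec <- seq(0, t_end, by = record_every)
  if (rec[length(rec)] < t_end - 1e-12) rec <- c(rec, t_end)
  states <- vector("list", length(rec))
  states[[1]] <- C
  ledger <- .new_ledger(.stored_mass_2d(C, grid))
  t <- 0
  for (k in seq_along(rec)[-1]) {
    span <- rec[k] - rec[k - 1]
    nsteps <- max(1L, as.integer(ceiling(span / dt - 1e-9)))
    out <- .advance_2d(C, t, grid, source_flux_fn, clearance, span / nsteps,
                       nsteps, ledger)
    C <- out$C; t <- rec[k]; ledger <- out$ledger
    states[[k]] <- C
  }
  structure(list(times = rec, states = states, ledger = ledger, grid = grid,
                 clearance = clearance, dt_used = dt),
            class = "sim_result")
}
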