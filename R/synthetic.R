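# Seeded synthetic-data generators: noisy release measurements, noisy in
# vivo concentration series, full fixture suites, and the fitting helpers
# that close the parameter-recovery loop. Every generator is a pure
# function of (parameters, seed); no global RNG state leaks.

#' Measurement-noise specification
#'
#' @param kind `"gaussian_relative"` (sd proportional to the signal) or
#'   `"gaussian_absolute"` (constant sd).
#' @param magnitude noise magnitude (>= 0): relative fraction or absolute
#'   value in the signal's units.
#' @param seed integer RNG seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian_relative", "gaussian_absolute"),
                       magnitude, seed = 1) {
  kind <- match.arg(kind)
  if (magnitude < 0) stop("noise magnitude must be >= 0")
  structure(list(kind = kind, magnitude = magnitude, seed = seed),
            class = "noise_spec")
}

.add_noise <- function(values, noise) {
  if (noise$magnitude == 0) return(values)
  .with_seed(noise$seed, {
    sd <- if (noise$kind == "gaussian_relative") {
      noise$magnitude * abs(values)
    } else {
      rep(noise$magnitude, length(values))
    }
    values + stats::rnorm(length(values), 0, sd)
  })
}

#' Simulate a noisy measured release profile
#'
#' Adds seeded Gaussian noise to the cumulative release fraction, then
#' restores physical validity: running-maximum re-monotonization, clipping
#' to [0, 1], and an exact zero at t = 0. Emulates assay variability in a
#' cumulative-release dataset.
#'
#' @param profile a [release_profile()] (the truth).
#' @param noise a [noise_spec()].
#' @return a new [release_profile()] with noisy cumulative values.
#' @export
gen_release_measurements <- function(profile, noise) {
  stopifnot(inherits(profile, "release_profile"),
            inherits(noise, "noise_spec"))
  f <- .add_noise(profile$fraction, noise)
  f <- pmin(pmax(cummax(f), 0), 1)
  f[1] <- 0
  release_profile(profile$times, f, profile$total_load,
                  profile$coating_area, kind = "fraction")
}

#' Simulate a noisy in vivo concentration series
#'
#' Samples a simulated truth series at the requested times (linear
#' interpolation) and adds seeded measurement noise, emulating an external
#' animal-study concentration table (units ug/mL).
#'
#' @param times,values the truth series (h, ug/mL).
#' @param noise a [noise_spec()].
#' @param sampling_times measurement instants, h; must lie within the
#'   simulated horizon.
#' @return data.frame with `time`, `concentration`, and attribute
#'   `units = "ug/mL"`.
#' @export
gen_invivo_series <- function(times, values, noise, sampling_times) {
  if (any(sampling_times < min(times) | sampling_times > max(times))) {
    stop("sampling times outside the simulated horizon [",
         min(times), ", ", max(times), "] h")
  }
  truth <- stats::approx(times, values, xout = sampling_times)$y
  out <- data.frame(time = sampling_times,
                    concentration = pmax(.add_noise(truth, noise), 0))
  attr(out, "units") <- "ug/mL"
  out
}

#' Fit an elimination half-life to a decaying series
#'
#' Log-linear least squares on the decay phase: `log C = a + b t` gives
#' `t_half = -log(2)/b`. Non-positive concentrations are dropped.
#'
#' @param times,concentration decay-phase series (h, ug/mL).
#' @return fitted half-life, h.
#' @export
fit_half_life <- function(times, concentration) {
  ok <- concentration > 0
  if (sum(ok) < 3) stop("need at least 3 positive points")
  fit <- stats::lm(log(concentration[ok]) ~ times[ok])
  b <- unname(stats::coef(fit)[2])
  if (b >= 0) stop("series is not decaying; cannot fit a half-life")
  -log(2) / b
}

#' Fit the power-law release exponent
#'
#' Log-log least squares of the (uncapped) cumulative fraction against
#' time: `log f = log k + n log t`.
#'
#' @param times,fraction cumulative release samples (t > 0, 0 < f < 1).
#' @return list with `k` and `n`.
#' @export
fit_release_exponent <- function(times, fraction) {
  ok <- times > 0 & fraction > 0 & fraction < 0.99
  if (sum(ok) < 3) stop("need at least 3 usable points")
  fit <- stats::lm(log(fraction[ok]) ~ log(times[ok]))
  co <- stats::coef(fit)
  list(k = exp(unname(co[1])), n = unname(co[2]))
}

#' Generate a complete fixture suite
#'
#' Emits all four scenario configurations at test resolution plus the
#' default synthetic release profile (with mild seeded measurement noise)
#' into a directory; the whole pipeline can run from this directory alone.
#' Different seeds give different profiles but identical config structure.
#'
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @param noise_magnitude relative noise on the emitted profile.
#' @return invisible list of the written file paths.
#' @export
gen_fixture_suite <- function(seed, dir, noise_magnitude = 0.02) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- gen_release_measurements(
    default_release_profile(),
    noise_spec("gaussian_relative", noise_magnitude, seed = seed))
  prof_path <- file.path(dir, "release_profile.tsv")
  write_release_profile(prof, prof_path)
  # Test-resolution overrides: coarser cells and shorter horizons so the
  # whole suite runs in seconds while exercising every code path.
  overrides <- list(
    in_vitro_release = list(
      geometry = list(slab_length_mm = 20.8, dx_mm = 0.8),
      run = list(t_end = 240, record_every = 24, seed = seed)),
    agar = list(
      geometry = list(domain_mm = 70, dx_mm = 2, square_mm = 30),
      source = list(path = prof_path),
      run = list(t_end = 12, record_every = 6, seed = seed)),
    rat_tibia = list(
      geometry = list(dx_mm = 0.2, cortical_mm = 0.8, cancellous_mm = 1.6),
      run = list(t_end = 12, record_every = 1, seed = seed)),
    human_bone_plate = list(
      geometry = list(tissue_dx_mm = 0.3, bone_dx_mm = 0.5),
      source = list(path = prof_path),
      run = list(t_end = 12, record_every = 1, seed = seed))
  )
  paths <- list(release_profile = prof_path)
  for (sc in .scenario_names) {
    cfg <- default_config(sc, overrides[[sc]])
    p <- file.path(dir, paste0(sc, ".yaml"))
    write_scenario_config(cfg, p)
    paths[[sc]] <- p
  }
  invisible(paths)
}
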