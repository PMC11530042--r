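#' Cumulative drug-release profile
#'
#' A release profile records the cumulative amount of drug released from the
#' coating as a function of time, either as a fraction of the total load
#' (M_t / M_inf in [0, 1]) or as mass (ug). Together with the total load and
#' the coating footprint it defines the flux boundary condition J_in(t) for
#' the solver.
#'
#' @param times sampling times, h; strictly increasing, starting at 0.
#' @param cumulative cumulative release at `times`: fraction in [0, 1] or
#'   mass in ug; non-decreasing, 0 at t = 0.
#' @param total_load total drug load in the coating, ug.
#' @param coating_area releasing footprint, mm^2.
#' @param kind `"fraction"`, `"mass"`, or `"auto"` (fraction when the final
#'   value is <= 1).
#' @return object of class `release_profile` with fields `times`,
#'   `fraction`, `mass` (ug), `total_load`, `coating_area`.
#' @export
release_profile <- function(times, cumulative, total_load, coating_area,
                            kind = c("auto", "fraction", "mass")) {
  kind <- match.arg(kind)
  if (length(times) != length(cumulative) || length(times) < 2) {
    stop("times and cumulative must be equal-length vectors (>= 2 points)")
  }
  if (any(diff(times) <= 0)) stop("release times must be strictly increasing")
  if (abs(times[1]) > 1e-12) stop("release profile must start at t = 0")
  if (any(diff(cumulative) < -1e-12)) {
    stop("cumulative release must be non-decreasing")
  }
  if (abs(cumulative[1]) > 1e-12) stop("cumulative release must be 0 at t = 0")
  .check_scalar(total_load, "total_load", lower = 0, strict = TRUE)
  .check_scalar(coating_area, "coating_area", lower = 0, strict = TRUE)
  if (kind == "auto") {
    kind <- if (max(cumulative) <= 1 + 1e-9) "fraction" else "mass"
  }
  if (kind == "fraction") {
    if (max(cumulative) > 1 + 1e-9) stop("release fraction exceeds 1")
    fraction <- pmin(cumulative, 1)
    mass <- fraction * total_load
  } else {
    if (max(cumulative) > total_load * (1 + 1e-9)) {
      stop("cumulative mass exceeds total_load")
    }
    mass <- cumulative
    fraction <- mass / total_load
  }
  structure(list(times = as.numeric(times), fraction = fraction, mass = mass,
                 total_load = total_load, coating_area = coating_area),
            class = "release_profile")
}

#' Flux boundary value from a release profile
#'
#' Piecewise-linear interpolation of the cumulative released mass,
#' differentiated per segment and divided by the coating footprint:
#' `J_in(t) = (dM/dt) / A` in ug mm^-2 h^-1. Zero beyond the last sample
#' (exhausted reservoir); never negative because non-monotone profiles are
#' rejected at construction.
#'
#' @param profile a [release_profile()].
#' @param t time(s), h (>= 0).
#' @return flux values, ug mm^-2 h^-1 (vectorized over `t`).
#' @export
flux_from_profile <- function(profile, t) {
  stopifnot(inherits(profile, "release_profile"))
  if (any(t < 0)) stop("t must be >= 0")
  slopes <- diff(profile$mass) / diff(profile$times) / profile$coating_area
  seg <- findInterval(t, profile$times, rightmost.closed = FALSE)
  out <- numeric(length(t))
  inside <- seg >= 1 & seg <= length(slopes)
  out[inside] <- slopes[seg[inside]]
  out
}

#' Flux function closure for the solver
#'
#' @param profile a [release_profile()].
#' @param scale multiplier on the flux (e.g. the tissue/bone split fraction).
#' @return a function `J(t)` suitable for [bc_flux_in()].
#' @export
profile_flux_fn <- function(profile, scale = 1) {
  force(profile); force(scale)
  function(t) scale * flux_from_profile(profile, t)
}

#' Analytic fractional release from a plane slab into a perfect sink
#'
#' Series solution for a slab of thickness L, initially at uniform
#' concentration, sealed on one face and releasing through the other into a
#' perfect sink:
#' `M_t/M_inf = 1 - sum_k 8/((2k+1)^2 pi^2) exp(-D (2k+1)^2 pi^2 t / (4 L^2))`.
#' Serves as the independent oracle for the in vitro release simulation.
#'
#' @param D diffusivity, mm^2/h.
#' @param L slab thickness, mm.
#' @param t time(s), h.
#' @param terms number of series terms (>= 10).
#' @return fraction released in [0, 1], monotone in `t`.
#' @export
slab_release_analytic <- function(D, L, t, terms = 50) {
  .check_scalar(D, "D", lower = 0, strict = TRUE)
  .check_scalar(L, "L", lower = 0, strict = TRUE)
  if (terms < 10) stop("terms must be >= 10")
  k <- 0:(terms - 1)
  a <- (2 * k + 1)^2 * pi^2
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    min(1, max(0, 1 - sum(8 / a * exp(-D * a * ti / (4 * L^2)))))
  }, numeric(1))
}

#' Korsmeyer-Peppas power-law release profile
#'
#' Empirical release model `M_t/M_inf = k t^n`, capped at 1; the exponent
#' n = 0.5 corresponds to Fickian-controlled release. This is the synthetic
#' stand-in for an experimental cumulative-release dataset.
#'
#' @param k rate constant, h^-n (> 0).
#' @param n release exponent, in (0, 1].
#' @param t_end profile duration, h.
#' @param n_points number of samples (including t = 0).
#' @param total_load total drug load, ug.
#' @param coating_area releasing footprint, mm^2.
#' @return a [release_profile()].
#' @examples
#' p <- peppas_profile(k = 0.1, n = 0.5, t_end = 25, n_points = 26)
#' p$fraction[p$times == 25] # 0.5
#' @export
peppas_profile <- function(k, n, t_end, n_points = 101,
                           total_load = 100, coating_area = 1) {
  .check_scalar(k, "k", lower = 0, strict = TRUE)
  .check_scalar(n, "n", lower = 0, upper = 1, strict = TRUE)
  .check_scalar(t_end, "t_end", lower = 0, strict = TRUE)
  times <- seq(0, t_end, length.out = n_points)
  release_profile(times, pmin(k * times^n, 1), total_load, coating_area,
                  kind = "fraction")
}

#' Default synthetic release profile
#'
#' Fickian-controlled (n = 0.5) three-week profile without an initial burst:
#' the rate constant is fixed so 95% of the load is released at 21 days
#' (504 h), emulating an extended-release double-layer coating.
#'
#' @param total_load total drug load, ug (default 100 ug per mm^2 of plate).
#' @param coating_area releasing footprint, mm^2.
#' @param n_points number of samples.
#' @return a [release_profile()].
#' @export
default_release_profile <- function(total_load = 100, coating_area = 1,
                                    n_points = 211) {
  peppas_profile(k = 0.95 / sqrt(504), n = 0.5, t_end = 504,
                 n_points = n_points, total_load = total_load,
                 coating_area = coating_area)
}

#' Read / write release profiles as delimited text
#'
#' Two-column tab-separated text (`time_h`, `cumulative`) preceded by a JSON
#' header block in `#`-prefixed comment lines carrying `total_load`,
#' `coating_area` and `kind`.
#'
#' @param profile a [release_profile()].
#' @param path file path.
#' @return `read_release_profile` returns a [release_profile()];
#'   `write_release_profile` returns `path` invisibly.
#' @export
write_release_profile <- function(profile, path) {
  stopifnot(inherits(profile, "release_profile"))
  hdr <- jsonlite::toJSON(list(total_load = profile$total_load,
                               coating_area = profile$coating_area,
                               kind = "fraction"), auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  writeLines("time_h\tcumulative", con)
  utils::write.table(
    data.frame(time_h = profile$times, cumulative = profile$fraction),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_release_profile
#' @export
read_release_profile <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  if (length(hdr_lines) == 0) stop("missing JSON header block in ", path)
  meta <- jsonlite::fromJSON(sub("^#\\s*", "", hdr_lines[1]))
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  release_profile(tab$time_h, tab$cumulative, meta$total_load,
                  meta$coating_area, kind = meta$kind)
}

#' @export
print.release_profile <- function(x, ...) {
  cat("Release profile:", length(x$times), "samples over",
      max(x$times), "h; load", x$total_load, "ug over",
      x$coating_area, "mm^2; final fraction",
      format(x$fraction[length(x$fraction)]), "\n")
  invisible(x)
}
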