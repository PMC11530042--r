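#' Volume-weighted average concentration over a region
#'
#' For a 1-D result, `region` selects cells either as an index range or by
#' layer name; cells have equal volume so the volume-weighted mean is the
#' plain mean over the region.
#'
#' @param result a `sim_result` from [simulate_1d()].
#' @param region integer cell indices, a layer name (character), or `NULL`
#'   for the whole domain.
#' @return data.frame with columns `time` (h) and `concentration` (ug/mL).
#' @export
average_concentration <- function(result, region = NULL) {
  grid <- result$grid
  if (is.null(region)) {
    idx <- seq_len(grid$n)
  } else if (is.character(region)) {
    idx <- which(grid$cell_layer %in% region)
    if (length(idx) == 0) stop("no cells in layer(s) ",
                               paste(region, collapse = ", "))
  } else {
    idx <- as.integer(region)
    if (length(idx) == 0 || any(idx < 1 | idx > grid$n)) {
      stop("region indices outside the grid (1..", grid$n, ")")
    }
  }
  data.frame(time = result$times,
             concentration = rowMeans(result$states[, idx, drop = FALSE]))
}

#' Inhibition area of a 2-D field
#'
#' Area (cm^2) of the medium where the drug concentration meets or exceeds
#' the minimum inhibitory concentration: count of non-source cells with
#' `C >= MIC` times `dx^2`, plus the source footprint when `include_source`
#' is set (the substrate itself supports no growth, so by default its
#' footprint counts toward the inhibition area).
#'
#' @param field `nx` by `ny` concentration matrix (ug/mL) or a 2-D
#'   `sim_result` (last snapshot used).
#' @param grid the [grid_2d()] the field lives on (taken from the result if
#'   a `sim_result` is given).
#' @param MIC threshold, ug/mL.
#' @param include_source add the source footprint to the area (default TRUE).
#' @return area, cm^2.
#' @export
inhibition_area <- function(field, grid = NULL, MIC = 2,
                            include_source = TRUE) {
  if (inherits(field, "sim_result")) {
    grid <- field$grid
    field <- field$states[[length(field$states)]]
  }
  if (is.null(grid)) stop("grid required when field is a bare matrix")
  if (!all(is.finite(field))) stop("field contains non-finite values")
  mask <- grid$source_mask
  fluid <- !mask
  area_mm2 <- sum(field[fluid] >= MIC) * grid$dx^2
  if (include_source) area_mm2 <- area_mm2 + sum(mask) * grid$dx^2
  area_mm2 / 100
}

#' Classify a concentration field against MIC and toxicity thresholds
#'
#' Partitions every cell into `sub_MIC` (C < MIC), `effective`
#' (MIC <= C <= toxicity) or `toxic` (C > toxicity), the zoning used to read
#' antibacterial-efficacy maps.
#'
#' @param field numeric vector (1-D state) or matrix (2-D field), ug/mL.
#' @param MIC minimum inhibitory concentration, ug/mL (default 2).
#' @param toxicity toxicity threshold, ug/mL (default 1000).
#' @param dx cell size, mm; when given, per-class measures are reported
#'   (length mm for vectors, area cm^2 for matrices).
#' @return object of class `zone_map`: `classes` (same shape as `field`),
#'   `counts`, `measure` (named per-class), `MIC`, `toxicity`.
#' @export
classify_zones <- function(field, MIC = 2, toxicity = 1000, dx = NULL) {
  if (MIC >= toxicity) stop("MIC must be below the toxicity threshold")
  cls <- ifelse(field < MIC, "sub_MIC",
                ifelse(field > toxicity, "toxic", "effective"))
  if (is.matrix(field)) dim(cls) <- dim(field)
  lev <- c("sub_MIC", "effective", "toxic")
  counts <- vapply(lev, function(l) sum(cls == l), numeric(1))
  measure <- NULL
  if (!is.null(dx)) {
    measure <- if (is.matrix(field)) counts * dx^2 / 100 else counts * dx
  }
  structure(list(classes = cls, counts = counts, measure = measure,
                 MIC = MIC, toxicity = toxicity),
            class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat("Zone map (MIC ", x$MIC, ", toxicity ", x$toxicity, " ug/mL): ",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
      " cells\n", sep = "")
  invisible(x)
}

#' One-sample t test from summary statistics
#'
#' Two-sided test of a sample mean against a reference value mu0 using only
#' the summary statistics: `t = (mean - mu0) / (sd / sqrt(n))` with `n - 1`
#' degrees of freedom. Used to compare a measured inhibition area (mean, sd
#' over replicates) with the simulated one.
#'
#' @param mean sample mean.
#' @param sd sample standard deviation (> 0).
#' @param n number of replicates (>= 2).
#' @param mu0 reference value.
#' @return list of class `t_test_result`: `statistic`, `df`, `p_value`.
#' @examples
#' one_sample_t_test(12.97, 1.30, n = 3, mu0 = 15.43) # p = 0.082
#' @export
one_sample_t_test <- function(mean, sd, n, mu0) {
  if (n < 2) stop("n must be >= 2")
  .check_scalar(sd, "sd", lower = 0, strict = TRUE)
  tstat <- (mean - mu0) / (sd / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(tstat), df = df)
  structure(list(statistic = tstat, df = df, p_value = p),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("One-sample t test: t = %.4f, df = %d, two-sided p = %.4f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
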