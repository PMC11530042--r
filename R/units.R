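# Canonical internal units: length mm, time h, concentration ug/mL, mass ug.
# 1 mL = 1000 mm^3, so mass[ug] = C[ug/mL] * volume[mm^3] / 1000.

#' Millilitres per cubic millimetre
#'
#' Conversion constant between the canonical volume unit used for
#' concentrations (mL) and the geometric unit (mm^3).
#' @keywords internal
ML_PER_MM3 <- 1e-3

.diff_unit_factors <- c(
  "cm2/s" = 100 * 3600, # -> mm2/h
  "cm2/h" = 100,
  "mm2/s" = 3600,
  "mm2/h" = 1
)

.normalize_diff_unit <- function(u) {
  u <- gsub("\\^", "", tolower(trimws(u)))
  u <- gsub("²", "2", u)
  if (!u %in% names(.diff_unit_factors)) {
    stop("unknown diffusivity unit '", u,
         "'; use one of: ", paste(names(.diff_unit_factors), collapse = ", "),
         call. = FALSE)
  }
  u
}

#' Convert a diffusion coefficient between unit systems
#'
#' Exact factor conversion between the unit systems that appear in the
#' drug-release literature (cm^2/s, cm^2/h, mm^2/s, mm^2/h). The package's
#' canonical internal unit is mm^2/h.
#'
#' @param value numeric diffusivity (vectorized).
#' @param from,to unit strings, one of `"cm2/s"`, `"cm2/h"`, `"mm2/s"`,
#'   `"mm2/h"` (case-insensitive, `^` tolerated).
#' @return diffusivity expressed in `to` units.
#' @examples
#' convert_diffusivity(2.83e-6, "cm2/s", "mm2/h") # 1.0188
#' @export
convert_diffusivity <- function(value, from, to) {
  from <- .normalize_diff_unit(from)
  to <- .normalize_diff_unit(to)
  value * .diff_unit_factors[[from]] / .diff_unit_factors[[to]]
}
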