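# Text output: snapshots as delimited matrices, ledgers/summaries as JSON.

#' Write recorded concentration snapshots as delimited text
#'
#' One row per recorded time, one column per cell; the header carries cell
#' positions in mm (1-D) or the flattened column index (2-D).
#'
#' @param result a `sim_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(result, path) {
  if (is.matrix(result$states)) {
    m <- result$states
    colnames(m) <- sprintf("x_%g_mm", result$grid$positions)
  } else {
    m <- t(vapply(result$states, as.numeric,
                  numeric(result$grid$nx * result$grid$ny)))
    colnames(m) <- sprintf("cell_%d", seq_len(ncol(m)))
  }
  df <- cbind(data.frame(time_h = result$times), as.data.frame(m))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the mass ledger as a JSON sidecar
#'
#' @param result a `sim_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(result, path) {
  jsonlite::write_json(mass_balance(result), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write the standard output set of a scenario run
#'
#' Snapshot matrices and derived series as tab-separated text, ledger and a
#' short summary (peak value/time, areas) as JSON.
#'
#' @param res a scenario result object.
#' @param out_dir directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_scenario_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  if (inherits(res, "in_vitro_result")) {
    utils::write.table(res$series, p("release_series.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_snapshots(res$result, p("snapshots.tsv"))
    write_ledger(res$result, p("ledger.json"))
    summary <- list(final_fraction = max(res$series$fraction_released),
                    L_eff_mm = res$L_eff)
  } else if (inherits(res, "agar_result")) {
    write_snapshots(res$result, p("snapshots.tsv"))
    write_ledger(res$result, p("ledger.json"))
    utils::write.table(res$zone_map$classes, p("zone_classes.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    summary <- list(inhibition_area_cm2 = res$area_cm2,
                    zone_counts = as.list(res$zone_map$counts))
  } else if (inherits(res, "rat_tibia_result")) {
    utils::write.table(res$series, p("cortical_series.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_snapshots(res$result, p("snapshots.tsv"))
    write_ledger(res$result, p("ledger.json"))
    pk <- which.max(res$series$concentration)
    summary <- list(peak_concentration = res$series$concentration[pk],
                    peak_time = res$series$time[pk])
  } else if (inherits(res, "bone_plate_result")) {
    utils::write.table(res$tissue_series, p("tissue_series.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(res$bone_series, p("bone_series.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_snapshots(res$tissue, p("tissue_snapshots.tsv"))
    write_snapshots(res$bone, p("bone_snapshots.tsv"))
    write_ledger(res$tissue, p("tissue_ledger.json"))
    write_ledger(res$bone, p("bone_ledger.json"))
    summary <- res$summary
  } else {
    stop("unknown scenario result type")
  }
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
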