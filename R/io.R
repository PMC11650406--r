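# Persistence: reports as CSV/JSON, field maps and phantoms as RDS with
# spacing/origin metadata, labels additionally exportable as NRRD
# (detached text header + raw) for visual inspection.

#' Write a metrics report
#'
#' Writes `report.csv` and `report.json` (one record per design, columns
#' current for 90\% transmurality, electrode area, ECD, N vectors, ECD x N,
#' efficiency, lesion volume) and optional bar-chart figures.
#'
#' @param report a `metrics_report`.
#' @param dir output directory (created if missing).
#' @param plots also write PNG bar charts of current, ECD and efficiency.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir, plots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- report$report
  write.csv(df, file.path(dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(list(report = df, errors = report$errors),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plots) {
    plot_one <- function(col, ylab, file) {
      grDevices::png(file.path(dir, file), width = 900, height = 600)
      graphics::barplot(df[[col]], names.arg = df$design, las = 2,
                        ylab = ylab, main = ylab)
      grDevices::dev.off()
    }
    plot_one("current_for_90_A", "Per-vector current for 90% transmurality (A)",
             "current.png")
    plot_one("ecd_A_cm2", "Electrode current density (A/cm^2)", "ecd.png")
    plot_one("efficiency_percent", "Power into target (%)", "efficiency.png")
  }
  invisible(dir)
}

#' Persist field maps
#'
#' Saves the potential, field-magnitude and conductivity arrays of a
#' solution together with grid spacing and origin attributes.
#'
#' @param sol a `field_solution`.
#' @param grid the `anatomy_grid` it was solved on.
#' @param path output file (`.rds`).
#' @return the path, invisibly.
#' @export
write_field_maps <- function(sol, grid, path) {
  saveRDS(list(phi_V = sol$phi, E_mag_V_cm = sol$E_mag, sigma_S_m = sol$sigma,
               applied_voltage_V = sol$applied_voltage,
               achieved_current_A = sol$achieved_current,
               spacing_mm = grid$spacing_mm, origin_mm = grid$origin_mm),
          path)
  invisible(path)
}

#' Export a label volume as NRRD
#'
#' Detached-header NRRD (text header + `.raw` payload) so the phantom can be
#' inspected in standard volume viewers.
#'
#' @param grid an `anatomy_grid`.
#' @param path output header path (`.nhdr`); the raw payload is written
#'   alongside.
#' @return the path, invisibly.
#' @export
write_nrrd <- function(grid, path) {
  raw_path <- sub("\\.nhdr$", ".raw", path)
  if (identical(raw_path, path)) raw_path <- paste0(path, ".raw")
  d <- dim(grid$labels)
  con <- file(raw_path, "wb")
  writeBin(as.integer(grid$labels), con, size = 2L)
  close(con)
  hdr <- c("NRRD0004",
           "type: short",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           "encoding: raw",
           sprintf("endian: %s", .Platform$endian),
           sprintf("spacings: %g %g %g", grid$spacing_mm, grid$spacing_mm,
                   grid$spacing_mm),
           sprintf("space origin: (%g,%g,%g)", grid$origin_mm[1],
                   grid$origin_mm[2], grid$origin_mm[3]),
           sprintf("data file: %s", basename(raw_path)))
  writeLines(hdr, path)
  invisible(path)
}
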