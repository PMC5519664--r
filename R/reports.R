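#' Write a comparison report or energy-loss result to JSON or CSV
#'
#' JSON output preserves full numeric precision and carries a `units`
#' block; CSV output has one row per (region, component) for comparison
#' reports, or one row for an energy-loss result, with units embedded in
#' the column names.
#'
#' @param report a `comparison_report` ([compare_fields()]) or
#'   `energy_loss_result` ([compute_el()]).
#' @param path output file path.
#' @param format `"json"`, `"csv"` or `"auto"` (from the file extension).
#' @export
write_report <- function(report, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", csv = "csv",
                     stop_flow4d("cannot infer report format from extension",
                                 "flow4d_format_error"))
  }
  if (inherits(report, "comparison_report")) {
    if (format == "json") {
      payload <- list(type = "comparison_report",
                      units = list(mean_abs_error = "m/s", sd_abs_error = "m/s"),
                      rows = as.data.frame(report))
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                           dataframe = "rows", na = "null")
    } else {
      df <- as.data.frame(report)
      names(df)[names(df) == "mean_abs_error"] <- "mean_abs_error_m_per_s"
      names(df)[names(df) == "sd_abs_error"] <- "sd_abs_error_m_per_s"
      utils::write.csv(df, path, row.names = FALSE)
    }
  } else if (inherits(report, "energy_loss_result")) {
    if (format == "json") {
      payload <- list(type = "energy_loss_result",
                      units = list(el = "W"),
                      closure = report$closure$kind,
                      includes_eddy_viscosity = report$includes_eddy_viscosity,
                      el_total = report$el_total,
                      el_boundary_layer = report$el_boundary_layer,
                      el_core = report$el_core,
                      voxel_count = as.list(report$voxel_count))
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
    } else {
      df <- data.frame(closure = report$closure$kind,
                       includes_eddy_viscosity = report$includes_eddy_viscosity,
                       el_total_W = report$el_total,
                       el_boundary_layer_W = report$el_boundary_layer,
                       el_core_W = report$el_core,
                       voxels_boundary_layer = report$voxel_count[["boundary_layer"]],
                       voxels_core = report$voxel_count[["core"]])
      utils::write.csv(df, path, row.names = FALSE)
    }
  } else {
    stop_flow4d("unsupported report object", "flow4d_format_error")
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path JSON file path.
#' @return A `comparison_report` or `energy_loss_result`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$type, "comparison_report")) {
    out <- as.data.frame(x$rows)
    class(out) <- c("comparison_report", "data.frame")
    out
  } else if (identical(x$type, "energy_loss_result")) {
    structure(list(el_total = x$el_total,
                   el_boundary_layer = x$el_boundary_layer,
                   el_core = x$el_core,
                   closure = closure_model(x$closure),
                   includes_eddy_viscosity = x$includes_eddy_viscosity,
                   voxel_count = unlist(x$voxel_count)),
              class = "energy_loss_result")
  } else {
    stop_flow4d("unrecognized report file", "flow4d_format_error")
  }
}
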