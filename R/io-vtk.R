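# Legacy VTK structured-points (ASCII) reader/writer, the interchange
# format for simulation-side fields. Point data: VECTORS (velocity) or
# SCALARS (one component), x fastest.

write_vtk_structured_points <- function(path, shape, spacing, origin,
                                        vectors = NULL, scalars = NULL,
                                        name = "velocity") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "flow4d structured points",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", shape[1], shape[2], shape[3]),
               sprintf("SPACING %.17g %.17g %.17g",
                       spacing[1], spacing[2], spacing[3]),
               sprintf("ORIGIN %.17g %.17g %.17g",
                       origin[1], origin[2], origin[3]),
               sprintf("POINT_DATA %d", prod(shape))), con)
  if (!is.null(vectors)) {
    writeLines(sprintf("VECTORS %s double", name), con)
    m <- matrix(aperm(vectors, c(4, 1, 2, 3)), nrow = 3)  # 3 x n, x fastest
    writeLines(paste(format(m[1, ], digits = 17), format(m[2, ], digits = 17),
                     format(m[3, ], digits = 17)), con)
  } else {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.vector(scalars), digits = 17)), con)
  }
  invisible(path)
}

read_vtk_structured_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1]))
    stop_flow4d("not a legacy VTK file", "flow4d_format_error")
  if (toupper(trimws(lines[3])) != "ASCII")
    stop_flow4d("only ASCII legacy VTK files are supported", "flow4d_format_error")
  if (!grepl("STRUCTURED_POINTS", lines[4]))
    stop_flow4d("only STRUCTURED_POINTS VTK datasets are supported",
                "flow4d_format_error")
  grab <- function(key) {
    i <- grep(paste0("^", key), lines)
    if (length(i) == 0L)
      stop_flow4d(sprintf("VTK header missing %s", key), "flow4d_metadata_error")
    as.numeric(strsplit(trimws(sub(key, "", lines[i[1]])), "\\s+")[[1]])
  }
  shape <- as.integer(grab("DIMENSIONS"))
  spacing <- grab("SPACING")
  origin <- grab("ORIGIN")
  n <- prod(shape)
  iv <- grep("^VECTORS", lines)
  is_ <- grep("^SCALARS", lines)
  if (length(iv) > 0L) {
    vals <- scan(text = paste(lines[(iv[1] + 1):length(lines)], collapse = "\n"),
                 what = numeric(), n = 3 * n, quiet = TRUE)
    if (length(vals) < 3 * n)
      stop_flow4d("VTK vector payload truncated", "flow4d_format_error")
    arr <- aperm(array(vals, dim = c(3, shape)), c(2, 3, 4, 1))
    list(shape = shape, spacing = spacing, origin = origin,
         vectors = arr, scalars = NULL)
  } else if (length(is_) > 0L) {
    start <- is_[1] + 1
    if (grepl("^LOOKUP_TABLE", lines[start])) start <- start + 1
    vals <- scan(text = paste(lines[start:length(lines)], collapse = "\n"),
                 what = numeric(), n = n, quiet = TRUE)
    if (length(vals) < n)
      stop_flow4d("VTK scalar payload truncated", "flow4d_format_error")
    list(shape = shape, spacing = spacing, origin = origin,
         vectors = NULL, scalars = array(vals, dim = shape))
  } else {
    stop_flow4d("VTK file carries neither VECTORS nor SCALARS point data",
                "flow4d_format_error")
  }
}
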