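# Triangle-mesh readers/writers: binary STL, ascii PLY, ascii VTP
# (VTK XML PolyData). VTP can carry per-face data arrays (e.g. WSS).

guess_mesh_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         stl = "stl", ply = "ply", vtp = "vtp",
         stop_flow4d(sprintf("cannot infer mesh format of '%s'", path),
                     "flow4d_format_error"))
}

#' Write a triangle mesh to STL, PLY or VTP
#'
#' STL is binary (duplicated vertices per facet, float32, so round trips
#' are exact to ~1e-5 mm); PLY and VTP are ascii with shared vertices at
#' full precision. `cell_data` (named list of per-face numeric vectors,
#' e.g. WSS magnitude) is written for VTP only.
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param format `"auto"` (extension), `"stl"`, `"ply"` or `"vtp"`.
#' @param cell_data optional named list of per-face numeric vectors (VTP).
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "vtp"),
                       cell_data = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_mesh_format(path)
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "stl") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw("flow4d binary STL")
    writeBin(c(hdr, raw(80 - length(hdr))), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    # interleave: normal, v1, v2, v3 (float32) + attr (uint16) per facet
    block <- matrix(0, nrow = 12, ncol = nrow(f))
    block[1:3, ] <- t(mesh$normals)
    block[4:6, ] <- t(v[f[, 1], , drop = FALSE])
    block[7:9, ] <- t(v[f[, 2], , drop = FALSE])
    block[10:12, ] <- t(v[f[, 3], , drop = FALSE])
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else if (format == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0", "comment flow4d",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(paste(format(v[, 1], digits = 17), format(v[, 2], digits = 17),
                     format(v[, 3], digits = 17)), con)
    writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else {
    num <- function(x) paste(format(x, digits = 17), collapse = " ")
    cd <- ""
    if (!is.null(cell_data)) {
      arrs <- vapply(names(cell_data), function(nm) {
        sprintf('    <DataArray type="Float64" Name="%s" format="ascii">\n      %s\n    </DataArray>',
                nm, num(as.numeric(cell_data[[nm]])))
      }, character(1))
      cd <- sprintf("   <CellData>\n%s\n   </CellData>\n", paste(arrs, collapse = "\n"))
    }
    xml <- sprintf(
'<?xml version="1.0"?>
<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">
 <PolyData>
  <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">
   <Points>
    <DataArray type="Float64" NumberOfComponents="3" format="ascii">
      %s
    </DataArray>
   </Points>
%s   <Polys>
    <DataArray type="Int64" Name="connectivity" format="ascii">
      %s
    </DataArray>
    <DataArray type="Int64" Name="offsets" format="ascii">
      %s
    </DataArray>
   </Polys>
  </Piece>
 </PolyData>
</VTKFile>',
      nrow(v), nrow(f), num(t(v)), cd, paste(t(f) - 1L, collapse = " "),
      paste(seq_len(nrow(f)) * 3L, collapse = " "))
    writeLines(xml, path)
  }
  invisible(path)
}

#' Read a triangle mesh written by [write_mesh()]
#'
#' STL facets are welded back into shared vertices (exact coordinate
#' match after float32 storage).
#'
#' @param path mesh file (.stl, .ply or .vtp).
#' @param format `"auto"`, `"stl"`, `"ply"` or `"vtp"`.
#' @return A [tri_mesh()]; VTP cell data, if present, is attached as
#'   attribute `"cell_data"`.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "vtp")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_flow4d(sprintf("file '%s' does not exist", path), "flow4d_format_error")
  if (format == "auto") format <- guess_mesh_format(path)
  if (format == "stl") {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    # each 50-byte record is normal + 3 vertices (float32) + uint16 attr;
    # read the whole block as raw and carve it
    blob <- readBin(con, "raw", nf * 50)
    if (length(blob) < nf * 50)
      stop_flow4d("STL payload truncated", "flow4d_format_error")
    m <- matrix(blob, nrow = 50)
    tri <- matrix(0, nf, 9)
    for (j in 1:9) {
      off <- 12 + (j - 1) * 4
      tri[, j] <- readBin(as.vector(m[(off + 1):(off + 4), ]), "double",
                          nf, size = 4, endian = "little")
    }
    pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                 tri[, 7:9, drop = FALSE])
    key <- paste(pts[, 1], pts[, 2], pts[, 3])
    uk <- !duplicated(key)
    vid <- match(key, key[uk])
    verts <- pts[uk, , drop = FALSE]
    faces <- cbind(vid[seq_len(nf)], vid[nf + seq_len(nf)], vid[2 * nf + seq_len(nf)])
    tri_mesh(verts, faces)
  } else if (format == "ply") {
    lines <- readLines(path, warn = FALSE)
    if (lines[1] != "ply" || !any(grepl("^format ascii", lines)))
      stop_flow4d("only ascii PLY is supported", "flow4d_format_error")
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
    start <- grep("^end_header", lines)[1]
    vv <- scan(text = paste(lines[(start + 1):(start + nv)], collapse = "\n"),
               quiet = TRUE)
    verts <- matrix(vv, ncol = 3, byrow = TRUE)
    ff <- scan(text = paste(lines[(start + nv + 1):(start + nv + nf)], collapse = "\n"),
               quiet = TRUE)
    ff <- matrix(ff, ncol = 4, byrow = TRUE)
    if (any(ff[, 1] != 3))
      stop_flow4d("PLY contains non-triangle faces", "flow4d_format_error")
    tri_mesh(verts, ff[, 2:4] + 1L)
  } else {
    doc <- xml2::read_xml(path)
    piece <- xml2::xml_find_first(doc, ".//Piece")
    pts <- xml2::xml_find_first(piece, ".//Points/DataArray")
    verts <- matrix(scan(text = xml2::xml_text(pts), quiet = TRUE),
                    ncol = 3, byrow = TRUE)
    conn <- scan(text = xml2::xml_text(
      xml2::xml_find_first(piece, ".//Polys/DataArray[@Name='connectivity']")),
      quiet = TRUE)
    offs <- scan(text = xml2::xml_text(
      xml2::xml_find_first(piece, ".//Polys/DataArray[@Name='offsets']")),
      quiet = TRUE)
    if (any(diff(c(0, offs)) != 3))
      stop_flow4d("VTP contains non-triangle polys", "flow4d_format_error")
    faces <- matrix(conn, ncol = 3, byrow = TRUE) + 1L
    mesh <- tri_mesh(verts, faces)
    cds <- xml2::xml_find_all(piece, ".//CellData/DataArray")
    if (length(cds) > 0) {
      cell_data <- lapply(cds, function(a) scan(text = xml2::xml_text(a), quiet = TRUE))
      names(cell_data) <- vapply(cds, function(a) xml2::xml_attr(a, "Name"), character(1))
      attr(mesh, "cell_data") <- cell_data
    }
    mesh
  }
}
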