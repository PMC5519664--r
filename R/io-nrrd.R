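# Minimal NRRD reader/writer: ascii header, raw little-endian or ascii
# payload, attached (.nrrd) files. Spacing is carried in "space directions"
# (mm), origin in "space origin". Vector volumes store the 3 components as
# the fastest axis with kind "vector".

write_nrrd_raw <- function(path, data_dims, spacing, origin, payload,
                           kinds, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  ndim <- length(data_dims)
  dirs <- character(ndim)
  sp_axes <- which(kinds == "space")
  for (a in seq_len(ndim)) {
    if (kinds[a] == "space") {
      v <- c(0, 0, 0)
      v[which(sp_axes == a)] <- spacing[which(sp_axes == a)]
      dirs[a] <- sprintf("(%.17g,%.17g,%.17g)", v[1], v[2], v[3])
    } else {
      dirs[a] <- "none"
    }
  }
  hdr <- c("NRRD0004",
           "# generated by flow4d",
           "type: double",
           sprintf("dimension: %d", ndim),
           "space dimension: 3",
           sprintf("sizes: %s", paste(data_dims, collapse = " ")),
           sprintf("space directions: %s", paste(dirs, collapse = " ")),
           sprintf("kinds: %s", paste(kinds, collapse = " ")),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   origin[1], origin[2], origin[3]),
           "space units: \"mm\" \"mm\" \"mm\"",
           sprintf("encoding: %s", encoding))
  if (encoding == "raw") hdr <- c(hdr, "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(payload), con, size = 8, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(payload), digits = 17), collapse = " "),
               con)
  }
  invisible(path)
}

parse_nrrd_tuple <- function(s) {
  s <- gsub("[()]", "", trimws(s))
  as.numeric(strsplit(s, ",")[[1]])
}

read_nrrd_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!grepl("^NRRD000", magic))
    stop_flow4d("not a NRRD file", "flow4d_format_error")
  fields <- list()
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0L)
      stop_flow4d("NRRD header not terminated", "flow4d_format_error")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- kv[3]
  }
  dims <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  type <- trimws(fields$type %||% "double")
  encoding <- trimws(fields$encoding %||% "raw")
  n <- prod(dims)
  if (encoding == "raw") {
    size <- switch(type, double = 8, float = 4, `unsigned char` = 1,
                   uchar = 1, short = 2, int = 4,
                   stop_flow4d(sprintf("unsupported NRRD type %s", type),
                               "flow4d_format_error"))
    what <- if (type %in% c("double", "float")) "double" else "integer"
    endian <- if (grepl("big", fields$endian %||% "little")) "big" else "little"
    vals <- readBin(con, what, n, size = size, endian = endian,
                    signed = !type %in% c("unsigned char", "uchar"))
  } else if (encoding %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else {
    stop_flow4d(sprintf("unsupported NRRD encoding %s", encoding),
                "flow4d_format_error")
  }
  if (length(vals) < n)
    stop_flow4d("NRRD payload truncated", "flow4d_format_error")
  spacing <- NULL
  origin <- c(0, 0, 0)
  kinds <- rep("space", length(dims))
  if (!is.null(fields$kinds))
    kinds <- strsplit(trimws(fields$kinds), "\\s+")[[1]]
  if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(fields[["space directions"]],
                       gregexpr("none|\\([^)]*\\)", fields[["space directions"]]))[[1]]
    sp <- c()
    for (t in toks) {
      if (t == "none") next
      v <- parse_nrrd_tuple(t)
      sp <- c(sp, sqrt(sum(v^2)))
    }
    spacing <- sp
  } else if (!is.null(fields$spacings)) {
    sp <- suppressWarnings(as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]]))
    spacing <- sp[is.finite(sp)]
  }
  if (is.null(spacing) || length(spacing) != 3L || any(spacing <= 0))
    stop_flow4d("NRRD header has no usable 3-D spacing", "flow4d_metadata_error")
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_tuple(fields[["space origin"]])
  list(dims = dims, data = array(as.numeric(vals), dim = dims),
       spacing = spacing, origin = origin, kinds = kinds)
}
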