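#' Read a point cloud from LAS, PLY or XYZ
#'
#' Formats:
#' * `xyz` — whitespace-separated text, >= 3 numeric columns; extra columns
#'   are kept as per-point attributes; lines starting with `#` are skipped.
#' * `ply` — ASCII or binary little-endian PLY with float/double `x`,`y`,`z`
#'   vertex properties; other scalar vertex properties are kept as attributes.
#' * `las` — ASPRS LAS 1.0–1.3, point record formats 0–3; the header scale and
#'   offset are applied so coordinates come back in meters; intensity is kept
#'   as an attribute. LAZ files are compressed and not supported.
#'
#' Point order is preserved exactly as stored, and clouds are returned in the
#' raw frame.
#'
#' @param path File path.
#' @param format `"auto"` (from extension), `"las"`, `"ply"` or `"xyz"`.
#' @return A raw-frame [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "las", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         xyz = read_xyz(path),
         ply = read_ply(path),
         las = read_las(path))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         xyz = , txt = , pts = "xyz",
         ply = "ply",
         las = "las",
         laz = stopf("LAZ is compressed; no decompressor is available — convert to LAS first"),
         stopf("cannot infer point-cloud format from extension '.%s'", ext))
}

#' Write a point cloud to LAS, PLY or XYZ
#'
#' XYZ writes coordinates (plus attribute columns) as plain text. PLY writes
#' ASCII by default or binary little-endian with `binary = TRUE`, with double
#' precision coordinates. LAS writes version 1.2, point format 0, with a
#' 0.001 m coordinate scale (so a LAS round trip is exact to a millimeter)
#' and offset at the floor of the minimum coordinate.
#'
#' @param cloud A [point_cloud()].
#' @inheritParams read_point_cloud
#' @param binary For PLY: write binary little-endian instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "las", "ply", "xyz"),
                              binary = FALSE) {
  stopifnot(is_point_cloud(cloud))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!dir.exists(dirname(path))) stopf("directory does not exist: %s", dirname(path))
  switch(format,
         xyz = write_xyz(cloud, path),
         ply = write_ply(cloud, path, binary = binary),
         las = write_las(cloud, path))
  invisible(path)
}

# ---- XYZ ---------------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stopf("no points in %s", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 3L)) {
    stopf("line %d of %s has %d fields; at least 3 (x y z) required",
          lineno[which(nf < 3L)[1]], path, min(nf))
  }
  ncols <- min(nf)  # ragged extra columns are truncated to the common width
  vals <- suppressWarnings(
    vapply(toks, function(t) as.double(t[seq_len(ncols)]), double(ncols)))
  mat <- t(matrix(vals, nrow = ncols))
  if (!all(is.finite(mat[, 1:3]))) {
    bad <- which(!apply(is.finite(mat[, 1:3, drop = FALSE]), 1, all))[1]
    stopf("non-numeric coordinate on line %d of %s", lineno[bad], path)
  }
  if (ncols > 3L) colnames(mat) <- c("x", "y", "z", paste0("attr", seq_len(ncols - 3L)))
  point_cloud(mat)
}

write_xyz <- function(cloud, path) {
  df <- as.data.frame(cloud)
  num <- vapply(df, is.numeric, logical(1))
  utils::write.table(format(df[num], digits = 17, trim = TRUE, scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
}

# ---- PLY ---------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stopf("%s is not a PLY file", path)
  fmt <- NULL; nvert <- NULL; props <- list(); in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stopf("unexpected end of PLY header in %s", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
      else if (!is.null(nvert)) in_vertex <- FALSE
    }
    if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") stopf("list properties on vertices are not supported (%s)", path)
      props[[tok[3]]] <- tok[2]
    }
    if (tok[1] == "end_header") break
  }
  if (is.null(nvert) || nvert < 1L) stopf("no vertices in %s", path)
  if (!all(c("x", "y", "z") %in% names(props))) stopf("PLY lacks x/y/z vertex properties")
  if (identical(fmt, "ascii")) {
    rows <- readLines(con, n = nvert)
    toks <- strsplit(trimws(rows), "\\s+")
    vals <- vapply(toks, function(t) as.double(t[seq_along(props)]), double(length(props)))
    mat <- t(matrix(vals, nrow = length(props)))
  } else if (identical(fmt, "binary_little_endian")) {
    sizes <- ply_type_size[unlist(props)]
    if (anyNA(sizes)) stopf("unknown PLY property type in %s", path)
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = rec * nvert)
    if (length(raw) < rec * nvert) stopf("truncated PLY payload in %s", path)
    rawm <- matrix(raw, nrow = rec)
    off <- cumsum(c(0L, sizes))[seq_along(sizes)]
    mat <- matrix(0, nvert, length(props))
    for (j in seq_along(props)) {
      bytes <- as.vector(rawm[(off[j] + 1L):(off[j] + sizes[j]), , drop = FALSE])
      ty <- props[[j]]
      mat[, j] <- if (ty %in% c("float", "float32", "double", "float64")) {
        readBin(bytes, "double", n = nvert, size = sizes[j], endian = "little")
      } else {
        readBin(bytes, "integer", n = nvert, size = sizes[j], endian = "little",
                signed = !(ty %in% c("uchar", "uint8", "ushort", "uint16")))
      }
    }
  } else {
    stopf("unsupported PLY format '%s' (big-endian not handled)", fmt)
  }
  colnames(mat) <- names(props)
  ord <- c("x", "y", "z", setdiff(names(props), c("x", "y", "z")))
  point_cloud(mat[, ord, drop = FALSE])
}

write_ply <- function(cloud, path, binary = FALSE) {
  df <- as.data.frame(cloud)
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  df <- df[num]
  header <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    "comment written by pcdenoise",
    sprintf("element vertex %d", nrow(df)),
    sprintf("property double %s", names(df)),
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (binary) {
    mat <- t(as.matrix(df))
    writeBin(as.double(mat), con, size = 8L, endian = "little")
  } else {
    writeLines(do.call(paste, c(lapply(df, function(x) format(x, digits = 17, trim = TRUE,
                                                              scientific = FALSE)))), con)
  }
}

# ---- LAS (ASPRS 1.2, point formats 0-3) --------------------------------

las_point_size <- c(`0` = 20L, `1` = 28L, `2` = 26L, `3` = 34L)

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 227L)
  if (length(hdr) < 227L || rawToChar(hdr[1:4]) != "LASF") {
    stopf("%s is not a LAS file (missing LASF signature)", path)
  }
  u32 <- function(off) readBin(hdr[(off + 1):(off + 4)], "integer", size = 4, endian = "little")
  u16 <- function(off) readBin(hdr[(off + 1):(off + 2)], "integer", size = 2,
                               endian = "little", signed = FALSE)
  dbl <- function(off) readBin(hdr[(off + 1):(off + 8)], "double", size = 8, endian = "little")
  offset_to_points <- u32(96L)
  pdf_id <- as.integer(hdr[105L])
  rec_len <- u16(105L)
  npts <- u32(107L)
  if (npts < 0) stopf("LAS files with >2^31 points are not supported")
  scale <- c(dbl(131L), dbl(139L), dbl(147L))
  off3 <- c(dbl(155L), dbl(163L), dbl(171L))
  if (!pdf_id %in% 0:3) stopf("LAS point data format %d not supported (0-3 only)", pdf_id)
  if (npts == 0L) stopf("LAS file contains zero points: %s", path)
  seek(con, offset_to_points)
  raw <- readBin(con, "raw", n = as.double(rec_len) * npts)
  if (length(raw) < rec_len * npts) stopf("truncated LAS payload in %s", path)
  rawm <- matrix(raw, nrow = rec_len)
  geti32 <- function(row0) readBin(as.vector(rawm[(row0 + 1):(row0 + 4), , drop = FALSE]),
                                   "integer", n = npts, size = 4, endian = "little")
  xyz <- cbind(geti32(0L) * scale[1] + off3[1],
               geti32(4L) * scale[2] + off3[2],
               geti32(8L) * scale[3] + off3[3])
  intensity <- readBin(as.vector(rawm[13:14, , drop = FALSE]), "integer",
                       n = npts, size = 2, endian = "little", signed = FALSE)
  mat <- cbind(xyz, intensity)
  colnames(mat) <- c("x", "y", "z", "intensity")
  point_cloud(mat)
}

write_las <- function(cloud, path) {
  xyz <- as_matrix(cloud)
  n <- nrow(xyz)
  scale <- c(0.001, 0.001, 0.001)
  off3 <- floor(apply(xyz, 2, min))
  q <- sweep(sweep(xyz, 2, off3), 2, scale, "/")
  qi <- round(q)
  if (any(abs(qi) > 2^31 - 1)) stopf("coordinates exceed the LAS integer range at 0.001 m scale")
  intensity <- if ("intensity" %in% names(cloud)) {
    as.integer(pmin(pmax(round(cloud$intensity), 0), 65535))
  } else rep(0L, n)
  intensity[intensity > 32767L] <- intensity[intensity > 32767L] - 65536L  # two's complement
  con <- file(path, "wb")
  on.exit(close(con))
  w8 <- function(x) writeBin(as.raw(x), con)
  wu16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wu32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wdbl <- function(x) writeBin(as.double(x), con, size = 8, endian = "little")
  writeChar("LASF", con, nchars = 4, eos = NULL)
  wu16(0); wu16(0)                                      # source id, global encoding
  wu32(0); wu16(0); wu16(0); w8(rep(0, 8))              # project GUID 1-4
  w8(c(1, 2))                                           # version 1.2
  sys <- charToRaw(formatC("pcdenoise", width = 32, flag = " "))
  writeBin(sys[1:32], con)
  writeBin(sys[1:32], con)                              # generating software
  wu16(1); wu16(2026)                                   # day/year
  wu16(227); wu32(227)                                  # header size, offset to points
  wu32(0)                                               # no VLRs
  w8(0); wu16(20)                                       # PDF 0, record length
  wu32(n)
  for (i in 1:5) wu32(0)                                # returns histogram
  wdbl(scale[1]); wdbl(scale[2]); wdbl(scale[3])
  wdbl(off3[1]); wdbl(off3[2]); wdbl(off3[3])
  wdbl(max(xyz[, 1])); wdbl(min(xyz[, 1]))
  wdbl(max(xyz[, 2])); wdbl(min(xyz[, 2]))
  wdbl(max(xyz[, 3])); wdbl(min(xyz[, 3]))
  rec <- matrix(as.raw(0), nrow = 20L, ncol = n)
  packi32 <- function(v) matrix(writeBin(as.integer(v), raw(), size = 4, endian = "little"), nrow = 4L)
  rec[1:4, ] <- packi32(qi[, 1]); rec[5:8, ] <- packi32(qi[, 2]); rec[9:12, ] <- packi32(qi[, 3])
  rec[13:14, ] <- matrix(writeBin(as.integer(intensity), raw(), size = 2, endian = "little"), nrow = 2L)
  rec[15, ] <- as.raw(9L)  # return 1 of 1
  writeBin(as.vector(rec), con)
}
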