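# Minimal PLY point-cloud reader/writer (vertex x/y/z only). Supports ascii
# and binary_little_endian, float32/float64 vertex properties; other elements
# and properties are skipped.

#' Read a PLY point cloud
#'
#' @param path path to a `.ply` file (ascii or binary little-endian).
#' @return Numeric `n x 3` matrix of points.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) ct_stop("parse_error", "truncated PLY header in %s", path)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (length(header) == 0 || trimws(header[1]) != "ply")
    ct_stop("parse_error", "%s is not a PLY file", path)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  elem_lines <- grep("^element ", header)
  vert_i <- grep("^element vertex ", header)
  if (length(vert_i) != 1) ct_stop("parse_error", "PLY without a vertex element")
  n <- as.integer(strsplit(trimws(header[vert_i]), "\\s+")[[1]][3])
  next_elem <- elem_lines[elem_lines > vert_i]
  prop_end <- if (length(next_elem)) next_elem[1] - 1 else length(header) - 1
  props <- header[(vert_i + 1):prop_end]
  props <- props[grepl("^property ", props)]
  ptypes <- vapply(strsplit(trimws(props), "\\s+"), `[`, "", 2)
  pnames <- vapply(strsplit(trimws(props), "\\s+"), `[`, "", 3)
  if (!all(c("x", "y", "z") %in% pnames))
    ct_stop("parse_error", "PLY vertex element lacks x/y/z properties")
  if (fmt == "ascii") {
    rows <- readLines(con, n = n)
    vals <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    pts <- vals[, match(c("x", "y", "z"), pnames), drop = FALSE]
  } else if (fmt == "binary_little_endian") {
    sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
               int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
               float = 4, float32 = 4, double = 8, float64 = 8)
    if (any(!ptypes %in% names(sizes)))
      ct_stop("parse_error", "unsupported PLY property type")
    psz <- sizes[ptypes]
    raw <- readBin(con, "raw", n = n * sum(psz))
    if (length(raw) < n * sum(psz)) ct_stop("parse_error", "truncated PLY body")
    offs <- cumsum(c(0, psz))[seq_along(psz)]
    pts <- matrix(NA_real_, n, 3)
    for (k in 1:3) {
      j <- match(c("x", "y", "z")[k], pnames)
      sz <- psz[j]
      what <- if (ptypes[j] %in% c("float", "float32", "double", "float64")) "double" else "integer"
      idx <- as.vector(outer(seq_len(sz), (seq_len(n) - 1) * sum(psz) + offs[j], `+`))
      pts[, k] <- readBin(raw[idx], what, n = n, size = sz, endian = "little")
    }
  } else ct_stop("parse_error", "unsupported PLY format '%s'", fmt)
  if (any(!is.finite(pts))) ct_stop("parse_error", "non-finite PLY vertex")
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Write a point cloud as ascii PLY
#'
#' @param points numeric `n x 3` matrix.
#' @param path output path.
#' @export
write_ply <- function(points, path) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(points)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  writeLines(apply(points, 1, function(p) paste(format(p, digits = 10), collapse = " ")), con)
  invisible(path)
}
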