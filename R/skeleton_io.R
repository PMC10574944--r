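#' Read a skeleton sequence from JSON or CSV
#'
#' JSON schema: `{"fps": number, "space": "camera"|"wall", "frames":`
#' `[{"i": int, "J2": [x,y,z], ..., "J14": [x,y,z]}, ...]}` with contiguous
#' 0-based frame indices. CSV dialect: one row per frame, columns
#' `frame, J2_x, J2_y, J2_z, ..., J14_z` (fps and space are not representable
#' in the CSV itself and are taken from the arguments).
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @param fps,space used for CSV input only (JSON carries both).
#' @return A [skeleton_sequence()].
#' @seealso [write_sequence()]
#' @export
read_sequence <- function(path, format = c("auto", "json", "csv"),
                          fps = 60, space = "camera") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (!file.exists(path)) ct_stop("parse_error", "file not found: %s", path)
  if (format == "json") read_sequence_json(path) else read_sequence_csv(path, fps, space)
}

read_sequence_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) ct_stop("parse_error", "malformed JSON in %s: %s",
                                              path, conditionMessage(e)))
  if (is.null(doc$frames) || length(doc$frames) == 0)
    ct_stop("parse_error", "no frames in %s", path)
  n <- length(doc$frames)
  pos <- array(NA_real_, c(n, 13, 3), dimnames = list(NULL, JOINT_IDS, c("x", "y", "z")))
  for (f in seq_len(n)) {
    fr <- doc$frames[[f]]
    idx <- fr$i %||% (f - 1)
    if (!identical(as.integer(idx), as.integer(f - 1)))
      ct_stop("parse_error", "frame indices not contiguous at record %d (i=%s)", f, idx)
    unknown <- setdiff(names(fr), c("i", JOINT_IDS, "confidence"))
    if (length(unknown) > 0)
      ct_stop("schema_error", "unknown joints in record %d: %s", f,
              paste(unknown, collapse = ", "))
    missing <- setdiff(JOINT_IDS, names(fr))
    if (length(missing) > 0)
      ct_stop("schema_error", "record %d missing joints: %s", f,
              paste(missing, collapse = ", "))
    for (j in JOINT_IDS) {
      v <- unlist(fr[[j]])
      if (length(v) != 3 || any(!is.finite(v)))
        ct_stop("parse_error", "record %d joint %s is not a finite 3-vector", f, j)
      pos[f, j, ] <- v
    }
  }
  skeleton_sequence(pos, fps = doc$fps %||% 60, space = doc$space %||% "camera")
}

read_sequence_csv <- function(path, fps, space) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) ct_stop("parse_error", "malformed CSV in %s", path))
  want <- as.vector(t(outer(JOINT_IDS, c("x", "y", "z"), paste, sep = "_")))
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols) > 0) {
    missing_joints <- unique(sub("_[xyz]$", "", missing_cols))
    ct_stop("schema_error", "CSV missing joints: %s", paste(missing_joints, collapse = ", "))
  }
  extra <- setdiff(names(df), c("frame", want))
  if (length(extra) > 0)
    ct_stop("schema_error", "unknown joints in CSV: %s", paste(extra, collapse = ", "))
  n <- nrow(df)
  pos <- array(NA_real_, c(n, 13, 3), dimnames = list(NULL, JOINT_IDS, c("x", "y", "z")))
  for (j in JOINT_IDS)
    for (k in c("x", "y", "z"))
      pos[, j, k] <- df[[paste(j, k, sep = "_")]]
  skeleton_sequence(pos, fps = fps, space = space)
}

#' Write a skeleton sequence to JSON or CSV
#'
#' Inverse of [read_sequence()]: a written file reads back with every
#' position preserved (up to float formatting, 15 significant digits).
#'
#' @param seq a [skeleton_sequence()].
#' @param path output path.
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @export
write_sequence <- function(seq, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    frames <- lapply(seq_len(length(seq)), function(f) {
      rec <- list(i = f - 1L)
      for (j in JOINT_IDS) rec[[j]] <- as.numeric(seq$positions[f, j, ])
      rec
    })
    jsonlite::write_json(list(fps = seq$fps, space = seq$space, frames = frames),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(frame = seq_len(length(seq)) - 1L)
    for (j in JOINT_IDS)
      for (k in c("x", "y", "z"))
        df[[paste(j, k, sep = "_")]] <- seq$positions[, j, k]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
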