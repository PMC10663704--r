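# Parser for the seven-column mammogram metadata table distributed with
# the mini-MIAS archive: reference id, background tissue, abnormality
# class, severity, (x, y) center and approximate radius in pixels.

MIAS_TISSUES <- c("F", "G", "D")
MIAS_CLASSES <- c("CALC", "CIRC", "SPIC", "MISC", "ARCH", "ASYM", "NORM")

#' Parse mammogram metadata records
#'
#' Accepts the whitespace-delimited text of the standard seven-column
#' metadata table. Lines carry 3 fields (normal cases) up to 7 fields
#' (abnormality with severity, center coordinates and radius); missing
#' trailing fields become `NA`.
#'
#' The `(x, y)` coordinates in the table use a bottom-left origin; they
#' are kept verbatim here and converted to matrix indices by
#' [mias_to_matrix_coords()].
#'
#' @param text character scalar (possibly multi-line) or vector of lines;
#'   alternatively a file path via `file`.
#' @param file optional path to a metadata file.
#' @return data.frame with columns `ref_id`, `tissue`, `class`,
#'   `severity`, `x`, `y`, `radius`.
#' @export
parse_mias_metadata <- function(text = NULL, file = NULL) {
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\\s+")[[1]]
    if (length(f) < 3 || length(f) > 7)
      stop("line ", i, ": expected 3-7 fields, got ", length(f))
    if (!f[2] %in% MIAS_TISSUES)
      stop("line ", i, ": unknown tissue character '", f[2], "'")
    if (!f[3] %in% MIAS_CLASSES)
      stop("line ", i, ": unknown abnormality class '", f[3], "'")
    sev <- if (length(f) >= 4) f[4] else NA_character_
    if (!is.na(sev) && !sev %in% c("B", "M"))
      stop("line ", i, ": unknown severity '", sev, "'")
    num <- function(j) if (length(f) >= j) suppressWarnings(as.numeric(f[j])) else NA_real_
    x <- num(5); y <- num(6); r <- num(7)
    if (f[3] == "NORM" && length(f) > 3)
      stop("line ", i, ": NORM records carry no severity or geometry")
    if (!is.na(r) && r <= 0)
      stop("line ", i, ": radius must be positive")
    recs[[i]] <- data.frame(ref_id = f[1], tissue = f[2], class = f[3],
                            severity = sev, x = x, y = y, radius = r,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' Convert bottom-left image coordinates to matrix indices
#'
#' The metadata table locates abnormalities in an `(x, y)` frame with the
#' origin at the bottom-left pixel and 0-based coordinates; internal
#' images are matrices with `[1, 1]` at the top-left. For an image of
#' `height` rows, `row = height - y` and `col = x + 1`.
#'
#' @param x,y numeric coordinates (0-based, bottom-left origin).
#' @param height image height in pixels.
#' @return data.frame with columns `row`, `col` (1-based, top-left origin).
#' @export
mias_to_matrix_coords <- function(x, y, height) {
  data.frame(row = height - y, col = x + 1)
}

#' @rdname mias_to_matrix_coords
#' @param row,col 1-based matrix indices.
#' @export
matrix_to_mias_coords <- function(row, col, height) {
  data.frame(x = col - 1, y = height - row)
}
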