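# PGM (portable graymap) reader/writer, P2 (ASCII) and P5 (binary) dialects.
# This is the distribution format of the classic mammogram archives.

# Tokenizer over a raw vector: skips whitespace and '#' comments, returns
# list(token, pos) with pos pointing just past the token's terminator.
pgm_next_token <- function(raw, pos) {
  n <- length(raw)
  ws <- as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  repeat {
    while (pos <= n && raw[pos] %in% ws) pos <- pos + 1L
    if (pos <= n && raw[pos] == as.raw(0x23)) {   # '#' comment to end of line
      while (pos <= n && !(raw[pos] %in% as.raw(c(0x0a, 0x0d)))) pos <- pos + 1L
    } else break
  }
  if (pos > n) stop("malformed PGM header: unexpected end of file")
  start <- pos
  while (pos <= n && !(raw[pos] %in% ws)) pos <- pos + 1L
  list(token = rawToChar(raw[start:(pos - 1L)]), pos = pos + 1L)
}

#' Read a PGM image
#'
#' Supports the P2 (ASCII) and P5 (binary) dialects with `maxval <= 255`.
#' Pixels are returned as an integer matrix in row-major order with the
#' top-left pixel at `[1, 1]`.
#'
#' @param path path to a `.pgm` file.
#' @return integer matrix of gray levels in `[0, 255]`.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", file.size(path))
  tk <- pgm_next_token(raw, 1L)
  magic <- tk$token
  if (!magic %in% c("P2", "P5"))
    stop("malformed PGM header: magic '", magic, "' (expected P2 or P5)")
  tk <- pgm_next_token(raw, tk$pos); width <- suppressWarnings(as.integer(tk$token))
  tk <- pgm_next_token(raw, tk$pos); height <- suppressWarnings(as.integer(tk$token))
  tk <- pgm_next_token(raw, tk$pos); maxval <- suppressWarnings(as.integer(tk$token))
  if (anyNA(c(width, height, maxval)) || width < 1 || height < 1)
    stop("malformed PGM header: non-numeric or non-positive dimensions")
  if (maxval > 255) stop("unsupported PGM depth: maxval ", maxval, " > 255")
  npix <- width * height
  if (magic == "P5") {
    if (length(raw) < tk$pos - 1L + npix - 1L + 1L)
      stop("malformed PGM: truncated pixel stream")
    vals <- as.integer(raw[tk$pos:(tk$pos + npix - 1L)])
  } else {
    txt <- rawToChar(raw[(tk$pos - 1L):length(raw)])
    txt <- gsub("#[^\n]*", " ", txt)
    vals <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1]]))
    if (length(vals) < npix || anyNA(vals[seq_len(npix)]))
      stop("malformed PGM: truncated pixel stream")
    vals <- vals[seq_len(npix)]
  }
  if (any(vals > maxval)) stop("malformed PGM: pixel exceeds maxval")
  matrix(vals, nrow = height, ncol = width, byrow = TRUE)
}

#' Write a PGM image
#'
#' @param image integer matrix of gray levels in `[0, 255]`.
#' @param path output file path.
#' @param ascii write the ASCII P2 dialect instead of binary P5.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, ascii = FALSE) {
  m <- round(image)
  if (anyNA(m) || min(m) < 0 || max(m) > 255)
    stop("image values must lie in [0, 255]")
  vals <- as.integer(t(m))    # row-major
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf("%s\n%d %d\n255\n", if (ascii) "P2" else "P5", ncol(m), nrow(m))
  writeBin(charToRaw(hdr), con)
  if (ascii) {
    body <- paste(vapply(split(vals, ceiling(seq_along(vals) / ncol(m))),
                         paste, character(1), collapse = " "),
                  collapse = "\n")
    writeBin(charToRaw(paste0(body, "\n")), con)
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}
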