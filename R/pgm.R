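# Portable Gray Map (PGM) input/output.  P2 (ASCII) and P5 (binary) are
# supported, with `#` comments anywhere in the header and 1- or 2-byte
# (big-endian) rasters; a mammogram is an integer pixel matrix
# (rows x cols, row 1 = top scanline) plus its maxval and reference id.

#' Construct a mammogram object
#'
#' @param pixels Integer matrix of intensities (rows x columns, top-left
#'   origin).
#' @param maxval Maximum representable intensity (default 255).
#' @param id Reference identifier.
#' @return A `mammogram` list with `pixels`, `maxval`, `id`.
#' @export
mammogram <- function(pixels, maxval = 255, id = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0) || any(pixels > maxval)) {
    stop("pixel intensities must lie in [0, maxval]", call. = FALSE)
  }
  structure(list(pixels = pixels, maxval = as.integer(maxval),
                 id = as.character(id)),
            class = "mammogram")
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram%s> %d x %d, maxval %d, intensity range [%d, %d]\n",
              if (nzchar(x$id)) paste0(" ", x$id) else "",
              nrow(x$pixels), ncol(x$pixels), x$maxval,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

pgm_error <- function(msg, offset) {
  stop(sprintf("malformed PGM at byte offset %d: %s", offset, msg),
       call. = FALSE)
}

# Tokenize the header: skip whitespace and '#' comments, returning the
# next `n` integer tokens and the offset just past them.
pgm_header_tokens <- function(bytes, start, n) {
  toks <- integer(0)
  i <- start
  len <- length(bytes)
  while (length(toks) < n) {
    while (i <= len) {
      ch <- bytes[i]
      if (ch %in% charToRaw(" \t\r\n")) {
        i <- i + 1
      } else if (ch == charToRaw("#")) {
        while (i <= len && bytes[i] != charToRaw("\n")) i <- i + 1
      } else {
        break
      }
    }
    if (i > len) pgm_error("truncated header", i - 1)
    j <- i
    while (j <= len && !(bytes[j] %in% charToRaw(" \t\r\n#"))) j <- j + 1
    tok <- rawToChar(bytes[i:(j - 1)])
    v <- suppressWarnings(as.integer(tok))
    if (is.na(v)) pgm_error(sprintf("expected integer, got '%s'", tok), i - 1)
    toks <- c(toks, v)
    i <- j
  }
  list(values = toks, offset = i)
}

#' Read and write PGM images
#'
#' `read_pgm()` parses a P2 (ASCII) or P5 (binary) Portable Gray Map;
#' `write_pgm()` emits P5 (or P2 on request).  A P5 round trip is
#' bit-exact.
#'
#' @param input File path or raw vector.
#' @param id Reference id to attach (defaults to the file base name).
#' @return A [mammogram()].
#' @export
read_pgm <- function(input, id = NULL) {
  bytes <- if (is.raw(input)) {
    input
  } else {
    readBin(input, "raw", n = file.info(input)$size)
  }
  if (is.null(id)) {
    id <- if (is.raw(input)) "" else sub("\\.pgm$", "", basename(input))
  }
  if (length(bytes) < 2) pgm_error("file too short", 0)
  magic <- rawToChar(bytes[1:2])
  if (!magic %in% c("P2", "P5")) {
    pgm_error(sprintf("unsupported magic '%s'", magic), 0)
  }
  hdr <- pgm_header_tokens(bytes, 3L, 3L)
  width <- hdr$values[1]; height <- hdr$values[2]; maxval <- hdr$values[3]
  if (width < 1 || height < 1) pgm_error("non-positive dimensions", 2)
  if (maxval < 1 || maxval > 65535) pgm_error("maxval out of range", 2)
  n <- width * height
  if (magic == "P5") {
    # exactly one whitespace byte separates maxval from the raster
    i <- hdr$offset + 1L
    bpp <- if (maxval > 255) 2L else 1L
    if (length(bytes) - i + 1L < n * bpp) {
      pgm_error("truncated raster", length(bytes))
    }
    raster <- bytes[i:(i + n * bpp - 1L)]
    vals <- if (bpp == 1L) {
      as.integer(raster)
    } else {
      as.integer(raster[c(TRUE, FALSE)]) * 256L +
        as.integer(raster[c(FALSE, TRUE)])
    }
  } else {
    toks <- pgm_header_tokens(bytes, hdr$offset, n)
    vals <- toks$values
  }
  if (any(vals > maxval)) pgm_error("pixel value exceeds maxval",
                                    hdr$offset)
  mammogram(matrix(vals, nrow = height, ncol = width, byrow = TRUE),
            maxval = maxval, id = id)
}

#' @rdname read_pgm
#' @param image A [mammogram()].
#' @param path Output file path, or `NULL` to return the raw bytes.
#' @param ascii Write P2 instead of P5.
#' @export
write_pgm <- function(image, path = NULL, ascii = FALSE) {
  stopifnot(inherits(image, "mammogram"))
  px <- image$pixels
  header <- sprintf("%s\n%d %d\n%d\n", if (ascii) "P2" else "P5",
                    ncol(px), nrow(px), image$maxval)
  vals <- as.integer(t(px))   # row-major scan order
  body <- if (ascii) {
    charToRaw(paste(c(paste(vals, collapse = " "), ""), collapse = "\n"))
  } else if (image$maxval > 255) {
    as.raw(as.vector(rbind(vals %/% 256L, vals %% 256L)))
  } else {
    as.raw(vals)
  }
  out <- c(charToRaw(header), body)
  if (is.null(path)) return(out)
  writeBin(out, path)
  invisible(path)
}
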