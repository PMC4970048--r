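#' Image input
#'
#' Reads 8-bit (or 16-bit) grayscale images as numeric matrices in [0, 1].
#' PNG and TIFF go through the png/tiff packages; PGM (both plain "P2" and
#' binary "P5") is parsed directly. Color inputs are converted to luminance
#' by channel averaging.
#'
#' @param path image file path (.png, .tif/.tiff, .pgm).
#' @return numeric matrix in [0, 1] (rows = image rows).
#' @export
read_grain_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = read_pgm(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  storage.mode(img) <- "double"
  if (max(img) > 1) img <- img / 255
  img
}

## minimal PGM reader (P2 ascii / P5 binary), maxval <= 65535
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  tokens <- character(0)
  while (length(tokens) < 3L) {
    line <- readLines(con, 1L)
    line <- sub("#.*", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1]])
    tokens <- tokens[nzchar(tokens)]
  }
  nc <- as.integer(tokens[1]); nr <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = nr * nc, quiet = TRUE)
  } else {
    bytes <- if (maxval < 256L) 1L else 2L
    raw <- readBin(con, "integer", n = nr * nc, size = bytes, signed = FALSE,
                   endian = "big")
    vals <- raw
  }
  matrix(vals, nr, nc, byrow = TRUE) / maxval
}

#' Write a matrix as a plain-text PGM image
#'
#' @param image numeric matrix in [0, 1].
#' @param path output path.
#' @param maxval quantization maximum (default 255).
#' @return the path, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  q <- image
  q[] <- round(pmin(pmax(image, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)), con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
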