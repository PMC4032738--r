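#' Read and write silhouettes as PGM or PNG
#'
#' Silhouettes travel between tools as 8-bit grayscale rasters with
#' object = 255, background = 0. PGM (both ASCII `P2` and binary `P5`) is
#' parsed directly; PNG goes through the \pkg{png} package. On read, any
#' pixel above half scale is taken as object.
#'
#' @param path File path; format chosen by extension (`.pgm`, `.png`).
#' @return `read_silhouette()`: a `"silhouette"` 0/1 matrix.
#'   `write_silhouette()`: `path`, invisibly.
#' @export
read_silhouette <- function(path) {
  if (!file.exists(path)) stop("raster not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(as_silhouette((img > 0.5) * 1L))
  }
  pgm <- read_pgm(path)
  as_silhouette((pgm$pixels > pgm$maxval / 2) * 1L)
}

#' @rdname read_silhouette
#' @param s A `"silhouette"` 0/1 matrix.
#' @export
write_silhouette <- function(s, path) {
  m <- unclass(s) * 255L
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m / 255, path)
  } else {
    write_pgm(m, path)
  }
  invisible(path)
}

# Plain parser for PGM P2 (ASCII) and P5 (8-bit binary); returns the pixel
# matrix (rows = image rows) and the declared maxval.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5")) stop("not a P2/P5 PGM file: ", path)
  toks <- character(0)
  buf <- ""
  while (length(toks) < 3) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (ch == "#") {                       # comment to end of line
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1))
        if (ch %in% c("\n", "\r")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { toks <- c(toks, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  dims <- as.integer(toks)
  w <- dims[1]; h <- dims[2]; maxval <- dims[3]
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- scan(con, integer(), n = n, quiet = TRUE)
  }
  list(pixels = matrix(vals, h, w, byrow = TRUE), maxval = maxval)
}

write_pgm <- function(m, path, maxval = 255L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
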