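# Raster input and output.  Intensities are held as doubles on the 8-bit
# [0, 255] scale regardless of the source bit depth; multi-channel rasters are
# reduced to a single channel by the channel average (luminance).

#' Read a grayscale raster image
#'
#' Reads PNG, TIFF or PGM rasters into a numeric intensity matrix on the
#' `[0, 255]` scale. Multi-channel inputs are reduced by averaging the
#' channels. PGM files may be plain (`P2`) or binary (`P5`), 8- or 16-bit;
#' 16-bit values are rescaled to `[0, 255]`.
#'
#' @param path file path; the format is chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.pgm`).
#' @return numeric matrix of intensities in `[0, 255]`.
#' @seealso [write_mask_png()], [write_membership_tiff()]
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path)
      # float TIFFs (membership maps) are stored as written; integer TIFFs
      # arrive normalised to [0, 1]
      if (max(x) <= 1 + 1e-9) x * 255 else x
    },
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  as_gray_image(img)
}

#' Coerce an array to a grayscale intensity matrix
#'
#' Averages the channels of a 3-d array (luminance average) and validates the
#' result as a finite numeric matrix.
#'
#' @param x numeric matrix or `height x width x channels` array.
#' @return numeric matrix.
#' @export
as_gray_image <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- apply(x, c(1, 2), mean)
  }
  check_gray_image(x)
  x
}

#' Write a binary mask as an 8-bit PNG
#'
#' Object pixels are written as 255, background as 0.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- (mask > 0.5) * 1
  png::writePNG(m, path)
  invisible(path)
}

#' Read a mask raster as a logical matrix
#'
#' @param path PNG/TIFF/PGM raster; any intensity above half scale is object.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  read_gray_image(path) > 127.5
}

#' Write a membership map as a 32-bit float TIFF
#'
#' Values are stored as single-precision floats, so a round trip is faithful
#' to about 1e-7 (float32 resolution). For bit-exact storage use
#' [write_matrix_csv()].
#'
#' @param membership numeric matrix in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_membership_tiff <- function(membership, path) {
  check_membership(membership)
  tiff::writeTIFF(membership, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a membership map written by [write_membership_tiff()]
#'
#' @param path float TIFF path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_membership_tiff <- function(path) {
  u <- tiff::readTIFF(path)
  check_membership(u)
  u
}

#' Exact text serialization of a numeric matrix
#'
#' Plain-text matrix storage (one row per line, comma separated, full
#' `%.17g` precision) that round-trips doubles bit-for-bit.
#'
#' @param x numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  stopifnot(is.matrix(x))
  lines <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
}

#' Read a PGM (portable graymap) image
#'
#' Supports plain (`P2`) and binary (`P5`) variants with maxval up to 65535.
#' Values are rescaled to the `[0, 255]` scale.
#'
#' @param path PGM file path.
#' @return numeric intensity matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok_state <- new.env(parent = emptyenv())
  next_token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") stop("unexpected end of PGM header")
      if (ch == "#") {  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (ch %in% c("\n", "") || length(ch) == 0L) break
        }
      } else if (!grepl("^[[:space:]]$", ch)) {
        tok <- ch
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || grepl("^[[:space:]]$", ch)) break
          tok <- paste0(tok, ch)
        }
        return(tok)
      }
    }
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  width <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  n <- width * height
  vals <- if (magic == "P2") {
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- as.numeric(next_token())
    out
  } else if (maxval < 256L) {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  } else {
    as.numeric(readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                       endian = "big"))
  }
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  m * (255 / maxval)
}

#' Write an intensity matrix as a plain-text PGM (P2)
#'
#' Values are rounded to integers and clipped to `[0, maxval]`. Integer-valued
#' matrices therefore round-trip exactly through [read_pgm()].
#'
#' @param image numeric matrix on the `[0, 255]` scale.
#' @param path output path.
#' @param maxval maximum gray value written in the header.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  check_gray_image(image)
  v <- pmin(pmax(round(image), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)), con)
  apply(v, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
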