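#' Image file I/O
#'
#' Supported formats: PNG (8- or 16-bit grayscale, via the `png` package)
#' and plain-text PGM (`P2`, handy for small text-only fixtures).
#' Multi-channel PNGs are converted to grayscale by the Rec. 601 luminance
#' weights. Intensities are kept on the native integer scale (0..255 for
#' 8-bit, 0..65535 for 16-bit).
#'
#' @param path file path; format chosen by extension (`.png`, `.pgm`).
#' @param spacing_mm pixel size to attach (PNG/PGM carry none); default 0.6.
#' @return [image2d()].
#' @export
load_image <- function(path, spacing_mm = 0.6) {
  if (!file.exists(path)) stop("load_image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path, info = TRUE)
    info <- attr(a, "info")
    bits <- if (is.null(info$bit.depth)) 8L else info$bit.depth
    scale <- 2^bits - 1
    if (length(dim(a)) == 3L) {
      ch <- dim(a)[3]
      a <- if (ch >= 3L) {
        0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
      } else a[, , 1]
    }
    image2d(round(a * scale), spacing_mm)
  } else if (ext == "pgm") {
    read_pgm(path, spacing_mm)
  } else {
    stop("load_image: unsupported format '.", ext, "' for ", path,
         " (use .png or .pgm)", call. = FALSE)
  }
}

#' @rdname load_image
#' @param image [image2d()] or matrix; values are clipped to the target
#'   bit range.
#' @param bits 8 or 16 (PNG only).
#' @export
save_image <- function(image, path, bits = 8L) {
  ext <- tolower(tools::file_ext(path))
  m <- as_plain_matrix(image)
  if (ext == "png") {
    if (bits != 8L) {
      # libpng via the png package only writes 8-bit; deep images go to PGM
      stop("save_image: PNG writing is 8-bit only; use a .pgm path for 16-bit",
           call. = FALSE)
    }
    png::writePNG(pmin(pmax(m, 0), 255) / 255, path)
  } else if (ext == "pgm") {
    write_pgm(image, path, maxval = as.integer(2^bits - 1))
  } else {
    stop("save_image: unsupported format '.", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Plain-text PGM (P2) read/write
#'
#' @param path file path.
#' @param spacing_mm pixel size to attach on read.
#' @export
read_pgm <- function(path, spacing_mm = 0.6) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("read_pgm: not an ASCII PGM (P2) file", call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("read_pgm: truncated pixel data", call. = FALSE)
  image2d(matrix(vals, nrow = h, ncol = w, byrow = TRUE), spacing_mm)
}

#' @rdname read_pgm
#' @param image image to write (values rounded, clipped at `maxval`).
#' @param maxval maximum gray value header field (default 255).
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  m <- round(pmin(pmax(as_plain_matrix(image), 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  apply(m, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Write / read a detection report
#'
#' JSON and CSV twins carry identical per-suspect records (id, centroid,
#' area, best scale, peak response, d1_mm, d2_mm, label) with a fixed
#' field order and 4-decimal floats.
#'
#' @param report a `detection_report` (or its `decisions` data.frame).
#' @param path output file.
#' @param format `"json"` or `"csv"`; default from the file extension.
#' @export
write_report <- function(report, path, format = NULL) {
  d <- if (inherits(report, "detection_report")) report$decisions else report
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(v) round(v, 4))
  if (format == "json") {
    jsonlite::write_json(d, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else if (format == "csv") {
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    stop("write_report: unknown format '", format, "'", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (format == "json") {
    jsonlite::fromJSON(path)
  } else if (format == "csv") {
    utils::read.csv(path)
  } else {
    stop("read_report: unknown format '", format, "'", call. = FALSE)
  }
}
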