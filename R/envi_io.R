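## ENVI-style cube I/O: a plain-text header (samples/lines/bands,
## interleave, data type, wavelength block) next to a flat binary file.
## No installed package in this stack reads the format, so the parser
## lives here. All three standard interleaves are accepted and converted
## to the canonical (line, pixel, band) order at read time.

.envi_types <- data.frame(
  code = c(1L, 2L, 3L, 4L, 5L, 12L, 13L),
  what = c("integer", "integer", "integer", "double", "double",
           "integer", "integer"),
  size = c(1L, 2L, 4L, 4L, 8L, 2L, 4L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
)

#' Read an ENVI-style hyperspectral cube
#'
#' Reads a header/binary pair and returns the cube in canonical
#' (line, pixel, band) order regardless of the stored interleave
#' (`bil`, `bip` or `bsq`). Integer raw counts are promoted to double.
#'
#' @param path Path to the header file (`.hdr`), or to the binary file if
#'   a sibling `.hdr` exists.
#' @param scan_id Scan identifier for the returned cube; defaults to the
#'   file stem.
#' @return A [hyper_cube()].
#' @export
read_cube <- function(path, scan_id = NULL) {
  paths <- envi_paths(path)
  if (!file.exists(paths$hdr))
    stop("ENVI header not found: ", paths$hdr, call. = FALSE)
  if (!file.exists(paths$bin))
    stop("ENVI binary not found: ", paths$bin, call. = FALSE)
  h <- parse_envi_header(paths$hdr)
  for (k in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(h[[k]]))
      stop("garbled ENVI header: missing field '", k, "'", call. = FALSE)
  ns <- as.integer(h$samples); nl <- as.integer(h$lines)
  nb <- as.integer(h$bands)
  wl <- as.numeric(h$wavelength)
  if (length(wl) == 0L)
    stop("garbled ENVI header: no wavelength block", call. = FALSE)
  if (length(wl) != nb)
    stop(sprintf("header declares %d bands but lists %d wavelengths",
                 nb, length(wl)), call. = FALSE)
  tp <- .envi_types[match(as.integer(h$`data type`), .envi_types$code), ]
  if (is.na(tp$code))
    stop("unsupported ENVI data type: ", h$`data type`, call. = FALSE)
  interleave <- tolower(h$interleave)
  if (!interleave %in% c("bil", "bip", "bsq"))
    stop("unsupported interleave: ", interleave, call. = FALSE)
  offset <- if (is.null(h$`header offset`)) 0L else
    as.integer(h$`header offset`)
  n <- ns * nl * nb
  expect_bytes <- offset + n * tp$size
  if (file.size(paths$bin) < expect_bytes)
    stop(sprintf("binary file truncated: %d bytes, expected >= %d",
                 file.size(paths$bin), expect_bytes), call. = FALSE)
  endian <- if (!is.null(h$`byte order`) && as.integer(h$`byte order`) == 1L)
    "big" else "little"
  con <- file(paths$bin, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", n = offset)
  raw <- readBin(con, tp$what, n = n, size = tp$size,
                 signed = tp$signed || tp$size > 2L, endian = endian)
  a <- switch(interleave,
    bsq = aperm(array(raw, dim = c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(raw, dim = c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(raw, dim = c(nb, ns, nl)), c(3L, 2L, 1L)))
  if (is.null(scan_id))
    scan_id <- sub("\\.hdr$", "", basename(paths$hdr))
  hyper_cube(a, wl, scan_id = scan_id)
}

#' Write an ENVI-style hyperspectral cube
#'
#' Writes a header/binary pair readable by [read_cube()]. The default
#' on-disk type is 32-bit float (camera-native data are integer counts,
#' but all downstream math is floating point); pass `data_type = 5` for
#' lossless 64-bit storage.
#'
#' @param cube A [hyper_cube()].
#' @param path Output path; `.hdr` is appended for the header and the
#'   binary carries no extension (or `.bin` stripped).
#' @param interleave One of `"bil"`, `"bip"`, `"bsq"`.
#' @param data_type ENVI data type code: 4 = float32 (default), 5 =
#'   float64, 12 = uint16, 2 = int16, 1 = uint8.
#' @return Invisibly, the header path.
#' @export
write_cube <- function(cube, path, interleave = "bil", data_type = 4L) {
  validate_cube(cube)
  interleave <- match.arg(tolower(interleave), c("bil", "bip", "bsq"))
  tp <- .envi_types[match(as.integer(data_type), .envi_types$code), ]
  if (is.na(tp$code))
    stop("unsupported ENVI data type: ", data_type, call. = FALSE)
  paths <- envi_paths(path)
  d <- dim(cube$values)
  a <- switch(interleave,  # inverse of the read-time permutation
    bsq = aperm(cube$values, c(2L, 1L, 3L)),
    bil = aperm(cube$values, c(2L, 3L, 1L)),
    bip = aperm(cube$values, c(3L, 2L, 1L)))
  hdr <- c(
    "ENVI",
    "description = {synthetic or processed reflectance cube}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", tp$code),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                  collapse = ", ")))
  writeLines(hdr, paths$hdr)
  vals <- as.vector(a)
  if (tp$what == "integer") vals <- as.integer(round(vals))
  con <- file(paths$bin, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = tp$size, endian = "little")
  invisible(paths$hdr)
}

envi_paths <- function(path) {
  if (grepl("\\.hdr$", path))
    bin <- sub("\\.hdr$", "", path)
  else {
    bin <- path
    path <- paste0(path, ".hdr")
  }
  list(hdr = path, bin = bin)
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*ENVI", txt))
    stop("not an ENVI header (missing ENVI magic): ", path, call. = FALSE)
  ## collapse newlines inside { ... } blocks, then split key = value
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "{") depth <- depth + 1L
    else if (chars[i] == "}") depth <- depth - 1L
    else if (chars[i] == "\n" && depth > 0L) chars[i] <- " "
  }
  lines <- strsplit(paste(chars, collapse = ""), "\n")[[1]]
  lines <- lines[grepl("=", lines)]
  h <- list()
  for (ln in lines) {
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl("^\\{", val)) {
      val <- gsub("[{}]", "", val)
      val <- trimws(strsplit(val, ",")[[1]])
    }
    h[[key]] <- val
  }
  h
}

#' Write an integer label image
#'
#' Stores a labeled mask (0 = background) as a 16-bit greyscale TIFF.
#'
#' @param labels Integer matrix, values in 0..65535.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_label_image <- function(labels, path) {
  if (any(labels < 0) || any(labels > 65535))
    stop("labels must be in 0..65535", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an integer label image written by [write_label_image()]
#'
#' @param path TIFF path.
#' @return Integer matrix of labels.
#' @export
read_label_image <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
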