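#' Cube header descriptions
#'
#' Raw cube files (`*.raw`, `*.dat`, `*.cube`) carry no self-description, so
#' each cube is paired with an ENVI-style sidecar text header (`<path>.hdr`)
#' holding its geometry and storage layout.  `cube_header()` builds the
#' in-memory form, used when reading a file whose sidecar is absent.
#'
#' The sidecar dialect is `key = value` with ENVI key names:
#' `samples` (N, columns), `lines` (M, rows), `bands` (I),
#' `data type` (1 = uint8, 4 = float32, 12 = uint16), `interleave`
#' (`bil` or `bsq`), `byte order` (0 = little, 1 = big),
#' `dynamic range` (bits, default 12) and `wavelength = { ... }` in
#' micrometres.
#'
#' In BIL (band-interleaved-by-line) layout the file stores, for each image
#' row in order, all bands of that row contiguously (band-major within the
#' row block); the element `(m, n, i)` (1-based) starts at byte offset
#' `(((m-1)*bands + (i-1))*samples + (n-1)) * bytes_per_element`.  BIL is the
#' canonical layout here — it is what permits reading the leading image rows
#' without touching the rest of the file — and BSQ (band-sequential) is
#' supported for interchange.
#'
#' @param lines,samples,bands positive integers: rows M, columns N, bands I.
#' @inheritParams hypercube
#' @return A list of class `"cube_header"`.
#' @export
cube_header <- function(lines, samples, bands, dtype = "uint16",
                        byte_order = "little", interleave = "bil",
                        wavelengths = NULL, bits = 12L) {
  lines <- as.integer(lines); samples <- as.integer(samples); bands <- as.integer(bands)
  if (any(c(lines, samples, bands) < 1L))
    stop("lines, samples and bands must all be >= 1")
  dtype <- match.arg(dtype, c("uint8", "uint16", "float32"))
  byte_order <- match.arg(byte_order, c("little", "big"))
  interleave <- match.arg(tolower(interleave), c("bil", "bsq"))
  bits <- as.integer(bits)
  if (bits < 8L || bits > 16L) stop("`bits` must lie in [8, 16]")
  if (is.null(wavelengths)) wavelengths <- seq(0.4, 1.0, length.out = bands)
  if (length(wavelengths) != bands)
    stop("`wavelengths` must have length `bands`")
  if (bands > 1L && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  structure(list(lines = lines, samples = samples, bands = bands,
                 dtype = dtype, byte_order = byte_order,
                 interleave = interleave,
                 wavelengths = as.numeric(wavelengths), bits = bits),
            class = "cube_header")
}

dtype_bytes <- function(dtype) {
  switch(dtype, uint8 = 1L, uint16 = 2L, float32 = 4L,
         stop("unknown dtype code: ", dtype))
}

dtype_envi_code <- function(dtype) {
  switch(dtype, uint8 = 1L, float32 = 4L, uint16 = 12L)
}

dtype_from_envi <- function(code) {
  switch(as.character(code), "1" = "uint8", "4" = "float32", "12" = "uint16",
         stop("unknown dtype code in header: data type = ", code))
}

header_path_for <- function(path) paste0(path, ".hdr")

#' Read and write sidecar headers
#'
#' @param path path of the header file itself (conventionally
#'   `<cube path>.hdr`).
#' @return `read_header()` returns a [cube_header()]; `write_header()`
#'   invisibly returns `path`.
#' @rdname cube_header
#' @export
read_header <- function(path) {
  if (!file.exists(path)) stop("header file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # brace-delimited list values may span lines: the `{[^}]*}` alternative
  # in the field pattern absorbs embedded newlines
  get_field <- function(key, required = TRUE) {
    pat <- paste0("(?mi)^\\s*", key, "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)")
    m <- regmatches(txt, regexpr(pat, txt, perl = TRUE))
    if (length(m) == 0L) {
      if (required) stop("header is missing required field `", key, "`: ", path)
      return(NULL)
    }
    val <- sub(paste0("(?mi)^\\s*", key, "\\s*=\\s*"), "", m, perl = TRUE)
    trimws(val)
  }
  parse_list <- function(s)
    as.numeric(strsplit(gsub("[{}\n]", "", s), ",")[[1]])
  wl <- get_field("wavelength", required = FALSE)
  cube_header(
    lines = as.integer(get_field("lines")),
    samples = as.integer(get_field("samples")),
    bands = as.integer(get_field("bands")),
    dtype = dtype_from_envi(get_field("data type")),
    byte_order = if (identical(get_field("byte order", FALSE) %||% "0", "1")) "big" else "little",
    interleave = get_field("interleave"),
    wavelengths = if (!is.null(wl)) parse_list(wl) else NULL,
    bits = as.integer(get_field("dynamic range", FALSE) %||% 12L))
}

#' @param header a [cube_header()].
#' @rdname cube_header
#' @export
write_header <- function(header, path) {
  stopifnot(inherits(header, "cube_header"))
  lines <- c(
    "ENVI",
    paste0("samples = ", header$samples),
    paste0("lines = ", header$lines),
    paste0("bands = ", header$bands),
    "header offset = 0",
    paste0("data type = ", dtype_envi_code(header$dtype)),
    paste0("interleave = ", header$interleave),
    paste0("byte order = ", if (header$byte_order == "big") 1L else 0L),
    paste0("dynamic range = ", header$bits),
    "wavelength units = Micrometers",
    paste0("wavelength = { ",
           paste(sprintf("%.6f", header$wavelengths), collapse = ", "), " }"))
  writeLines(lines, path)
  invisible(path)
}

read_elements <- function(con, n, dtype, byte_order) {
  endian <- if (byte_order == "big") "big" else "little"
  got <- switch(dtype,
    uint8   = readBin(con, "integer", n = n, size = 1L, signed = FALSE),
    uint16  = readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = endian),
    float32 = readBin(con, "numeric", n = n, size = 4L, endian = endian))
  as.numeric(got)
}

write_elements <- function(con, v, dtype, byte_order) {
  endian <- if (byte_order == "big") "big" else "little"
  switch(dtype,
    uint8 = {
      x <- as.integer(round(v))
      writeBin(as.raw(x), con)
    },
    uint16 = {
      x <- as.integer(round(v))
      x[x > 32767L] <- x[x > 32767L] - 65536L  # reinterpret as signed 16-bit
      writeBin(x, con, size = 2L, endian = endian)
    },
    float32 = writeBin(as.double(v), con, size = 4L, endian = endian))
  invisible(NULL)
}

#' Read a raw hyperspectral cube
#'
#' Reads a raw binary cube described by an ENVI-style sidecar header (see
#' [cube_header()] for the dialect and the BIL byte layout).
#'
#' @param path path of the raw cube file.
#' @param header a [cube_header()]; by default read from `<path>.hdr`.
#' @return A [hypercube()].
#' @seealso [read_partial_rows()] for the fast leading-rows read,
#'   [write_cube()] for the inverse.
#' @export
read_cube <- function(path, header = NULL) {
  if (is.null(header)) header <- read_header(header_path_for(path))
  stopifnot(inherits(header, "cube_header"))
  nelem <- header$lines * header$samples * header$bands
  expected <- as.numeric(nelem) * dtype_bytes(header$dtype)
  actual <- file.size(path)
  if (is.na(actual)) stop("cube file not found: ", path)
  if (actual != expected)
    stop(sprintf("cube file size mismatch: expected %.0f bytes (%d x %d x %d %s), found %.0f",
                 expected, header$lines, header$samples, header$bands,
                 header$dtype, actual))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- read_elements(con, nelem, header$dtype, header$byte_order)
  values <- assemble_cube(v, header, header$lines)
  hypercube(values, wavelengths = header$wavelengths, dtype = header$dtype,
            byte_order = header$byte_order, interleave = header$interleave,
            bits = header$bits)
}

# Reshape a flat element vector (file order) into values[m, n, i].
assemble_cube <- function(v, header, lines) {
  N <- header$samples; I <- header$bands
  if (header$interleave == "bil") {
    aperm(array(v, dim = c(N, I, lines)), c(3, 1, 2))
  } else {
    aperm(array(v, dim = c(N, lines, I)), c(2, 1, 3))
  }
}

#' Read only the leading rows of a BIL cube
#'
#' In BIL layout the first `row_count` image rows — each with its full
#' spectral range — occupy the first `row_count * samples * bands` elements
#' of the file, so a screening pass over the leading rows (the fast-path of
#' [ske_segment()]) reads exactly
#' `row_count * samples * bands * bytes_per_element` bytes and nothing more.
#'
#' @inheritParams read_cube
#' @param row_count number of leading rows to read, `1 <= row_count <= lines`.
#' @return A [hypercube()] of dimensions `(row_count, samples, bands)`, equal
#'   to the first `row_count` rows of the full cube.
#' @export
read_partial_rows <- function(path, row_count, header = NULL) {
  if (is.null(header)) header <- read_header(header_path_for(path))
  stopifnot(inherits(header, "cube_header"))
  if (header$interleave != "bil")
    stop("partial-row reads require BIL layout; a BSQ cube must be read in full")
  row_count <- as.integer(row_count)
  if (row_count < 1L || row_count > header$lines)
    stop("`row_count` must lie in [1, ", header$lines, "]")
  nelem <- row_count * header$samples * header$bands
  con <- file(path, "rb")
  on.exit(close(con))
  v <- read_elements(con, nelem, header$dtype, header$byte_order)
  if (length(v) < nelem)
    stop(sprintf("cube file truncated: expected at least %.0f bytes for %d rows",
                 as.numeric(nelem) * dtype_bytes(header$dtype), row_count))
  values <- assemble_cube(v, header, row_count)
  hypercube(values, wavelengths = header$wavelengths, dtype = header$dtype,
            byte_order = header$byte_order, interleave = header$interleave,
            bits = header$bits)
}

#' Write a raw hyperspectral cube
#'
#' Writes the raw binary file in the cube's interleave and byte order, plus
#' the ENVI-style sidecar header at `<path>.hdr`.  Byte-exact inverse of
#' [read_cube()] for the same header.
#'
#' @param cube a [hypercube()].
#' @param path destination path for the raw file.
#' @return Invisibly, `path`.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  header <- cube_header(lines = d[1], samples = d[2], bands = d[3],
                        dtype = cube$dtype, byte_order = cube$byte_order,
                        interleave = cube$interleave,
                        wavelengths = cube$wavelengths, bits = cube$bits)
  v <- if (cube$interleave == "bil") {
    aperm(cube$values, c(2, 3, 1))   # file order: n fastest, then i, then m
  } else {
    aperm(cube$values, c(2, 1, 3))   # file order: n, then m, then i
  }
  con <- file(path, "wb")
  tryCatch(write_elements(con, as.vector(v), cube$dtype, cube$byte_order),
           finally = close(con))
  write_header(header, header_path_for(path))
  invisible(path)
}

#' Read and write 2D label masks
#'
#' Masks round-trip through plain formats chosen by file extension:
#' `.csv` (arbitrary integer labels), `.pgm` (ASCII P2 or binary P5,
#' labels 0–255) or `.png` (labels 0–255, via the png package).  For PGM and
#' PNG a binary mask (values in `{0, 1}`) is scaled to `{0, 255}` on disk and
#' scaled back to `{0, 1}` when read; label maps with a maximum above 1 are
#' stored verbatim.
#'
#' @param mask integer matrix of labels (0 = background).
#' @param path file path ending in `.csv`, `.pgm` or `.png`.
#' @return `read_mask()` returns an integer matrix; `write_mask()` invisibly
#'   returns `path`.
#' @export
write_mask <- function(mask, path) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  if (min(mask) < 0) stop("mask labels must be non-negative")
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(mask, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else if (ext %in% c("pgm", "png")) {
    if (max(mask) > 255L)
      stop("label ", max(mask), " exceeds the 255 limit of ", toupper(ext),
           "; use CSV for wide label ranges")
    stored <- if (max(mask) <= 1L) mask * 255L else mask
    if (ext == "pgm") {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(c("P2", paste(ncol(stored), nrow(stored)), "255"), con)
      utils::write.table(stored, con, sep = " ", row.names = FALSE, col.names = FALSE)
    } else {
      png::writePNG(stored / 255, path)
    }
  } else stop("unsupported mask format: .", ext)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "csv") {
    as.matrix(utils::read.csv(path, header = FALSE))
  } else if (ext == "pgm") {
    read_pgm(path)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * 255)
  } else stop("unsupported mask format: .", ext)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  if (ext %in% c("pgm", "png") && all(m %in% c(0L, 255L))) m <- m %/% 255L
  m
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # header tokens: width height maxval (comments allowed)
  tokens <- integer(0)
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (ch == "#") { repeat { c2 <- rawToChar(readBin(con, "raw", 1L)); if (c2 == "\n") break } ; next }
    if (grepl("[0-9]", ch)) {
      num <- ch
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1L))
        if (grepl("[0-9]", c2)) num <- paste0(num, c2) else break
      }
      tokens <- c(tokens, as.integer(num))
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (maxval > 255L) stop("PGM maxval > 255 not supported")
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
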