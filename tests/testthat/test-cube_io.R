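test_that("cubes round-trip through every dtype/interleave/byte-order combination", {
  set.seed(42)
  grid <- expand.grid(dtype = c("uint8", "uint16", "float32"),
                      interleave = c("bil", "bsq"),
                      byte_order = c("little", "big"),
                      stringsAsFactors = FALSE)
  for (g in seq_len(nrow(grid))) {
    d <- c(sample(2:5, 1), sample(2:5, 1), sample(2:4, 1))
    vals <- if (grid$dtype[g] == "float32") {
      # snap to single precision so the round trip is bit-exact
      snap32 <- function(x)
        readBin(writeBin(as.double(x), raw(), size = 4L), "numeric",
                length(x), size = 4L)
      array(snap32(runif(prod(d))), d)
    } else {
      array(sample.int(2^8, prod(d)) - 1L, d)  # fits both integer widths
    }
    cube <- hypercube(vals, dtype = grid$dtype[g],
                      byte_order = grid$byte_order[g],
                      interleave = grid$interleave[g])
    path <- tempfile(fileext = ".raw")
    write_cube(cube, path)
    back <- read_cube(path)
    expect_identical(back$values, cube$values,
                     info = paste(grid[g, ], collapse = "/"))
    expect_identical(back$dtype, cube$dtype)
    unlink(c(path, paste0(path, ".hdr")))
  }
})

test_that("the same content reads identically from BIL and BSQ files", {
  set.seed(1)
  vals <- array(sample.int(4096, 3 * 4 * 5) - 1L, c(3, 4, 5))
  p_bil <- tempfile(fileext = ".raw"); p_bsq <- tempfile(fileext = ".raw")
  write_cube(hypercube(vals, interleave = "bil"), p_bil)
  write_cube(hypercube(vals, interleave = "bsq"), p_bsq)
  expect_identical(read_cube(p_bil)$values, read_cube(p_bsq)$values)
  expect_false(identical(readBin(p_bil, "raw", 120), readBin(p_bsq, "raw", 120)))
})

test_that("uint16 value 4095 is stored little-endian as 0xFF 0x0F", {
  cube <- hypercube(array(4095, c(1, 1, 1)), dtype = "uint16",
                    byte_order = "little")
  path <- tempfile(fileext = ".raw")
  write_cube(cube, path)
  expect_identical(readBin(path, "raw", 2), as.raw(c(0xFF, 0x0F)))
})

test_that("a truncated cube file raises a format error naming the byte counts", {
  set.seed(2)
  cube <- hypercube(array(sample.int(256, 24) - 1L, c(2, 3, 4)), dtype = "uint16")
  path <- tempfile(fileext = ".raw")
  write_cube(cube, path)
  full <- readBin(path, "raw", file.size(path))
  writeBin(full[-length(full)], path)
  expect_error(read_cube(path), "size mismatch.*expected 48 bytes.*found 47")
})

test_that("the BIL byte offset of element (m,n,i) follows the layout formula", {
  set.seed(3)
  d <- c(4, 5, 3)
  cube <- hypercube(array(sample.int(4096, prod(d)) - 1L, d), dtype = "uint16")
  path <- tempfile(fileext = ".raw")
  write_cube(cube, path)
  con <- file(path, "rb")
  on.exit(close(con))
  for (k in 1:10) {
    m <- sample(d[1], 1); n <- sample(d[2], 1); i <- sample(d[3], 1)
    # 0-based offset arithmetic on the raw stream
    offset <- (((m - 1) * d[3] + (i - 1)) * d[2] + (n - 1)) * 2
    seek(con, offset)
    expect_identical(readBin(con, "integer", 1, size = 2, signed = FALSE,
                             endian = "little"),
                     as.integer(cube$values[m, n, i]))
  }
})

test_that("partial-row reads equal the leading slice of a full read", {
  set.seed(4)
  d <- c(6, 5, 4)
  cube <- hypercube(array(sample.int(4096, prod(d)) - 1L, d), dtype = "uint16")
  path <- tempfile(fileext = ".raw")
  write_cube(cube, path)
  full <- read_cube(path)
  for (k in seq_len(d[1])) {
    part <- read_partial_rows(path, k)
    expect_identical(part$values, full$values[1:k, , , drop = FALSE])
  }
  expect_error(read_partial_rows(path, 0), "row_count")
  expect_error(read_partial_rows(path, d[1] + 1), "row_count")
})

test_that("partial-row reads touch exactly row_count*samples*bands elements", {
  set.seed(5)
  d <- c(6, 5, 4)
  cube <- hypercube(array(sample.int(4096, prod(d)) - 1L, d), dtype = "uint16")
  path <- tempfile(fileext = ".raw")
  write_cube(cube, path)
  # keep only the bytes of the first 2 rows: 2 * 5 * 4 * 2 bytes
  keep <- 2 * d[2] * d[3] * 2
  writeBin(readBin(path, "raw", keep), path)
  part <- read_partial_rows(path, 2, header = cube_header(d[1], d[2], d[3]))
  expect_identical(part$values, cube$values[1:2, , , drop = FALSE])
  # one element short of two rows must fail
  writeBin(readBin(path, "raw", keep - 2), path)
  expect_error(read_partial_rows(path, 2, header = cube_header(d[1], d[2], d[3])),
               "truncated")
})

test_that("partial-row reads refuse BSQ layout", {
  cube <- hypercube(array(0L, c(3, 3, 2)), interleave = "bsq")
  path <- tempfile(fileext = ".raw")
  write_cube(cube, path)
  expect_error(read_partial_rows(path, 1), "BIL")
})

test_that("sidecar headers round-trip including the wavelength axis", {
  h <- cube_header(696, 520, 8, dtype = "uint16", byte_order = "big",
                   interleave = "bsq", wavelengths = seq(0.4, 1.0, length.out = 8),
                   bits = 12)
  path <- tempfile(fileext = ".hdr")
  write_header(h, path)
  h2 <- read_header(path)
  expect_equal(h2$lines, 696L)
  expect_equal(h2$samples, 520L)
  expect_equal(h2$dtype, "uint16")
  expect_equal(h2$byte_order, "big")
  expect_equal(h2$interleave, "bsq")
  expect_equal(h2$wavelengths, h$wavelengths, tolerance = 1e-6)
})

test_that("masks round-trip through PGM, PNG and CSV with documented scaling", {
  set.seed(6)
  bin <- matrix(rbinom(30, 1, 0.5), 5, 6)
  p <- tempfile(fileext = ".pgm")
  write_mask(bin, p)
  expect_true(any(grepl("255", readLines(p))))   # stored as {0,255}
  expect_identical(read_mask(p), matrix(as.integer(bin), 5, 6))

  labs <- matrix(sample(0:3, 30, replace = TRUE), 5, 6)
  pc <- tempfile(fileext = ".csv")
  write_mask(labs, pc)
  expect_identical(read_mask(pc), matrix(as.integer(labs), 5, 6))

  pp <- tempfile(fileext = ".png")
  write_mask(labs, pp)
  expect_identical(read_mask(pp), matrix(as.integer(labs), 5, 6))

  expect_error(write_mask(matrix(300L, 2, 2), tempfile(fileext = ".pgm")),
               "255")
})

test_that("spectra round-trip through two-column CSV", {
  s <- ref_spectrum(c(0.2, 0.5, 0.3), c(0.4, 0.6, 0.8))
  path <- tempfile(fileext = ".csv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path)
  expect_equal(s2$values, s$values)
  expect_equal(s2$wavelengths, s$wavelengths)
})
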