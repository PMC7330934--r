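# Minimal baseline TIFF codec (8-bit, uncompressed, chunky planar layout).
# Covers the grey/RGB stills this pipeline exchanges; no external TIFF
# library is available in the target environment, and the subset below is
# byte-level trivial, so it is implemented here rather than pulled in.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L) # BYTE, ASCII, SHORT, LONG, RATIONAL

read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) io_error("not a TIFF file (too short): %s", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    io_error("not a TIFF file (bad byte order mark): %s", path)
  rd <- function(off, what, n, size) {
    readBin(raw[(off + 1L):length(raw)], what, n = n, size = size,
            endian = endian, signed = size >= 4L)
  }
  if (rd(2L, "integer", 1L, 2L) != 42L)
    io_error("not a TIFF file (bad magic): %s", path)
  ifd <- rd(4L, "integer", 1L, 4L)
  n_entries <- rd(ifd, "integer", 1L, 2L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- rd(off, "integer", 1L, 2L)
    type <- rd(off + 2L, "integer", 1L, 2L)
    cnt <- rd(off + 4L, "integer", 1L, 4L)
    size <- if (type >= 1L && type <= 5L) TIFF_TYPE_SIZES[type] else
      io_error("unsupported TIFF field type %d in %s", type, path)
    voff <- if (size * cnt > 4L) rd(off + 8L, "integer", 1L, 4L) else off + 8L
    vals <- switch(as.character(type),
      "3" = rd(voff, "integer", cnt, 2L),
      "4" = rd(voff, "integer", cnt, 4L),
      "1" = as.integer(rd(voff, "raw", cnt, 1L)),
      "5" = { # RATIONAL: numerator/denominator pairs
        v <- rd(voff, "integer", 2L * cnt, 4L)
        v[seq(1L, by = 2L, length.out = cnt)] /
          v[seq(2L, by = 2L, length.out = cnt)]
      },
      rd(voff, "integer", cnt, 1L))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) io_error("TIFF tag %d missing in %s", tag, path)
      default
    } else v
  }
  W <- need(256L); H <- need(257L)
  bits <- need(258L, 8L)
  if (any(bits != 8L)) io_error("only 8-bit TIFF supported: %s", path)
  if (need(259L, 1L) != 1L)
    io_error("only uncompressed TIFF supported: %s", path)
  spp <- need(277L, 1L)
  if (need(284L, 1L) != 1L)
    io_error("only chunky (PlanarConfiguration=1) TIFF supported: %s", path)
  offsets <- need(273L); counts <- need(279L)
  data <- raw(0)
  for (i in seq_along(offsets))
    data <- c(data, raw[(offsets[i] + 1L):(offsets[i] + counts[i])])
  if (length(data) != H * W * spp)
    io_error("TIFF pixel data has %d bytes, expected %d: %s",
             length(data), H * W * spp, path)
  arr <- array(as.integer(data), c(spp, W, H))
  arr <- aperm(arr, c(3L, 2L, 1L))
  if (spp == 1L) arr[, , 1L] else arr[, , 1:3, drop = FALSE]
}

write_tiff <- function(pixels, path) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  d <- dim(pixels)
  H <- d[1]; W <- d[2]; spp <- d[3]
  storage.mode(pixels) <- "integer"
  data <- as.raw(aperm(pixels, c(3L, 2L, 1L))) # interleaved raster order
  photometric <- if (spp == 3L) 2L else 1L

  entries <- list( # tag, type, count, values
    list(256L, 4L, 1L, W),
    list(257L, 4L, 1L, H),
    list(258L, 3L, spp, rep(8L, spp)),
    list(259L, 3L, 1L, 1L),
    list(262L, 3L, 1L, photometric),
    list(273L, 4L, 1L, 8L), # single strip right after the header
    list(277L, 3L, 1L, spp),
    list(278L, 4L, 1L, H),
    list(279L, 4L, 1L, length(data)),
    list(284L, 3L, 1L, 1L)
  )
  ifd_off <- 8L + length(data)
  extra_off <- ifd_off + 2L + 12L * length(entries) + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  writeBin(charToRaw("II"), con); wb(42L, 2L); wb(ifd_off, 4L)
  writeBin(data, con)
  wb(length(entries), 2L)
  extras <- list()
  for (e in entries) {
    wb(e[[1]], 2L); wb(e[[2]], 2L); wb(e[[3]], 4L)
    size <- TIFF_TYPE_SIZES[e[[2]]] * e[[3]]
    if (size > 4L) {
      wb(extra_off, 4L)
      extras[[length(extras) + 1L]] <- e
      extra_off <- extra_off + size
    } else if (e[[2]] == 3L) { # SHORT(s), left-justified in 4 bytes
      v <- c(e[[4]], rep(0L, 2L - e[[3]]))
      wb(v, 2L)
    } else {
      wb(e[[4]], 4L)
    }
  }
  wb(0L, 4L) # no next IFD
  for (e in extras) wb(e[[4]], TIFF_TYPE_SIZES[e[[2]]])
  invisible(path)
}
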