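# Minimal PNG codec for 8-bit grayscale (and RGB on read, converted by
# luminance weighting). No PNG library ships with this R stack, so the
# format is handled directly: zlib streams via memCompress/memDecompress,
# chunk CRCs via a table-driven CRC-32. Writing always emits color type 0,
# bit depth 8, filter 0; reading supports filters 0-4, color types 0 and 2,
# no interlacing, no 16-bit.

.crcEnv <- new.env(parent = emptyenv())

.crcTable <- function() {
  if (!is.null(.crcEnv$table)) return(.crcEnv$table)
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      # bitwShiftR is a logical (unsigned) shift; -306674912L is 0xEDB88320
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1L))
      else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  .crcEnv$table <- tab
  tab
}

.crc32 <- function(bytes) {
  tab <- .crcTable()
  c <- -1L  # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (b in v) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(bitwShiftR(c, 8L), tab[idx + 1L])
  }
  bitwXor(c, -1L)
}

.int32be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

.readInt32be <- function(r) {
  v <- as.integer(r)
  v[1L] * 16777216 + v[2L] * 65536 + v[3L] * 256 + v[4L]
}

.pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- .crc32(body)
  c(.int32be(length(data)), body, .int32be(crc))
}

.pngSignature <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

#' Read and write 8-bit grayscale PNG files
#'
#' \code{writeGrayPNG} stores an intensity matrix in \code{[0, 1]} as an
#' 8-bit grayscale PNG (\code{round(255 x)}). \code{readGrayPNG} reads 8-bit
#' grayscale or RGB PNGs (RGB is collapsed by Rec. 601 luminance
#' 0.299 R + 0.587 G + 0.114 B) and returns intensities in \code{[0, 1]}.
#' Interlaced, paletted and 16-bit files are rejected.
#'
#' @param mat numeric matrix of intensities in \code{[0, 1]}; rows are image
#'   rows.
#' @param path file path.
#' @return \code{writeGrayPNG}: the path, invisibly; \code{readGrayPNG}: an
#'   intensity matrix in \code{[0, 1]}.
#' @export
writeGrayPNG <- function(mat, path) {
  if (!is.matrix(mat) || any(!is.finite(mat)) || min(mat) < 0 || max(mat) > 1)
    stop("mat must be a finite matrix with values in [0, 1]", call. = FALSE)
  H <- nrow(mat); W <- ncol(mat)
  px <- matrix(as.raw(round(255 * t(mat))), W, H)  # column = one image row
  rows <- rbind(as.raw(0L), px)                    # filter byte 0 per row
  ihdr <- c(.int32be(W), .int32be(H),
            as.raw(c(8L, 0L, 0L, 0L, 0L)))
  idat <- memCompress(as.vector(rows), type = "gzip")
  out <- c(.pngSignature, .pngChunk("IHDR", ihdr), .pngChunk("IDAT", idat),
           .pngChunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

.paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

#' @rdname writeGrayPNG
#' @export
readGrayPNG <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 8L || !identical(r[1:8], .pngSignature))
    stop(path, ": not a PNG file", call. = FALSE)
  pos <- 9L
  idat <- list()
  ihdr <- NULL
  while (pos + 8L <= length(r)) {
    len <- .readInt32be(r[pos:(pos + 3L)])
    type <- rawToChar(r[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) r[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") ihdr <- data
    else if (type == "IDAT") idat[[length(idat) + 1L]] <- data
    else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(ihdr)) stop(path, ": missing IHDR", call. = FALSE)
  W <- .readInt32be(ihdr[1:4]); H <- .readInt32be(ihdr[5:8])
  bitDepth <- as.integer(ihdr[9L]); colorType <- as.integer(ihdr[10L])
  interlace <- as.integer(ihdr[13L])
  if (bitDepth != 8L)
    stop(path, ": only 8-bit PNGs are supported", call. = FALSE)
  if (!colorType %in% c(0L, 2L))
    stop(path, ": only grayscale or RGB PNGs are supported", call. = FALSE)
  if (interlace != 0L)
    stop(path, ": interlaced PNGs are not supported", call. = FALSE)
  channels <- if (colorType == 0L) 1L else 3L
  stride <- W * channels
  rawData <- memDecompress(do.call(c, idat), type = "gzip")
  if (length(rawData) != H * (stride + 1L))
    stop(path, ": corrupt image data", call. = FALSE)
  sc <- matrix(as.integer(rawData), stride + 1L, H)  # col = filter byte + row
  out <- matrix(0L, stride, H)
  prev <- integer(stride)
  left <- function(v) c(integer(channels), v[seq_len(stride - channels)])
  for (j in seq_len(H)) {
    f <- sc[1L, j]
    cur <- sc[-1L, j]
    cur <- switch(as.character(f),
      "0" = cur,
      "1" = { x <- integer(stride)
              for (i in seq_len(stride))
                x[i] <- (cur[i] + if (i > channels) x[i - channels] else 0L) %% 256L
              x },
      "2" = (cur + prev) %% 256L,
      "3" = { x <- integer(stride)
              for (i in seq_len(stride)) {
                a <- if (i > channels) x[i - channels] else 0L
                x[i] <- (cur[i] + (a + prev[i]) %/% 2L) %% 256L
              }
              x },
      "4" = { x <- integer(stride)
              for (i in seq_len(stride)) {
                a <- if (i > channels) x[i - channels] else 0L
                cc <- if (i > channels) prev[i - channels] else 0L
                x[i] <- (cur[i] + .paeth(a, prev[i], cc)) %% 256L
              }
              x },
      stop(path, ": unsupported filter type ", f, call. = FALSE))
    out[, j] <- cur
    prev <- cur
  }
  if (channels == 1L) {
    mat <- t(matrix(out, W, H)) / 255
  } else {
    rIdx <- seq(1L, stride, by = 3L)
    lum <- 0.299 * out[rIdx, , drop = FALSE] +
      0.587 * out[rIdx + 1L, , drop = FALSE] +
      0.114 * out[rIdx + 2L, , drop = FALSE]
    mat <- t(matrix(lum, W, H)) / 255
  }
  mat
}
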