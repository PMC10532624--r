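# Dataset I/O and preprocessing: load a directory of PNGs, resize bilinearly
# to the configured square size, scale into [0, 1]. No augmentation is ever
# applied. Writing quantises to 8 bits, so a save/load round trip agrees to
# within 1/255.

#' Bilinear resize of an intensity matrix
#'
#' Standard bilinear interpolation with pixel-centre alignment
#' (half-pixel convention); identity when the size is unchanged.
#'
#' @param mat numeric matrix.
#' @param newH,newW target dimensions.
#' @return resized matrix.
#' @export
resizeBilinear <- function(mat, newH, newW = newH) {
  H <- nrow(mat); W <- ncol(mat)
  if (H == newH && W == newW) return(mat)
  coord <- function(nOut, nIn) {
    c0 <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
    pmin(pmax(c0, 0), nIn - 1)
  }
  y <- coord(newH, H); x <- coord(newW, W)
  y0 <- pmin(floor(y), H - 2); x0 <- pmin(floor(x), W - 2)
  fy <- y - y0; fx <- x - x0
  a <- mat[cbind(rep(y0 + 1, newW), rep(x0 + 1, each = newH))]
  b <- mat[cbind(rep(y0 + 1, newW), rep(x0 + 2, each = newH))]
  cc <- mat[cbind(rep(y0 + 2, newW), rep(x0 + 1, each = newH))]
  d <- mat[cbind(rep(y0 + 2, newW), rep(x0 + 2, each = newH))]
  wfy <- rep(fy, newW); wfx <- rep(fx, each = newH)
  matrix(a * (1 - wfy) * (1 - wfx) + b * (1 - wfy) * wfx +
         cc * wfy * (1 - wfx) + d * wfy * wfx, newH, newW)
}

#' Load a directory of PNG images
#'
#' Reads every \code{.png} in the directory (sorted by name), resizes each
#' bilinearly to \code{imageSize} x \code{imageSize} and scales intensities
#' into \code{[0, 1]} (8-bit values divided by 255). RGB inputs are
#' collapsed to grayscale by luminance weighting. No augmentation.
#'
#' @param directory path containing readable 8-bit PNG files.
#' @param imageSize target square size in pixels.
#' @return an [ImageBatch-class] tagged with the source filenames.
#' @export
loadImages <- function(directory, imageSize = 256L) {
  if (!dir.exists(directory))
    stop("directory not found: ", directory, call. = FALSE)
  files <- sort(list.files(directory, pattern = "\\.png$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no PNG files in ", directory, call. = FALSE)
  imgs <- array(0, c(length(files), imageSize, imageSize))
  for (i in seq_along(files)) {
    mat <- tryCatch(readGrayPNG(files[i]), error = function(e)
      stop(sprintf("failed to read %s: %s", files[i], conditionMessage(e)),
           call. = FALSE))
    imgs[i, , ] <- resizeBilinear(mat, imageSize, imageSize)
  }
  ImageBatch(imgs, basename(files))
}

#' Save an image batch as PNG files
#'
#' Writes one 8-bit grayscale PNG per image, named
#' \code{prefix-0001.png, ...}, plus a \code{manifest.csv} with columns
#' \code{filename} and \code{source}.
#'
#' @param batch an [ImageBatch-class].
#' @param directory output directory (created if needed).
#' @param prefix filename prefix.
#' @return character vector of written image paths, invisibly.
#' @export
saveImages <- function(batch, directory, prefix = "image") {
  stopifnot(is(batch, "ImageBatch"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  n <- nImages(batch)
  paths <- file.path(directory, sprintf("%s-%04d.png", prefix, seq_len(n)))
  for (i in seq_len(n))
    writeGrayPNG(intensities(batch)[i, , ], paths[i])
  utils::write.csv(
    data.frame(filename = basename(paths), source = sourceTags(batch)),
    file.path(directory, "manifest.csv"), row.names = FALSE)
  invisible(paths)
}

#' Tile an image batch into a contact sheet
#'
#' Arranges the images on a grid with 2-pixel white gutters and writes the
#' result as a single 8-bit grayscale PNG.
#'
#' @param batch an [ImageBatch-class].
#' @param path output PNG path.
#' @param ncol images per row (default: ceiling of the square root).
#' @return the path, invisibly.
#' @export
writeContactSheet <- function(batch, path, ncol = NULL) {
  stopifnot(is(batch, "ImageBatch"))
  n <- nImages(batch)
  if (is.null(ncol)) ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  d <- dim(intensities(batch))
  S1 <- d[2L]; S2 <- d[3L]; gap <- 2L
  sheet <- matrix(1, nrow * S1 + (nrow - 1) * gap,
                  ncol * S2 + (ncol - 1) * gap)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol
    cl <- (i - 1) %% ncol
    sheet[r * (S1 + gap) + seq_len(S1), cl * (S2 + gap) + seq_len(S2)] <-
      intensities(batch)[i, , ]
  }
  writeGrayPNG(sheet, path)
}
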