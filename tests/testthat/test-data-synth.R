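# Synthetic phantoms, PNG codec and dataset I/O.

test_that("phantom generation is seeded and anatomically ordered", {
  cfg <- phantomConfig(imageSize = 32L, nImages = 6L, seed = 7L)
  b1 <- generatePhantoms(cfg)
  b2 <- generatePhantoms(cfg)
  expect_identical(intensities(b1), intensities(b2))  # bit-identical
  expect_equal(dim(intensities(b1)), c(6L, 32L, 32L))
  expect_true(all(intensities(b1) >= 0 & intensities(b1) <= 1))
  expect_lt(attr(b1, "clipFraction"), 0.01)
  expect_match(sourceTags(b1)[1], "phantom-seed7")

  # lung fields are brighter than their surroundings in every image
  bm <- generatePhantoms(phantomConfig(imageSize = 32L, nImages = 100L,
                                       seed = 8L), withMasks = TRUE)
  masks <- attr(bm, "masks")
  for (i in seq_len(100)) {
    img <- intensities(bm)[i, , ]
    expect_gt(mean(img[masks[i, , ]]), mean(img[!masks[i, , ]]))
  }
})

test_that("noiseless ribless phantoms are piecewise smooth", {
  # threshold calibrated once on the noiseless generator; the noisy default
  # sits an order of magnitude above it
  smooth <- generatePhantoms(phantomConfig(imageSize = 64L, nImages = 5L,
                                           seed = 1L, ribCount = 0L,
                                           noiseSD = 0))
  for (i in 1:5) {
    m <- intensities(smooth)[i, , ]
    expect_lt(differentialLoss(m, boxBlur3(m)), 5e-4)
  }
  noisy <- generatePhantoms(phantomConfig(imageSize = 64L, nImages = 5L,
                                          seed = 1L))
  m <- intensities(noisy)[1, , ]
  expect_gt(differentialLoss(m, boxBlur3(m)), 1e-3)
})

test_that("the PNG codec round-trips and agrees with an external reader", {
  withr::with_seed(2, m <- matrix(runif(28 * 19), 28, 19))
  f <- tempfile(fileext = ".png")
  writeGrayPNG(m, f)
  r <- readGrayPNG(f)
  expect_identical(dim(r), dim(m))
  expect_equal(r, round(m * 255) / 255, tolerance = 1e-12)
  expect_error(writeGrayPNG(m * 2, f), "\\[0, 1\\]")
  # cross-check the byte stream with Pillow (pre-installed python stack)
  py <- sprintf(
    "from PIL import Image; import numpy as np; a = np.array(Image.open(%s)); print(a.shape[0], a.shape[1], int(a.sum()))",
    shQuote(f))
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  expect_identical(out, sprintf("28 19 %d", sum(round(m * 255))))
  # read a Pillow-written grayscale PNG (exercises its filter heuristics)
  f2 <- tempfile(fileext = ".png")
  py2 <- sprintf(
    "from PIL import Image; import numpy as np; rng = np.random.default_rng(0); a = rng.integers(0, 256, (24, 31), dtype=np.uint8); Image.fromarray(a, mode='L').save(%s); print(int(a.sum()))",
    shQuote(f2))
  s <- system2("python", c("-c", shQuote(py2)), stdout = TRUE)
  expect_equal(sum(readGrayPNG(f2) * 255), as.numeric(s))
  # RGB input collapses by Rec. 601 luminance
  f3 <- tempfile(fileext = ".png")
  py3 <- sprintf(
    "from PIL import Image; import numpy as np; rng = np.random.default_rng(1); a = rng.integers(0, 256, (16, 19, 3), dtype=np.uint8); Image.fromarray(a).save(%s); print(float((0.299*a[:,:,0] + 0.587*a[:,:,1] + 0.114*a[:,:,2]).sum()))",
    shQuote(f3))
  s3 <- system2("python", c("-c", shQuote(py3)), stdout = TRUE)
  expect_equal(sum(readGrayPNG(f3) * 255), as.numeric(s3), tolerance = 1e-6)
  expect_error(readGrayPNG(tempfile(fileext = ".txt")), "not found")
  ftxt <- tempfile(fileext = ".txt")
  writeLines("not a png", ftxt)
  expect_error(readGrayPNG(ftxt), "not a PNG")
})

test_that("bilinear resize preserves constants, ranges and ramps", {
  expect_equal(resizeBilinear(matrix(1, 10, 10), 5), matrix(1, 5, 5))
  m <- matrix(seq(0, 1, length.out = 12), 12, 12)        # varies down rows
  r <- resizeBilinear(m, 6, 6)
  expect_true(all(diff(r[, 1]) > 0))                      # still monotone
  expect_true(all(apply(r, 1, function(x) max(abs(diff(x)))) < 1e-12))
  expect_true(min(r) >= 0 && max(r) <= 1)
  expect_identical(resizeBilinear(m, 12, 12), m)          # identity
})

test_that("image loading and saving round-trip within 8-bit quantisation", {
  dir <- file.path(tempdir(), "png-roundtrip")
  unlink(dir, recursive = TRUE)
  batch <- generatePhantoms(phantomConfig(imageSize = 24L, nImages = 3L,
                                          seed = 5L))
  paths <- saveImages(batch, dir)
  expect_length(paths, 3L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  re <- loadImages(dir, 24L)
  expect_equal(nImages(re), 3L)
  expect_lt(max(abs(intensities(re) - intensities(batch))), 1 / 255 / 2 + 1e-12)
  # reloading saved output is idempotent (already quantised)
  dir2 <- file.path(tempdir(), "png-roundtrip2")
  unlink(dir2, recursive = TRUE)
  saveImages(re, dir2)
  re2 <- loadImages(dir2, 24L)
  expect_identical(intensities(re2), intensities(re))
  # larger files are resized on load
  dir3 <- file.path(tempdir(), "png-resize")
  unlink(dir3, recursive = TRUE)
  dir.create(dir3)
  writeGrayPNG(matrix(1, 48, 48), file.path(dir3, "big.png"))
  got <- loadImages(dir3, 24L)
  expect_equal(dim(intensities(got)), c(1L, 24L, 24L))
  expect_equal(max(intensities(got)), 1)                  # uniform-255 -> 1.0
  # error contracts
  expect_error(loadImages(tempfile()), "not found")
  dirE <- file.path(tempdir(), "png-empty")
  dir.create(dirE, showWarnings = FALSE)
  expect_error(loadImages(dirE, 24L), "no PNG")
  dirC <- file.path(tempdir(), "png-corrupt")
  dir.create(dirC, showWarnings = FALSE)
  writeBin(as.raw(1:64), file.path(dirC, "bad.png"))
  expect_error(loadImages(dirC, 24L), "bad\\.png")
})

test_that("contact sheets tile batches with gutters", {
  batch <- generatePhantoms(phantomConfig(imageSize = 8L, nImages = 5L,
                                          seed = 6L))
  f <- tempfile(fileext = ".png")
  writeContactSheet(batch, f, ncol = 3L)
  sheet <- readGrayPNG(f)
  expect_identical(dim(sheet), c(2L * 8L + 2L, 3L * 8L + 2L * 2L))
})
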