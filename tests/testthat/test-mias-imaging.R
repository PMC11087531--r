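test_that("PGM parsing handles ASCII, binary, comments and errors", {
  p2 <- read_pgm(charToRaw("P2 2 2 255 0 1 2 3"))
  expect_equal(p2$pixels, matrix(c(0L, 2L, 1L, 3L), 2, 2))
  expect_equal(p2$maxval, 255L)
  withcomment <- read_pgm(charToRaw("P2\n# a comment\n2 1\n255\n7 9\n"))
  expect_equal(as.vector(withcomment$pixels), c(7L, 9L))
  expect_error(read_pgm(charToRaw("P7 2 2 255 0 0 0 0")), "magic")
  expect_error(read_pgm(charToRaw("P2 2 2")), "truncated")
  expect_error(read_pgm(charToRaw("P5 2 2 255 ")), "truncated raster")
})

test_that("P5 round trips are bit-exact, including 16-bit rasters", {
  img <- qibgwo:::with_seed(26, {
    mammogram(matrix(sample(0:255, 16 * 16, TRUE), 16, 16), id = "rt")
  })
  raw <- write_pgm(img)
  back <- read_pgm(raw)
  expect_identical(back$pixels, img$pixels)
  expect_identical(write_pgm(back), raw)
  img16 <- mammogram(matrix(c(0L, 300L, 65535L, 12L), 2, 2),
                     maxval = 65535)
  expect_identical(read_pgm(write_pgm(img16))$pixels, img16$pixels)
  # ASCII writer round trip
  expect_identical(read_pgm(write_pgm(img, ascii = TRUE))$pixels,
                   img$pixels)
})

test_that("MIAS annotation parsing converts coordinates and validates", {
  a <- parse_mias_annotations(c("mdb001 G CIRC B 535 425 197",
                                "mdb003 D NORM"), image_height = 1024)
  expect_equal(nrow(a), 2)
  expect_equal(a$severity[1], "benign")
  expect_equal(a$abnormality[2], "NORM")
  expect_true(is.na(a$x[2]) && is.na(a$radius[2]))
  expect_equal(a$col[1], 535)
  expect_equal(a$row[1], 1024 - 425)
  expect_equal(nrow(parse_mias_annotations(character(0))), 0)
  expect_error(parse_mias_annotations("mdb001 G BLOB B 1 2 3"),
               "line 1.*abnormality")
  expect_error(parse_mias_annotations("mdb001 Q CIRC B 1 2 3"),
               "tissue")
  expect_error(parse_mias_annotations("mdb001 G CIRC B 1"), "severity")
  # write/parse round trip
  expect_equal(parse_mias_annotations(write_mias_annotations(a), 1024), a)
})

test_that("median filtering removes impulses and fixes constants", {
  const <- mammogram(matrix(40L, 12, 12))
  expect_identical(median_filter(const, 3)$pixels, const$pixels)
  expect_identical(median_filter(const, 1)$pixels, const$pixels)
  imp <- matrix(0L, 9, 9); imp[5, 5] <- 255L
  filtered <- median_filter(mammogram(imp), 3)
  expect_equal(filtered$pixels[5, 5], 0L)
  expect_error(median_filter(const, 4), "odd")
})

test_that("CLAHE preserves range, constants and level ordering", {
  const <- clahe(mammogram(matrix(100L, 64, 64)))
  expect_equal(length(unique(as.vector(const$pixels))), 1)
  img <- qibgwo:::with_seed(27, {
    mammogram(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
  })
  out <- clahe(img, clip_limit = 2, tile_grid = c(8, 8))
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
  expect_equal(dim(out$pixels), dim(img$pixels))
  # two-level image keeps the ordering of its levels
  two <- matrix(60L, 64, 64); two[1:32, 1:32] <- 20L
  e <- clahe(mammogram(two), tile_grid = c(4, 4))
  expect_lt(mean(e$pixels[1:32, 1:32]), mean(e$pixels[33:64, 33:64]))
  expect_error(clahe(img, clip_limit = 0), "clip_limit")
})

test_that("ROI extraction is centred, border-shifted and full-size", {
  img <- mammogram(matrix(seq_len(200 * 200) %% 256, 200, 200))
  roi <- extract_roi(img, c(100, 100), size = 120)
  expect_equal(dim(roi$pixels), c(120, 120))
  expect_equal(roi$pixels, img$pixels[40:159, 40:159])
  # odd window: exactly symmetric about the centre
  roi3 <- extract_roi(img, c(100, 100), size = 5)
  expect_equal(roi3$pixels, img$pixels[98:102, 98:102])
  # near-corner centre: window flush with the border, still full size
  corner <- extract_roi(img, c(10, 10), size = 120)
  expect_equal(dim(corner$pixels), c(120, 120))
  expect_equal(corner$pixels, img$pixels[1:120, 1:120])
  expect_error(extract_roi(img, c(500, 10), 120), "outside")
  expect_error(extract_roi(img, c(100, 100), 300), "larger than")
})

test_that("random normal regions stay inside the breast foreground", {
  ph <- make_phantom("normal", tiny_phantom_spec(), seed = 31, id = "t1")
  mask <- qibgwo:::breast_mask(ph$image)
  hits <- vapply(1:50, function(s) {
    roi <- random_normal_roi(ph$image, size = 40, seed = s)
    expect_equal(dim(roi$pixels), c(40, 40))
    mask[roi$center[1], roi$center[2]]
  }, logical(1))
  expect_true(all(hits))
  r1 <- random_normal_roi(ph$image, 40, seed = 9)
  r2 <- random_normal_roi(ph$image, 40, seed = 9)
  expect_identical(r1$pixels, r2$pixels)
})

test_that("corpus preprocessing conserves counts and sizes", {
  spec <- phantom_spec(counts = c(normal = 4, benign = 2, malignant = 2),
                       image_size = 160, seed = 32)
  corp <- make_mias_like_corpus(spec)
  pc <- preprocess_corpus(corp$images, corp$annotations, roi_size = 100,
                          patch_size = 72, seed = 32)
  expect_length(pc$rois, 8)
  expect_length(pc$patches, 8)
  expect_equal(as.integer(table(pc$manifest$label)[c("normal", "benign",
                                                     "malignant")]),
               c(4L, 2L, 2L))
  for (p in pc$patches) expect_equal(dim(p$pixels), c(72, 72))
  for (r in pc$rois) expect_equal(dim(r$pixels), c(100, 100))
  # abnormal regions are centred on the annotated location
  ab <- which(corp$annotations$abnormality != "NORM")[1]
  expect_equal(pc$rois[[ab]]$center,
               c(corp$annotations$row[ab], corp$annotations$col[ab]))
  # determinism of the full chain
  pc2 <- preprocess_corpus(corp$images, corp$annotations, roi_size = 100,
                           patch_size = 72, seed = 32)
  expect_identical(pc$patches[[1]]$pixels, pc2$patches[[1]]$pixels)
  expect_error(
    preprocess_corpus(corp$images[-1], corp$annotations, seed = 1),
    "missing images")
})

test_that("a corpus directory of PGM files is read back transparently", {
  spec <- phantom_spec(counts = c(normal = 1, benign = 1, malignant = 0),
                       image_size = 160, seed = 33)
  corp <- make_mias_like_corpus(spec)
  dir <- file.path(tempdir(), "miascorp")
  dir.create(dir, showWarnings = FALSE)
  for (id in names(corp$images)) {
    write_pgm(corp$images[[id]], file.path(dir, paste0(id, ".pgm")))
  }
  annfile <- file.path(dir, "ann.txt")
  write_mias_annotations(corp$annotations, annfile)
  pc <- preprocess_corpus(dir, annfile, roi_size = 80, patch_size = 48,
                          seed = 33)
  expect_length(pc$patches, 2)
  unlink(dir, recursive = TRUE)
})
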