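# MIAS-style annotation parsing and the mammogram preprocessing chain:
# median filter -> CLAHE -> region-of-interest crop -> patch extraction.

mias_tissues <- c(F = "fatty", G = "fatty-glandular", D = "dense-glandular")
mias_classes <- c("CALC", "CIRC", "SPIC", "MISC", "ARCH", "ASYM", "NORM")

#' Parse a MIAS-format annotation file
#'
#' Rows are whitespace-delimited: `reference tissue abnormality
#' [severity x y radius]`.  `NORM` rows carry no severity or location.
#' Annotation coordinates use the dataset's bottom-left origin; they are
#' converted to top-left row/column on parse with
#' `row = image_height - y` and `col = x` (1-based matrix indices).
#'
#' @param input File path or character vector of lines.
#' @param image_height Height in pixels of the referenced images
#'   (default 1024), used for the origin conversion.
#' @return A data frame with columns `reference`, `tissue`,
#'   `abnormality`, `severity` (`"benign"`, `"malignant"` or `NA`),
#'   `x`, `y` (original bottom-left coordinates, `NA` for normals),
#'   `radius`, `row`, `col` (converted top-left indices).
#' @export
parse_mias_annotations <- function(input, image_height = 1024) {
  lines <- if (length(input) == 1 && file.exists(input)) {
    readLines(input)
  } else {
    input
  }
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  rows <- lapply(which(keep), function(ln) {
    f <- strsplit(lines[ln], "\\s+")[[1]]
    if (length(f) < 3) {
      stop(sprintf("annotation line %d: expected at least 3 fields", ln),
           call. = FALSE)
    }
    if (!f[2] %in% names(mias_tissues)) {
      stop(sprintf("annotation line %d: unknown tissue code '%s'", ln, f[2]),
           call. = FALSE)
    }
    if (!f[3] %in% mias_classes) {
      stop(sprintf("annotation line %d: unknown abnormality code '%s'",
                   ln, f[3]), call. = FALSE)
    }
    if (f[3] == "NORM") {
      data.frame(reference = f[1], tissue = unname(mias_tissues[f[2]]),
                 abnormality = f[3], severity = NA_character_,
                 x = NA_real_, y = NA_real_, radius = NA_real_)
    } else {
      if (length(f) < 7) {
        stop(sprintf(
          "annotation line %d: abnormal record needs severity, x, y, radius",
          ln), call. = FALSE)
      }
      sev <- c(B = "benign", M = "malignant")[f[4]]
      if (is.na(sev)) {
        stop(sprintf("annotation line %d: unknown severity '%s'", ln, f[4]),
             call. = FALSE)
      }
      data.frame(reference = f[1], tissue = unname(mias_tissues[f[2]]),
                 abnormality = f[3], severity = unname(sev),
                 x = as.numeric(f[5]), y = as.numeric(f[6]),
                 radius = as.numeric(f[7]))
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(reference = character(), tissue = character(),
                      abnormality = character(), severity = character(),
                      x = numeric(), y = numeric(), radius = numeric())
  }
  out$row <- image_height - out$y
  out$col <- out$x
  out
}

#' Write MIAS-format annotation lines
#'
#' Inverse of [parse_mias_annotations()] (round-trips exactly).
#'
#' @param annotations Data frame as returned by
#'   [parse_mias_annotations()].
#' @param path Optional output file.
#' @return The character vector of lines (invisibly when written).
#' @export
write_mias_annotations <- function(annotations, path = NULL) {
  tiss <- names(mias_tissues)[match(annotations$tissue, mias_tissues)]
  lines <- vapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    if (a$abnormality == "NORM") {
      paste(a$reference, tiss[i], "NORM")
    } else {
      paste(a$reference, tiss[i], a$abnormality,
            c(benign = "B", malignant = "M")[a$severity],
            format(a$x, trim = TRUE), format(a$y, trim = TRUE),
            format(a$radius, trim = TRUE))
    }
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

to_unit <- function(image) image$pixels / image$maxval

from_unit <- function(u, image) {
  px <- round(pmin(pmax(u, 0), 1) * image$maxval)
  mammogram(px, maxval = image$maxval, id = image$id)
}

#' Median filter a mammogram
#'
#' Replaces each pixel by the median of its square window (window 1 is the
#' identity); delegated to the constant-time median filter in EBImage.
#'
#' @param image A [mammogram()].
#' @param window Odd window size (default 3).
#' @return The filtered [mammogram()].
#' @export
median_filter <- function(image, window = 3) {
  stopifnot(inherits(image, "mammogram"))
  if (window %% 2 != 1 || window < 1) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  if (window == 1) return(image)
  u <- EBImage::medianFilter(to_unit(image), size = (window - 1) / 2)
  from_unit(u, image)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Per-tile histogram equalization with a clip limit, delegated to
#' EBImage; output intensities stay within the image's representable
#' range and a constant image maps to a constant image.
#'
#' @param image A [mammogram()].
#' @param clip_limit Positive contrast clip limit (default 2).
#' @param tile_grid Integer pair `(rows, cols)` of tiles (default 8 x 8).
#' @return The equalized [mammogram()].
#' @export
clahe <- function(image, clip_limit = 2, tile_grid = c(8, 8)) {
  stopifnot(inherits(image, "mammogram"))
  if (!is_scalar_number(clip_limit) || clip_limit <= 0) {
    stop("`clip_limit` must be positive", call. = FALSE)
  }
  # EBImage's first image dimension corresponds to the matrix rows here
  u <- EBImage::clahe(to_unit(image), nx = tile_grid[1], ny = tile_grid[2],
                      limit = clip_limit)
  from_unit(u, image)
}

# Clamp a window of length `size` centred at `c` into [1, n]:
# shifted (not padded) so the output window is always full size.
window_range <- function(c, size, n) {
  half <- floor(size / 2)
  start <- round(c) - half
  start <- min(max(start, 1), n - size + 1)
  start:(start + size - 1)
}

#' Extract a fixed-size region of interest
#'
#' Crops a `size x size` window centred at `center`; windows within
#' `size / 2` of a border are shifted inside (never padded) so the output
#' always has the full size.
#'
#' @param image A [mammogram()].
#' @param center `(row, col)` pair in top-left matrix coordinates (as
#'   produced by [parse_mias_annotations()]).
#' @param size Window side in pixels (default 120).
#' @param label Optional class label to attach.
#' @return A `roi_patch`: list with `pixels`, `maxval`, `label`, `source`
#'   (image id) and `center`.
#' @export
extract_roi <- function(image, center, size = 120, label = NA_character_) {
  stopifnot(inherits(image, "mammogram"))
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc) {
    stop(sprintf("center (%g, %g) outside the %d x %d image",
                 center[1], center[2], nr, nc), call. = FALSE)
  }
  if (size > nr || size > nc) {
    stop("requested window larger than the image", call. = FALSE)
  }
  px <- image$pixels[window_range(center[1], size, nr),
                     window_range(center[2], size, nc), drop = FALSE]
  structure(list(pixels = px, maxval = image$maxval, label = label,
                 source = image$id, center = center),
            class = "roi_patch")
}

#' @export
print.roi_patch <- function(x, ...) {
  cat(sprintf("<roi_patch> %d x %d from %s at (%g, %g), label %s\n",
              nrow(x$pixels), ncol(x$pixels), x$source,
              x$center[1], x$center[2], x$label))
  invisible(x)
}

# Breast-region foreground: Otsu threshold on the median-filtered image,
# then the largest connected foreground component.
breast_mask <- function(image) {
  u <- to_unit(median_filter(image, 3))
  thr <- EBImage::otsu(EBImage::Image(u))
  bw <- EBImage::bwlabel(u > thr)
  if (max(bw) == 0) return(matrix(TRUE, nrow(u), ncol(u)))
  sizes <- tabulate(as.integer(bw[bw > 0]))
  bw == which.max(sizes)
}

#' Random region of interest inside the breast region
#'
#' Draws a uniformly random full-size window whose centre lies on the
#' breast-containing foreground (Otsu threshold, largest connected
#' component); used to sample regions from images with no annotated
#' location.
#'
#' @inheritParams extract_roi
#' @param seed Integer seed.
#' @return A `roi_patch` labelled `"normal"` by default.
#' @export
random_normal_roi <- function(image, size = 120, seed = 1,
                              label = "normal") {
  stopifnot(inherits(image, "mammogram"))
  mask <- breast_mask(image)
  idx <- which(mask, arr.ind = TRUE)
  with_seed(seed, {
    pick <- idx[sample.int(nrow(idx), 1), ]
    extract_roi(image, c(pick[1], pick[2]), size, label = label)
  })
}

#' Preprocess a MIAS-style corpus into labelled patches
#'
#' Runs the full chain per image: median filter, CLAHE, then one
#' `roi_size` region per annotation record (centred on the annotated
#' location for abnormal records; random within the breast region for
#' normals) and `patches_per_roi` random `patch_size` patches per region.
#'
#' @param images Named list of [mammogram()] objects (names = reference
#'   ids) or a directory of `.pgm` files.
#' @param annotations Annotation data frame
#'   ([parse_mias_annotations()]) or file path.
#' @param roi_size,patch_size Window sides in pixels (defaults 120, 72).
#' @param patches_per_roi Patches extracted per region (default 1).
#' @param window,clip_limit,tile_grid Filter/CLAHE settings.
#' @param seed Integer seed driving the random region and patch draws.
#' @return A `roi_corpus`: list with `rois`, `patches` (lists of
#'   `roi_patch`) and `manifest` (data frame: patch filename stub, label,
#'   source, centre).
#' @export
preprocess_corpus <- function(images, annotations, roi_size = 120,
                              patch_size = 72, patches_per_roi = 1,
                              window = 3, clip_limit = 2,
                              tile_grid = c(8, 8), seed = 1) {
  if (is.character(images) && length(images) == 1) {
    files <- list.files(images, pattern = "\\.pgm$", full.names = TRUE)
    images <- lapply(files, read_pgm)
    names(images) <- vapply(images, `[[`, character(1), "id")
  }
  if (is.character(annotations)) {
    h <- nrow(images[[1]]$pixels)
    annotations <- parse_mias_annotations(annotations, image_height = h)
  }
  missing <- setdiff(annotations$reference, names(images))
  if (length(missing)) {
    stop(sprintf("annotation references missing images: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rois <- list(); patches <- list(); manifest <- list()
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    img <- images[[a$reference]]
    img <- clahe(median_filter(img, window), clip_limit, tile_grid)
    label <- if (a$abnormality == "NORM") "normal" else a$severity
    roi <- if (a$abnormality == "NORM") {
      random_normal_roi(img, roi_size, seed = derive_seed(seed, i),
                        label = label)
    } else {
      extract_roi(img, c(a$row, a$col), roi_size, label = label)
    }
    rois[[i]] <- roi
    with_seed(derive_seed(seed, 10000 + i), {
      for (p in seq_len(patches_per_roi)) {
        r0 <- sample.int(roi_size - patch_size + 1, 1)
        c0 <- sample.int(roi_size - patch_size + 1, 1)
        patch <- structure(list(
          pixels = roi$pixels[r0:(r0 + patch_size - 1),
                              c0:(c0 + patch_size - 1), drop = FALSE],
          maxval = roi$maxval, label = label, source = a$reference,
          center = roi$center), class = "roi_patch")
        patches[[length(patches) + 1]] <- patch
        manifest[[length(manifest) + 1]] <- data.frame(
          filename = sprintf("%s_patch%02d.pgm", a$reference, p),
          label = label, source = a$reference,
          center_row = roi$center[1], center_col = roi$center[2])
      }
    })
  }
  structure(list(rois = rois, patches = patches,
                 manifest = do.call(rbind, manifest)),
            class = "roi_corpus")
}

#' @export
print.roi_corpus <- function(x, ...) {
  cat(sprintf("<roi_corpus> %d regions, %d patches\n",
              length(x$rois), length(x$patches)))
  print(table(x$manifest$label))
  invisible(x)
}

#' Flatten patches into an intensity feature table
#'
#' Each patch becomes one row of intensities scaled to `[0, 1]`; the
#' label column is taken from the patches.
#'
#' @param corpus A `roi_corpus` from [preprocess_corpus()], or a list of
#'   `roi_patch` objects.
#' @return A list with feature matrix `x` and label factor `y`.
#' @export
patches_to_features <- function(corpus) {
  patches <- if (inherits(corpus, "roi_corpus")) corpus$patches else corpus
  x <- t(vapply(patches, function(p) as.numeric(p$pixels) / p$maxval,
                numeric(length(patches[[1]]$pixels))))
  y <- factor(vapply(patches, `[[`, character(1), "label"))
  list(x = x, y = y)
}
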