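# Synthetic data: stylized mammogram phantoms with a MIAS-like corpus
# layout, and class-conditional Gaussian feature tables with a known
# informative subset.  Every generator is a pure function of (spec, seed).

#' Specification of a phantom mammogram corpus
#'
#' @param counts Named integer vector `(normal, benign, malignant)`;
#'   defaults to the MIAS class sizes 207/63/52.
#' @param image_size Image side in pixels (default 1024; tests typically
#'   use 256).
#' @param noise_sigma Gaussian background noise standard deviation in
#'   intensity units (default 8).
#' @param background_mean Mean breast-tissue intensity (default 60).
#' @param blob_intensity Peak added intensity of a mass (default 120).
#' @param spiculation_spikes Number of angular ridges on malignant
#'   masses (default 12).
#' @param seed Integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(counts = c(normal = 207, benign = 63,
                                    malignant = 52),
                         image_size = 1024, noise_sigma = 8,
                         background_mean = 60, blob_intensity = 120,
                         spiculation_spikes = 12, seed = 1) {
  stopifnot(all(counts >= 0), image_size >= 64, noise_sigma > 0,
            blob_intensity > 0)
  structure(list(counts = counts, image_size = as.integer(image_size),
                 noise_sigma = noise_sigma,
                 background_mean = background_mean,
                 blob_intensity = blob_intensity,
                 spiculation_spikes = as.integer(spiculation_spikes),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom mammogram
#'
#' The background is a noisy low-intensity breast disk.  A benign mass is
#' a radially symmetric Gaussian blob at a random interior centre — dense,
#' well-demarcated and roughly circular.  A malignant mass adds angular
#' spiculation ridges and harmonic boundary jitter to the same blob,
#' giving the irregular, indistinct outline that distinguishes malignant
#' from benign masses on mammography.  The returned annotation records
#' the true centre and radius (bottom-left origin, MIAS convention);
#' normal phantoms carry no location.
#'
#' @param class `"normal"`, `"benign"` or `"malignant"`.
#' @param spec A [phantom_spec()].
#' @param seed Integer seed (bit-identical output for a fixed seed).
#' @param id Reference id for the image and annotation.
#' @return A list with elements `image` ([mammogram()]) and `annotation`
#'   (one-row data frame in the layout of [parse_mias_annotations()]).
#' @export
make_phantom <- function(class = c("normal", "benign", "malignant"),
                         spec = phantom_spec(), seed = 1, id = "mdb001") {
  class <- match.arg(class)
  n <- spec$image_size
  with_seed(seed, {
    # breast disk: circle toward the left edge, as in a mediolateral view
    cr <- n * 0.5; cc <- n * 0.35; br <- n * 0.42
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    disk <- (rows - cr)^2 + (cols - cc)^2 <= br^2
    img <- matrix(0, n, n)
    img[disk] <- spec$background_mean +
      stats::rnorm(sum(disk), 0, spec$noise_sigma)

    ann <- data.frame(reference = id,
                      tissue = sample(unname(mias_tissues), 1),
                      abnormality = "NORM", severity = NA_character_,
                      x = NA_real_, y = NA_real_, radius = NA_real_)
    if (class != "normal") {
      radius <- stats::runif(1, 0.05, 0.09) * n
      # centre well inside the breast disk
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 0.55 * br)
      mr <- cr + rad * sin(ang); mc <- cc + rad * cos(ang)
      d2 <- (rows - mr)^2 + (cols - mc)^2
      sb <- radius / 2
      if (class == "benign") {
        img <- img + spec$blob_intensity * exp(-d2 / (2 * sb^2))
        ann$abnormality <- "CIRC"; ann$severity <- "benign"
      } else {
        phi <- atan2(rows - mr, cols - mc)
        # harmonic boundary jitter: direction-dependent effective width
        h <- stats::runif(3, 0, 1); ph <- stats::runif(3, 0, 2 * pi)
        jitter <- 1 + 0.35 * (h[1] * sin(2 * phi + ph[1]) +
                                h[2] * sin(3 * phi + ph[2]) +
                                h[3] * sin(5 * phi + ph[3])) /
          max(1e-9, sum(h))
        img <- img + spec$blob_intensity * exp(-d2 / (2 * (sb * jitter)^2))
        # spiculation: narrow angular ridges decaying over ~3 blob widths
        spike_ang <- stats::runif(spec$spiculation_spikes, 0, 2 * pi)
        for (a in spike_ang) {
          dphi <- atan2(sin(phi - a), cos(phi - a))
          img <- img + 0.6 * spec$blob_intensity *
            exp(-dphi^2 / (2 * 0.05^2)) * exp(-d2 / (2 * (3 * sb)^2))
        }
        ann$abnormality <- "SPIC"; ann$severity <- "malignant"
      }
      ann$x <- round(mc); ann$y <- round(n - mr); ann$radius <- round(radius)
    }
    img <- round(pmin(pmax(img, 0), 255))
    list(image = mammogram(img, maxval = 255, id = id),
         annotation = ann)
  })
}

#' Generate a MIAS-like phantom corpus
#'
#' Produces images plus a MIAS-format annotation file text that
#' round-trips through [parse_mias_annotations()].  Default class counts
#' are 207 normal / 63 benign / 52 malignant (322 images).
#'
#' @param spec A [phantom_spec()].
#' @return A list with `images` (named list of [mammogram()]),
#'   `annotations` (data frame) and `annotation_text` (character lines).
#' @export
make_mias_like_corpus <- function(spec = phantom_spec()) {
  classes <- rep(c("normal", "benign", "malignant"), spec$counts)
  images <- list(); anns <- list()
  for (i in seq_along(classes)) {
    id <- sprintf("mdb%03d", i)
    ph <- make_phantom(classes[i], spec, seed = derive_seed(spec$seed, i),
                       id = id)
    images[[id]] <- ph$image
    anns[[i]] <- ph$annotation
  }
  annotations <- do.call(rbind, anns)
  annotations$row <- spec$image_size - annotations$y
  annotations$col <- annotations$x
  list(images = images, annotations = annotations,
       annotation_text = write_mias_annotations(annotations))
}

#' Specification of a class-conditional Gaussian feature table
#'
#' @param n_per_class Samples per class (default 150).
#' @param total_features Total feature count (default 30).
#' @param informative Number of informative features (default 5).
#' @param mean_shift Class-mean separation of an informative feature, in
#'   units of `noise_sigma` (default 2).
#' @param noise_sigma Within-class standard deviation (default 1).
#' @param classes Number of classes (default 2).
#' @param seed Integer seed.
#' @return A `feature_table_spec` list.
#' @export
feature_table_spec <- function(n_per_class = 150, total_features = 30,
                               informative = 5, mean_shift = 2,
                               noise_sigma = 1, classes = 2, seed = 1) {
  stopifnot(informative <= total_features, n_per_class >= 1, classes >= 2)
  structure(list(n_per_class = as.integer(n_per_class),
                 total_features = as.integer(total_features),
                 informative = as.integer(informative),
                 mean_shift = mean_shift, noise_sigma = noise_sigma,
                 classes = as.integer(classes), seed = as.integer(seed)),
            class = "feature_table_spec")
}

#' Generate a labelled feature table with known informative structure
#'
#' Informative features are class-conditional Gaussians whose class means
#' are `mean_shift * noise_sigma` apart (equally spaced for more than two
#' classes); the remaining features are identical noise across classes.
#'
#' @param spec A [feature_table_spec()].
#' @return A list with feature matrix `x` (`n x total_features`), label
#'   factor `y` and logical `informative_mask` (the ground truth).
#' @export
make_feature_table <- function(spec = feature_table_spec()) {
  stopifnot(inherits(spec, "feature_table_spec"))
  n <- spec$n_per_class * spec$classes
  p <- spec$total_features
  with_seed(spec$seed, {
    x <- matrix(stats::rnorm(n * p, 0, spec$noise_sigma), n, p)
    y <- factor(rep(seq_len(spec$classes) - 1L, each = spec$n_per_class))
    informative <- seq_len(spec$informative)
    sep <- spec$mean_shift * spec$noise_sigma
    offsets <- (as.integer(y) - 1 - (spec$classes - 1) / 2) * sep
    for (j in informative) x[, j] <- x[, j] + offsets
    mask <- logical(p)
    mask[informative] <- TRUE
    list(x = x, y = y, informative_mask = mask)
  })
}

#' Generate an XOR-pattern two-class dataset
#'
#' Four Gaussian clusters at the corners of a square, with diagonally
#' opposite clusters sharing a class: linearly inseparable, the standard
#' stress test for kernel-width tuning.
#'
#' @param n Total number of points (default 200).
#' @param scale Corner offset (default 1).
#' @param noise_sigma Cluster spread (default 0.35).
#' @param seed Integer seed.
#' @return A list with `x` (n x 2 matrix) and label factor `y`.
#' @export
make_xor_data <- function(n = 200, scale = 1, noise_sigma = 0.35,
                          seed = 1) {
  with_seed(seed, {
    corner <- sample.int(4, n, replace = TRUE)
    cx <- c(-1, 1, -1, 1)[corner] * scale
    cy <- c(-1, -1, 1, 1)[corner] * scale
    x <- cbind(cx + stats::rnorm(n, 0, noise_sigma),
               cy + stats::rnorm(n, 0, noise_sigma))
    y <- factor(as.integer(corner %in% c(2, 3)))
    list(x = x, y = y)
  })
}
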