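# Synthetic fundus-like image generator: a 5-class severity problem whose
# ground truth is analytic. Class k carries exactly k small bright lesion
# blobs inside a circular retina disc with one optic-disc ellipse; severity
# is lesion count, a deliberately simple monotone analogue of clinical
# grading.

#' Synthetic dataset specification
#'
#' Default class proportions follow the published APTOS training
#' distribution 1805:370:999:193:295 over severities 0-4.
#'
#' @param n_total number of images.
#' @param n_classes number of severity classes (default 5).
#' @param image_size square image side in pixels (default 64).
#' @param noise_sigma additive Gaussian pixel noise (sd, on the `[0,1]`
#'   scale) applied after rendering.
#' @param class_proportions simplex vector of class frequencies; `"aptos"`
#'   (the default) or `"uniform"` are accepted shorthands.
#' @param lesion_intensity peak added intensity of a lesion blob.
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return a `synth_spec` object.
#' @export
synth_spec <- function(n_total, n_classes = 5L, image_size = 64L,
                       noise_sigma = 0.05, class_proportions = "aptos",
                       lesion_intensity = 0.9, seed = 1L) {
  if (identical(class_proportions, "aptos")) {
    class_proportions <- c(1805, 370, 999, 193, 295) / 3662
  } else if (identical(class_proportions, "uniform")) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  stopifnot(n_total >= n_classes, n_classes >= 2, image_size >= 16,
            noise_sigma >= 0, length(class_proportions) == n_classes)
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class proportions must sum to 1")
  }
  structure(list(n_total = as.integer(n_total), n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size), noise_sigma = noise_sigma,
                 class_proportions = class_proportions,
                 lesion_intensity = lesion_intensity, seed = as.integer(seed)),
            class = "synth_spec")
}

# largest-remainder apportionment of n_total over the proportions;
# conserves n_total exactly, ties to the lower class index
apportion_counts <- function(n_total, props) {
  x <- n_total * props
  base <- floor(x)
  rem <- x - base
  short <- n_total - sum(base)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Render one synthetic fundus-like image
#'
#' A reddish circular retina disc on a dark background, one bright
#' optic-disc ellipse at a random position inside the disc, and exactly
#' `class_k` lesion blobs at rejection-sampled, non-overlapping positions
#' inside the disc (avoiding the optic disc), followed by Gaussian noise
#' clipped to `[0, 1]`. With the same RNG state the first `k` blob
#' positions agree across severities, so the mean intensity is strictly
#' increasing in `k` at zero noise.
#'
#' @param class_k severity, 0-based (number of lesions).
#' @param spec a [synth_spec()].
#' @param seed optional seed fixing geometry and noise.
#' @return list with `image` (`H x W x 3` array in `[0,1]`) and `blobs`
#'   (data frame of lesion centers).
#' @export
generate_image <- function(class_k, spec, seed = NULL) {
  stopifnot(class_k >= 0, class_k < spec$n_classes)
  if (!is.null(seed)) set.seed(seed)
  S <- spec$image_size
  cx <- (S + 1) / 2; cy <- (S + 1) / 2
  R <- 0.45 * S
  xg <- matrix(rep(seq_len(S), S), S, S)          # row (y) coordinate
  yg <- t(xg)                                     # column (x) coordinate
  d2 <- (xg - cx)^2 + (yg - cy)^2
  disc <- d2 <= R^2
  img <- array(0.04, c(S, S, 3))
  base <- c(0.55, 0.25, 0.10)                     # fundus red-orange
  shade <- 1 - 0.25 * sqrt(d2) / R                # mild radial falloff
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[disc] <- base[ch] * shade[disc]
    img[, , ch] <- pl
  }
  # optic disc: bright ellipse at a random position well inside the retina
  ang <- stats::runif(1, 0, 2 * pi)
  od_r <- 0.5 * R
  ox <- cx + od_r * cos(ang); oy <- cy + od_r * sin(ang)
  a <- 0.14 * S; b <- 0.10 * S
  od <- ((xg - ox) / a)^2 + ((yg - oy) / b)^2 <= 1
  od_col <- c(0.95, 0.85, 0.55)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[od & disc] <- od_col[ch]
    img[, , ch] <- pl
  }
  # lesions: class_k non-overlapping bright blobs inside the disc; the
  # radius scales with the image so blobs stay salient after downsampling
  br <- max(1.2, 0.08 * S)
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  # separation and placement radius relax stepwise when the sampler
  # struggles (small images); large images keep the strict geometry
  while (nrow(centers) < class_k) {
    tries <- tries + 1L
    if (tries > 2400L) {
      stop(sprintf("image too small to place %d lesions", class_k))
    }
    sep <- if (tries <= 800L) 3.0 else if (tries <= 1600L) 2.5 else 2.0
    reach <- if (tries <= 800L) 0.80 else if (tries <= 1600L) 0.85 else 0.90
    rr <- sqrt(stats::runif(1)) * reach * R
    th <- stats::runif(1, 0, 2 * pi)
    px <- cx + rr * cos(th); py <- cy + rr * sin(th)
    if (((px - ox) / (a + br))^2 + ((py - oy) / (b + br))^2 <= 1) next
    if (nrow(centers) > 0 &&
        any((centers[, 1] - px)^2 + (centers[, 2] - py)^2 < (sep * br)^2)) next
    centers <- rbind(centers, c(px, py))
  }
  if (class_k > 0) {
    lesion_col <- c(1.0, 0.95, 0.80)
    for (bidx in seq_len(class_k)) {
      bump <- exp(-((xg - centers[bidx, 1])^2 + (yg - centers[bidx, 2])^2) /
                    (2 * br^2))
      for (ch in 1:3) {
        img[, , ch] <- img[, , ch] + spec$lesion_intensity * lesion_col[ch] * bump
      }
    }
  }
  if (spec$noise_sigma > 0) {
    img <- img + array(stats::rnorm(length(img), sd = spec$noise_sigma), dim(img))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  blobs <- if (class_k > 0) {
    data.frame(x = centers[, 1], y = centers[, 2])
  } else data.frame(x = numeric(0), y = numeric(0))
  list(image = img, blobs = blobs)
}

#' Generate a synthetic dataset
#'
#' Class counts are the largest-remainder apportionment of
#' `n_total * class_proportions` (exactly conserving `n_total`); image
#' order is shuffled. Bitwise deterministic given `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return a `synth_dataset`: list with `images` (`H x W x 3 x N` array),
#'   `labels` (0-based integer severities), `ids` (id_code strings),
#'   `counts` (per-class counts), `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  counts <- apportion_counts(spec$n_total, spec$class_proportions)
  if (any(counts == 0L)) {
    stop(sprintf("class %d receives 0 samples at n_total = %d",
                 which(counts == 0L)[1] - 1L, spec$n_total))
  }
  set.seed(spec$seed)
  labels <- rep(seq_len(spec$n_classes) - 1L, counts)
  n <- spec$n_total
  S <- spec$image_size
  images <- array(0, c(S, S, 3, n))
  for (i in seq_len(n)) {
    images[, , , i] <- generate_image(labels[i], spec)$image
  }
  ord <- sample.int(n)
  images <- images[, , , ord, drop = FALSE]
  labels <- labels[ord]
  ids <- sprintf("synth_%05d", seq_len(n))
  structure(list(images = images, labels = labels, ids = ids,
                 counts = counts, spec = spec),
            class = "synth_dataset")
}

#' Write a dataset to disk in the APTOS layout
#'
#' One 8-bit PNG per image named `<id_code>.png` plus a labels CSV with
#' header exactly `id_code,diagnosis`.
#'
#' @param ds a `synth_dataset` (or any list with `images`, `labels`,
#'   `ids`).
#' @param out_dir writable directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$labels)
  for (i in seq_len(n)) {
    png::writePNG(ds$images[, , , i],
                  file.path(out_dir, paste0(ds$ids[i], ".png")))
  }
  utils::write.csv(data.frame(id_code = ds$ids, diagnosis = ds$labels),
                   file.path(out_dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(out_dir)
}

#' Read a dataset from the APTOS layout
#'
#' @param dir directory holding `<id_code>.png` images.
#' @param labels_csv path to the labels CSV (`id_code,diagnosis`); defaults
#'   to `labels.csv` inside `dir`.
#' @return list with `images` (`H x W x 3 x N`), `labels`, `ids`.
#' @export
read_dataset <- function(dir, labels_csv = file.path(dir, "labels.csv")) {
  lab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!all(c("id_code", "diagnosis") %in% names(lab))) {
    stop("labels CSV must have columns id_code and diagnosis")
  }
  n <- nrow(lab)
  first <- file.path(dir, paste0(lab$id_code[1], ".png"))
  if (!file.exists(first)) {
    stop(sprintf("missing image for id_code '%s'", lab$id_code[1]))
  }
  im1 <- png::readPNG(first)
  images <- array(0, c(dim(im1)[1], dim(im1)[2], 3, n))
  for (i in seq_len(n)) {
    f <- file.path(dir, paste0(lab$id_code[i], ".png"))
    if (!file.exists(f)) {
      stop(sprintf("missing image for id_code '%s'", lab$id_code[i]))
    }
    im <- png::readPNG(f)
    if (length(dim(im)) == 2L) im <- array(rep(im, 3), c(dim(im), 3))
    images[, , , i] <- im[, , 1:3]
  }
  list(images = images, labels = as.integer(lab$diagnosis), ids = lab$id_code)
}

#' Per-class sample counts for a dataset size
#'
#' The largest-remainder apportionment used by [generate_dataset()],
#' exposed directly: at `n_total = 3662` with the APTOS proportions it
#' reproduces the published class counts (1805, 370, 999, 193, 295).
#'
#' @param n_total dataset size.
#' @param class_proportions simplex vector, or `"aptos"` / `"uniform"`.
#' @param n_classes number of classes (used by the shorthands).
#' @return integer vector of per-class counts summing to `n_total`.
#' @export
synth_class_counts <- function(n_total, class_proportions = "aptos",
                               n_classes = 5L) {
  if (identical(class_proportions, "aptos")) {
    class_proportions <- c(1805, 370, 999, 193, 295) / 3662
  } else if (identical(class_proportions, "uniform")) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  apportion_counts(n_total, class_proportions)
}

#' The "easy" synthetic study profile
#'
#' The package's reference condition for search-quality and learnability
#' checks: 600 images, 5 balanced classes, 32 x 32 pixels, additive noise
#' sd 0.02. Balanced classes isolate learnability from the class-imbalance
#' difficulty, which the APTOS-proportioned default profile adds back.
#'
#' @param seed integer seed.
#' @param n_total,image_size,noise_sigma overridable condition parameters.
#' @return a [synth_spec()].
#' @export
synth_easy_spec <- function(seed = 1L, n_total = 600L, image_size = 32L,
                            noise_sigma = 0.02) {
  synth_spec(n_total = n_total, image_size = image_size,
             noise_sigma = noise_sigma, class_proportions = "uniform",
             seed = seed)
}
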