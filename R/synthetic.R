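# Procedural dermoscopy-like image generator. Emulates the qualitative
# challenges of dermoscopy segmentation — blurred lesion boundaries, uneven
# colour distribution, low contrast, hair and bubble artefacts — with fully
# seeded, parametric lesions so every stage of the pipeline is testable
# without any external dataset.

#' Lesion specification
#'
#' @param center Lesion centre `c(row, col)` in pixels; `NULL` centres it.
#' @param base_radius Mean lesion radius in pixels.
#' @param irregularity Radial perturbation amplitude (>= 0): the boundary
#'   radius is `base_radius * (1 + irregularity * s(theta))` for a smooth
#'   periodic `s` with `max |s| = 1`.
#' @param boundary_blur Gaussian sigma (pixels) softening the lesion edge in
#'   the rendered image (the mask itself stays binary).
#' @param contrast Lesion/skin intensity gap in (0, 1]; 1 is a clean dark
#'   lesion, small values emulate low-contrast cases.
#' @param hair_count,bubble_count Number of dark hair strands / bright
#'   bubble artefacts overlaid on the image.
#' @param seed Integer seed; mask and rendering are deterministic given it.
#' @return A `lesion_spec` list.
#' @export
lesionSpec <- function(center = NULL, base_radius = 16, irregularity = 0.2,
                       boundary_blur = 1, contrast = 0.6,
                       hair_count = 0L, bubble_count = 0L, seed = 1L) {
  stopifnot(base_radius > 0, irregularity >= 0, boundary_blur >= 0,
            contrast > 0, contrast <= 1, hair_count >= 0, bubble_count >= 0)
  structure(list(center = center, base_radius = base_radius,
                 irregularity = irregularity, boundary_blur = boundary_blur,
                 contrast = contrast, hair_count = as.integer(hair_count),
                 bubble_count = as.integer(bubble_count),
                 seed = as.integer(seed)),
            class = "lesion_spec")
}

# Smooth periodic radial perturbation with unit sup-norm.
radialProfile <- function(theta, nharm = 5L) {
  a <- stats::rnorm(nharm) / seq_len(nharm)
  b <- stats::rnorm(nharm) / seq_len(nharm)
  s <- function(th) {
    out <- 0
    for (h in seq_len(nharm)) {
      out <- out + a[h] * cos(h * th) + b[h] * sin(h * th)
    }
    out
  }
  grid <- s(seq(0, 2 * pi, length.out = 720))
  m <- max(abs(grid))
  if (m == 0) m <- 1
  s(theta) / m
}

#' Generate a star-convex binary lesion mask
#'
#' Rasterises the region whose boundary radius at angle `theta` is
#' `base_radius * (1 + irregularity * s(theta))` for a smooth random
#' periodic `s` (seeded). The region is star-convex about the centre, hence
#' a single connected foreground component.
#'
#' @param spec A [lesionSpec()].
#' @param size Image side in pixels.
#' @return `size x size` matrix with values in {0, 1}.
#' @examples
#' m <- generateLesionMask(lesionSpec(base_radius = 10, seed = 7), 48)
#' sum(m) / (pi * 10^2)   # near 1 for a near-disc
#' @export
generateLesionMask <- function(spec, size) {
  stopifnot(inherits(spec, "lesion_spec"))
  set.seed(spec$seed)
  ctr <- if (is.null(spec$center)) c((size + 1) / 2, (size + 1) / 2)
         else spec$center
  rmax <- spec$base_radius * (1 + spec$irregularity)
  if (ctr[1] - rmax < 1 || ctr[1] + rmax > size ||
      ctr[2] - rmax < 1 || ctr[2] + rmax > size) {
    stop("lesion (radius up to ", round(rmax, 1),
         " at centre ", ctr[1], ",", ctr[2],
         ") exceeds the ", size, "x", size, " image bounds", call. = FALSE)
  }
  dy <- matrix(seq_len(size) - ctr[1], size, size)
  dx <- matrix(seq_len(size) - ctr[2], size, size, byrow = TRUE)
  theta <- atan2(dy, dx)
  r <- pmax(spec$base_radius *
              (1 + spec$irregularity * radialProfile(theta)), 2)
  mask <- (sqrt(dx^2 + dy^2) <= r) * 1
  dim(mask) <- c(size, size)
  mask
}

gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma)
}

# Quadratic Bezier polyline through three random control points.
hairCurve <- function(size) {
  pts <- matrix(stats::runif(6, 1, size), 3, 2)
  tt <- seq(0, 1, length.out = 4L * size)
  b <- cbind((1 - tt)^2, 2 * tt * (1 - tt), tt^2) %*% pts
  ij <- unique(round(b))
  ij[ij[, 1] >= 1 & ij[, 1] <= size & ij[, 2] >= 1 & ij[, 2] <= size, ,
     drop = FALSE]
}

#' Render a dermoscopy-like RGB image for a lesion mask
#'
#' Skin-tone background with low-frequency intensity variation; the lesion
#' region is darker by `contrast` with its own colour unevenness; the lesion
#' edge is softened by a Gaussian of sigma `boundary_blur`; dark hair
#' strands (random Bezier curves) and bright bubble discs are overlaid; the
#' result is quantised to 8 bits per channel. Deterministic given the spec
#' seed.
#'
#' @param mask Binary mask from [generateLesionMask()].
#' @param spec The same [lesionSpec()].
#' @return `(size, size, 3)` array with values in \[0, 1\] on an 8-bit grid.
#' @export
renderDermoscopyImage <- function(mask, spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  size <- nrow(mask)
  set.seed(spec$seed + 1L)
  skin <- c(0.85, 0.68, 0.60)
  lesion <- skin * (1 - spec$contrast)
  xs <- matrix(seq_len(size) / size, size, size)
  ys <- t(xs)
  field <- 0
  for (k in 1:3) {
    field <- field + stats::runif(1, 0.3, 1) *
      sin(2 * pi * (stats::runif(1, 0.5, 2) * xs +
                    stats::runif(1, 0.5, 2) * ys) + stats::runif(1, 0, 2 * pi))
  }
  field <- 0.04 * field / max(abs(field))
  lesionField <- 0
  for (k in 1:2) {
    lesionField <- lesionField + stats::runif(1, 0.3, 1) *
      sin(2 * pi * (stats::runif(1, 2, 4) * xs +
                    stats::runif(1, 2, 4) * ys) + stats::runif(1, 0, 2 * pi))
  }
  lesionField <- 0.05 * lesionField / max(abs(lesionField))
  alpha <- gaussBlur(mask, spec$boundary_blur)
  alpha <- pmin(pmax(alpha, 0), 1)
  img <- array(0, c(size, size, 3))
  for (c in 1:3) {
    bg <- skin[c] + field
    fg <- lesion[c] + lesionField
    img[, , c] <- bg * (1 - alpha) + fg * alpha
  }
  if (spec$hair_count > 0) {
    hairCol <- c(0.15, 0.10, 0.08)
    for (h in seq_len(spec$hair_count)) {
      ij <- hairCurve(size)
      for (c in 1:3) {
        pl <- img[, , c]
        pl[ij] <- 0.25 * pl[ij] + 0.75 * hairCol[c]
        img[, , c] <- pl
      }
    }
  }
  if (spec$bubble_count > 0) {
    for (bb in seq_len(spec$bubble_count)) {
      bc <- stats::runif(2, 4, size - 3)
      br <- stats::runif(1, 1.5, 3.5)
      dy <- matrix(seq_len(size) - bc[1], size, size)
      dx <- matrix(seq_len(size) - bc[2], size, size, byrow = TRUE)
      dd <- sqrt(dx^2 + dy^2)
      disc <- dd <= br
      ring <- dd > br & dd <= br + 1
      for (c in 1:3) {
        pl <- img[, , c]
        pl[disc] <- pmin(pl[disc] + 0.22, 1)
        pl[ring] <- pl[ring] * 0.8
        img[, , c] <- pl
      }
    }
  }
  img <- img + array(stats::rnorm(size * size * 3, sd = 0.008),
                     c(size, size, 3))
  round(pmin(pmax(img, 0), 1) * 255) / 255
}

difficultyPreset <- function(difficulty) {
  switch(difficulty,
         easy = list(contrast = c(0.70, 0.80), blur = 0.6,
                     irregularity = 0.15, hair = 0L, bubbles = 0L),
         medium = list(contrast = c(0.40, 0.50), blur = 1.5,
                       irregularity = 0.30, hair = 6L, bubbles = 2L),
         hard = list(contrast = c(0.18, 0.26), blur = 2.5,
                     irregularity = 0.45, hair = 14L, bubbles = 4L),
         stop("unknown difficulty: ", difficulty, call. = FALSE))
}

#' Generate paired images and masks in memory
#'
#' Draws per-sample lesion specifications from the difficulty preset
#' (radius, centre jitter, contrast band, artefact counts) and renders each
#' pair. Sample `i` uses seed `seed * 1000 + i`, so datasets with the same
#' `(n, size, difficulty, seed)` are identical.
#'
#' @param n Number of samples.
#' @param size Image side in pixels (use a multiple of 32 for the network).
#' @param difficulty `"easy"`, `"medium"` or `"hard"`.
#' @param seed Integer seed.
#' @return List of `n` elements, each `list(image, mask, spec)`.
#' @export
generateSamples <- function(n, size = 64L,
                            difficulty = c("easy", "medium", "hard"),
                            seed = 1L) {
  difficulty <- match.arg(difficulty)
  preset <- difficultyPreset(difficulty)
  lapply(seq_len(n), function(i) {
    si <- as.integer(seed) * 1000L + i
    set.seed(si)
    rad <- stats::runif(1, 0.16, 0.30) * size
    margin <- rad * (1 + preset$irregularity) + 2
    ctr <- stats::runif(2, margin, size - margin + 1)
    spec <- lesionSpec(center = ctr, base_radius = rad,
                       irregularity = preset$irregularity,
                       boundary_blur = preset$blur,
                       contrast = stats::runif(1, preset$contrast[1],
                                               preset$contrast[2]),
                       hair_count = preset$hair, bubble_count = preset$bubbles,
                       seed = si)
    mask <- generateLesionMask(spec, size)
    list(image = renderDermoscopyImage(mask, spec), mask = mask, spec = spec)
  })
}

#' Split sizes in the 70/10/20 convention
#'
#' `floor(0.7 n)` train, `floor(0.1 n)` validation, remainder test — the
#' ratio used by the common 2594-image dermoscopy benchmark split
#' (1815/259/520).
#'
#' @param n Total sample count (>= 10).
#' @return Named integer vector `train`, `val`, `test`.
#' @export
splitSizes <- function(n) {
  stopifnot(n >= 10)
  tr <- floor(0.7 * n)
  va <- floor(0.1 * n)
  c(train = tr, val = va, test = n - tr - va)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `images/<id>.png` (RGB) and `masks/<id>.png` (single channel,
#' 0/255) plus a JSON manifest recording each sample's split assignment and
#' full lesion specification. Identical `(n, size, difficulty, seed)` yield
#' byte-identical files and manifest.
#'
#' @param n Number of samples (>= 10).
#' @param dir Output directory (created if needed).
#' @inheritParams generateSamples
#' @return The manifest as a data.frame (invisibly); also written to
#'   `manifest.json`.
#' @export
generateDataset <- function(n, dir, size = 64L,
                            difficulty = c("easy", "medium", "hard"),
                            seed = 1L) {
  difficulty <- match.arg(difficulty)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    stop("output directory ", dir, " is not writable", call. = FALSE)
  }
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  samples <- generateSamples(n, size, difficulty, seed)
  sizes <- splitSizes(n)
  split <- rep(c("train", "val", "test"), sizes)
  ids <- sprintf("sample_%04d", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(samples[[i]]$image, file.path(dir, "images",
                                                paste0(ids[i], ".png")))
    png::writePNG(samples[[i]]$mask, file.path(dir, "masks",
                                               paste0(ids[i], ".png")))
  }
  manifest <- data.frame(
    id = ids, split = split,
    base_radius = vapply(samples, function(s) s$spec$base_radius, numeric(1)),
    irregularity = vapply(samples, function(s) s$spec$irregularity,
                          numeric(1)),
    boundary_blur = vapply(samples, function(s) s$spec$boundary_blur,
                           numeric(1)),
    contrast = vapply(samples, function(s) s$spec$contrast, numeric(1)),
    hair_count = vapply(samples, function(s) s$spec$hair_count, integer(1)),
    bubble_count = vapply(samples, function(s) s$spec$bubble_count,
                          integer(1)),
    seed = vapply(samples, function(s) s$spec$seed, integer(1)),
    stringsAsFactors = FALSE)
  meta <- list(n = n, size = size, difficulty = difficulty, seed = seed,
               samples = manifest)
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Naive intensity-threshold baseline mask
#'
#' Channel-mean grey image thresholded by Otsu's method, with the lesion
#' taken as the darker class. Used as a classical baseline and by the
#' difficulty-ordering checks.
#'
#' @param img RGB array `(H, W, 3)`.
#' @return Binary matrix, 1 = lesion (darker class).
#' @export
thresholdBaselineMask <- function(img) {
  grey <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  th <- EBImage::otsu(grey, range = c(0, 1))
  (grey < th) * 1
}
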