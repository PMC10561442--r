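# Readers/writers for images, masks, predictions and evaluation reports.
# Conventions: masks are single-channel PNG with 0 = background and
# 255 = lesion; probability maps are stored losslessly as RDS; images and
# masks share a row-major, origin-top-left pixel grid.

#' Resize an image array
#'
#' Bilinear for continuous imagery, nearest-neighbour for label masks.
#'
#' @param x `(H, W)` matrix or `(H, W, C)` array.
#' @param size Target side in pixels (square output).
#' @param method `"bilinear"` or `"nearest"`.
#' @return Resized array of the same rank.
#' @export
resizeImage <- function(x, size, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  x4 <- ensure4d(x)
  node <- if (method == "bilinear") {
    agResizeBilinear(agConst(x4), size, size)
  } else {
    agResizeNearest(agConst(x4), size, size)
  }
  out <- node$val
  if (is.matrix(x)) matrix(out, size, size) else array(out, c(size, size,
                                                              dim(x)[3]))
}

readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

readMaskPNG <- function(path) {
  m <- png::readPNG(path)
  if (!is.matrix(m)) m <- m[, , 1]
  (m >= 0.5) * 1
}

#' Load paired images and masks from a directory
#'
#' Expects `images/` and `masks/` subdirectories with PNG files matched by
#' file stem. Images are decoded to RGB in \[0, 1\] and bilinearly resized
#' to `size x size`; masks are nearest-neighbour resized and binarised at
#' 0.5. Pairs are returned in lexicographic stem order. Unmatched stems
#' raise an error listing them; unreadable files are skipped with a
#' warning.
#'
#' @param dir Dataset directory.
#' @param size Target side in pixels.
#' @return List of `list(image, mask, id)` samples.
#' @export
loadImageMaskPairs <- function(dir, size) {
  idir <- file.path(dir, "images")
  mdir <- file.path(dir, "masks")
  if (!dir.exists(idir) || !dir.exists(mdir)) {
    stop("expected images/ and masks/ under ", dir, call. = FALSE)
  }
  istems <- sort(sub("\\.png$", "", list.files(idir, pattern = "\\.png$")))
  mstems <- sort(sub("\\.png$", "", list.files(mdir, pattern = "\\.png$")))
  unmatched <- c(setdiff(istems, mstems), setdiff(mstems, istems))
  if (length(unmatched)) {
    stop("unmatched image/mask stem(s): ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (stem in istems) {
    img <- tryCatch(readImagePNG(file.path(idir, paste0(stem, ".png"))),
                    error = function(e) NULL)
    msk <- tryCatch(readMaskPNG(file.path(mdir, paste0(stem, ".png"))),
                    error = function(e) NULL)
    if (is.null(img) || is.null(msk)) {
      warning("skipping unreadable pair: ", stem)
      next
    }
    out[[length(out) + 1L]] <- list(
      image = resizeImage(img, size, "bilinear"),
      mask = (resizeImage(msk, size, "nearest") >= 0.5) * 1,
      id = stem)
  }
  out
}

#' Write predictions for a set of images
#'
#' For each sample writes `prob/<id>.rds` (the lossless probability map),
#' `pred/<id>.png` (the mask binarised at `threshold`, 0/255), and — when
#' ground truth is available and `panel = TRUE` — a three-row comparison
#' strip `panel/<id>.png` (input on top, ground truth in the middle,
#' prediction at the bottom).
#'
#' @param model An `adffnet` model or a checkpoint path.
#' @param samples List of `list(image[, mask], id)` samples.
#' @param out_dir Output directory.
#' @param threshold Binarisation threshold.
#' @param panel Write comparison panels where masks are present.
#' @return Invisibly, a data.frame of written files.
#' @export
predictToFiles <- function(model, samples, out_dir, threshold = 0.5,
                           panel = FALSE) {
  if (is.character(model)) model <- loadModel(model)
  for (d in c("prob", "pred", if (panel) "panel")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- list()
  for (s in samples) {
    id <- s$id %||% sprintf("sample_%04d", length(rows) + 1L)
    p <- adffnetPredict(model, s$image)
    p2 <- matrix(p, dim(p)[1], dim(p)[2])
    saveRDS(p2, file.path(out_dir, "prob", paste0(id, ".rds")))
    png::writePNG((p2 >= threshold) * 1,
                  file.path(out_dir, "pred", paste0(id, ".png")))
    if (panel && !is.null(s$mask)) {
      grey <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
      strip <- rbind(grey, s$mask, (p2 >= threshold) * 1)
      png::writePNG(strip, file.path(out_dir, "panel", paste0(id, ".png")))
    }
    rows[[length(rows) + 1L]] <- data.frame(id = id, stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, rows))
}

#' Evaluate prediction files against ground truth
#'
#' Matches prediction files (probability `.rds` from [predictToFiles()], or
#' binary `.png`) to truth masks by stem, pools pixels, and writes/returns
#' the six-metric report plus ROC points and AUC.
#'
#' @param pred_dir Directory of predictions (a `prob/` subdirectory is used
#'   when present, else `.png` masks in `pred_dir` itself).
#' @param truth_dir Directory of ground-truth mask PNGs (a `masks/`
#'   subdirectory is used when present).
#' @param threshold Binarisation threshold.
#' @param out_dir If non-NULL, writes `metrics.csv`, `metrics.json` and
#'   `roc.csv` there.
#' @return List with `metrics`, `counts`, `auc`, `roc`.
#' @export
evaluateDirs <- function(pred_dir, truth_dir, threshold = 0.5,
                         out_dir = NULL) {
  probdir <- file.path(pred_dir, "prob")
  useRds <- dir.exists(probdir)
  pdir <- if (useRds) probdir else pred_dir
  pat <- if (useRds) "\\.rds$" else "\\.png$"
  tdir <- if (dir.exists(file.path(truth_dir, "masks"))) {
    file.path(truth_dir, "masks")
  } else {
    truth_dir
  }
  pstems <- sort(sub(pat, "", list.files(pdir, pattern = pat)))
  tstems <- sort(sub("\\.png$", "", list.files(tdir, pattern = "\\.png$")))
  stems <- intersect(pstems, tstems)
  if (!length(stems)) stop("no matched prediction/truth pairs", call. = FALSE)
  ps <- list()
  ts <- list()
  for (stem in stems) {
    ps[[stem]] <- if (useRds) readRDS(file.path(pdir, paste0(stem, ".rds")))
                  else readMaskPNG(file.path(pdir, paste0(stem, ".png")))
    ts[[stem]] <- readMaskPNG(file.path(tdir, paste0(stem, ".png")))
  }
  counts <- Reduce(`+`, Map(function(p, t) confusionCounts(p, t, threshold),
                            ps, ts))
  metrics <- segmentationMetrics(counts)
  roc <- rocAuc(ps, ts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rep <- data.frame(f1 = metrics[["f1"]], se = metrics[["se"]],
                      sp = metrics[["sp"]], ac = metrics[["ac"]],
                      pc = metrics[["pc"]], js = metrics[["js"]],
                      auc = roc$auc)
    utils::write.csv(rep, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(as.list(rep), list(counts = as.list(counts))),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(roc$curve, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
  }
  list(metrics = metrics, counts = counts, auc = roc$auc, roc = roc$curve)
}

#' Write a reproducibility manifest for a run
#'
#' @param dir Output directory.
#' @param config Named list of the run's full configuration (seed included).
#' @return The manifest path, invisibly.
#' @export
writeRunManifest <- function(dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(
    list(package = "adffnet",
         version = as.character(utils::packageVersion("adffnet")),
         timestamp = format(Sys.time(), tz = "UTC"),
         config = config),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
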