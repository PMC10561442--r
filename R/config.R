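#' Model configuration
#'
#' Builds and validates the configuration of the dual-path segmentation
#' network: a VGG16-style five-block encoder feeding a spatial path (boundary
#' refinement over the two shallowest blocks) and a context path (multi-scale
#' dilated context extraction plus channel-attention feature selection over
#' the three deepest blocks), fused by the dual-path fusion block and a
#' 1x1-conv + sigmoid prediction head.
#'
#' @param input_size Input image side in pixels; must be divisible by 32
#'   (five 2x2 poolings). Default 256, the resolution dermoscopy benchmarks
#'   are commonly resized to.
#' @param base_channels Channel count of the first encoder block; doubled per
#'   block up to a cap of `8 * base_channels`. Default 64 (VGG16); reduce for
#'   desk-scale runs.
#' @param backbone Encoder family; only `"vgg16"` is provided.
#' @param br_kernel Odd strip-kernel length k of the boundary-refinement
#'   module (1xk and kx1 convolution pairs). Default 3.
#' @param dilation_rates Strictly increasing dilation rates of the three 3x3
#'   branches of the multi-scale context block. Default `c(3, 5, 7)`.
#' @param fs_reduction Bottleneck ratio of the two fully connected layers in
#'   the feature-selection block; hidden width is
#'   `max(channels / fs_reduction, 8)`. Default 16.
#' @param head_upsample Interpolation used by the prediction head to return
#'   to input resolution: `"bilinear"` (default) or `"nearest"`.
#' @param seed Integer seed controlling weight initialisation.
#' @param init Weight initialisation: `"he"` (default; zero-mean Gaussian
#'   with sd `sqrt(2 / fan_in)`) or `"standard_gaussian"` (unit variance).
#' @param modules Character subset of `c("BR", "MCIE", "FS", "DFF")` to
#'   enable; omitted blocks are replaced by identity/bypass paths, which is
#'   how ablation rows are expressed.
#'
#' @return An object of class `adffnet_config` (a validated list).
#' @examples
#' cfg <- modelConfig(input_size = 64, base_channels = 8)
#' cfg$dilation_rates
#' @export
modelConfig <- function(input_size = 256L,
                        base_channels = 64L,
                        backbone = "vgg16",
                        br_kernel = 3L,
                        dilation_rates = c(3L, 5L, 7L),
                        fs_reduction = 16L,
                        head_upsample = c("bilinear", "nearest"),
                        seed = 1L,
                        init = c("he", "standard_gaussian"),
                        modules = c("BR", "MCIE", "FS", "DFF")) {
  head_upsample <- match.arg(head_upsample)
  init <- match.arg(init)
  backbone <- match.arg(backbone, "vgg16")
  input_size <- as.integer(input_size)
  base_channels <- as.integer(base_channels)
  br_kernel <- as.integer(br_kernel)
  dilation_rates <- as.integer(dilation_rates)
  if (input_size %% 32L != 0L) {
    stop("input_size (", input_size, ") must be divisible by 32", call. = FALSE)
  }
  if (base_channels < 4L) {
    stop("base_channels must be >= 4", call. = FALSE)
  }
  if (br_kernel %% 2L == 0L || br_kernel < 3L) {
    stop("br_kernel must be an odd integer >= 3, got ", br_kernel,
         call. = FALSE)
  }
  if (length(dilation_rates) != 3L || any(dilation_rates <= 0L) ||
      any(diff(dilation_rates) <= 0L)) {
    stop("dilation_rates must be three strictly increasing positive integers",
         call. = FALSE)
  }
  if (fs_reduction < 1L) stop("fs_reduction must be >= 1", call. = FALSE)
  modules <- unique(as.character(modules))
  bad <- setdiff(modules, c("BR", "MCIE", "FS", "DFF"))
  if (length(bad)) {
    stop("unknown module name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(input_size = input_size, base_channels = base_channels,
         backbone = backbone, br_kernel = br_kernel,
         dilation_rates = dilation_rates,
         fs_reduction = as.integer(fs_reduction),
         head_upsample = head_upsample, seed = as.integer(seed),
         init = init, modules = modules),
    class = "adffnet_config")
}

#' @export
print.adffnet_config <- function(x, ...) {
  cat("adffnet_config\n")
  cat("  input:", x$input_size, "x", x$input_size, " backbone:", x$backbone,
      " base channels:", x$base_channels, "\n")
  cat("  BR kernel:", x$br_kernel,
      " dilation rates:", paste(x$dilation_rates, collapse = "/"),
      " FS reduction:", x$fs_reduction, "\n")
  cat("  modules:", if (length(x$modules)) paste(x$modules, collapse = "+")
      else "(none: bypass baseline)", " init:", x$init,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Loss configuration
#'
#' Weights and constants of the multivariate training loss
#' `lambda1 * L_E + lambda2 * L_BCE + lambda3 * L_Dice`, where `L_E` is the
#' Laplacian boundary-oriented cross-entropy, `L_BCE` the mean binary
#' cross-entropy, and `L_Dice` the two-sided smoothed Dice loss.
#'
#' @param lambda1,lambda2,lambda3 Nonnegative component weights; defaults
#'   0.2, 1, 1.
#' @param epsilon Dice smoothing constant, default 1.
#' @param clip Probability clipping bound applied before every logarithm,
#'   default 1e-7; must lie in (0, 0.5).
#' @return An object of class `adffnet_loss_config`.
#' @export
lossConfig <- function(lambda1 = 0.2, lambda2 = 1, lambda3 = 1,
                       epsilon = 1, clip = 1e-7) {
  if (any(c(lambda1, lambda2, lambda3) < 0)) {
    stop("loss weights must be nonnegative", call. = FALSE)
  }
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (clip <= 0 || clip >= 0.5) stop("clip must lie in (0, 0.5)", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 epsilon = epsilon, clip = clip),
            class = "adffnet_loss_config")
}
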