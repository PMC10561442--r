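#' Build the VGG16-style encoder
#'
#' Five convolutional blocks of 3x3 convolutions (2, 2, 3, 3, 3 layers) with
#' ReLU activations, each followed by a 2x2 max pooling. Block outputs c1..c5
#' have spatial sizes S/2 .. S/32 and channel counts `base`, `2*base`,
#' `4*base`, `8*base`, `8*base` — the channel count doubles per block up to
#' the VGG16-style plateau at `8*base`.
#'
#' @param config An [modelConfig()] object; `config$seed` seeds the weight
#'   draws.
#' @return An encoder object (list of blocks) usable with
#'   [encoderForward()].
#' @examples
#' enc <- buildEncoder(modelConfig(input_size = 64, base_channels = 8))
#' outs <- encoderForward(enc, array(0, c(64, 64, 3, 1)))
#' vapply(outs, function(o) dim(o)[1], numeric(1))
#' @export
buildEncoder <- function(config) {
  stopifnot(inherits(config, "adffnet_config"))
  set.seed(config$seed)
  b <- config$base_channels
  outs <- c(b, 2L * b, 4L * b, 8L * b, 8L * b)
  counts <- c(2L, 2L, 3L, 3L, 3L)
  ins <- c(3L, outs[-5])
  blocks <- vector("list", 5L)
  for (i in 1:5) {
    convs <- vector("list", counts[i])
    cin <- ins[i]
    for (j in seq_len(counts[i])) {
      convs[[j]] <- newConv(3L, 3L, cin, outs[i], config$init)
      cin <- outs[i]
    }
    blocks[[i]] <- list(convs = convs)
  }
  structure(list(blocks = blocks, base = b, channels = outs,
                 config = config),
            class = "adffnet_encoder")
}

checkDiv32 <- function(h, w) {
  if (h %% 32L != 0L) {
    stop("input height ", h, " is not divisible by 32", call. = FALSE)
  }
  if (w %% 32L != 0L) {
    stop("input width ", w, " is not divisible by 32", call. = FALSE)
  }
}

# Internal tape forward: x is an agNode (H, W, 3, N); returns list of nodes.
encForwardNode <- function(enc, x) {
  d <- dim(x$val)
  checkDiv32(d[1], d[2])
  cs <- vector("list", 5L)
  h <- x
  for (i in 1:5) {
    for (conv in enc$blocks[[i]]$convs) {
      h <- agRelu(convFwd(conv, h))
    }
    h <- agMaxPool2(h)
    cs[[i]] <- h
  }
  names(cs) <- paste0("c", 1:5)
  cs
}

#' Run the encoder
#'
#' @param encoder An encoder from [buildEncoder()].
#' @param x Input image array, `(H, W, 3)` or `(H, W, 3, N)`, with H and W
#'   divisible by 32.
#' @return Named list `c1..c5` of feature-map arrays (same rank as the
#'   input), with a `scales` attribute giving each block's downsampling
#'   factor relative to the input.
#' @export
encoderForward <- function(encoder, x) {
  was3d <- length(dim(x)) == 3L
  cs <- encForwardNode(encoder, agConst(ensure4d(x)))
  out <- lapply(cs, function(n) if (was3d) dropTo3d(n$val) else n$val)
  attr(out, "scales") <- c(2L, 4L, 8L, 16L, 32L)
  out
}
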