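# The three bespoke attention blocks: boundary refinement (BR), multi-scale
# context information extraction (MCIE), feature selection (FS), and the
# dual-path feature fusion (DFF). Each has a constructor returning a layer
# list (parameters are agNode environments, overwritable in place) and a
# forward that accepts either plain arrays or tape nodes; plain-array calls
# return plain arrays.

isRaw <- function(...) !any(vapply(list(...), inherits, logical(1), "agNode"))

toNode4 <- function(x) if (inherits(x, "agNode")) x else agConst(ensure4d(x))

#' Boundary refinement module
#'
#' Spatial-attention gate over the shallow encoder features. The deeper map
#' `c2` is bilinearly upsampled to `c1`'s grid, passed through two
#' independent strip-convolution branches (1xk then kx1, and kx1 then 1xk;
#' the first convolution of each branch preserves the channel count, the
#' second reduces to a single channel), and the branch sum is squashed by a
#' sigmoid into a one-channel attention map `A` in (0,1). The output is
#' `X = A * c1`, broadcast over c1's channels.
#'
#' @param channels Channel count of `c2`.
#' @param k Odd strip-kernel length, default 3.
#' @param init Weight initialisation scheme (see [modelConfig()]).
#' @return A BR layer for [brForward()].
#' @examples
#' set.seed(1)
#' br <- brModule(channels = 4, k = 3)
#' c1 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
#' c2 <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
#' out <- brForward(br, c1, c2)
#' range(out$attention)   # inside (0, 1)
#' @export
brModule <- function(channels, k = 3L, init = "he") {
  k <- as.integer(k)
  if (k %% 2L == 0L) {
    stop("BR strip kernel k must be odd, got ", k, call. = FALSE)
  }
  list(kind = "br", k = k,
       conv1a = newConv(1L, k, channels, channels, init),
       conv1b = newConv(k, 1L, channels, 1L, init),
       conv2a = newConv(k, 1L, channels, channels, init),
       conv2b = newConv(1L, k, channels, 1L, init))
}

#' Run the boundary refinement module
#'
#' @param br Layer from [brModule()].
#' @param c1 Shallow feature map `(H, W, C1[, N])`.
#' @param c2 Deeper feature map at exactly half c1's spatial size.
#' @return List with `x` (refined map, c1's shape) and `attention` (the
#'   single-channel map `A`).
#' @export
brForward <- function(br, c1, c2) {
  raw <- isRaw(c1, c2)
  c1 <- toNode4(c1); c2 <- toNode4(c2)
  d1 <- dim(c1$val); d2 <- dim(c2$val)
  if (d2[1] * 2L != d1[1] || d2[2] * 2L != d1[2]) {
    stop("c2 spatial size (", d2[1], "x", d2[2],
         ") must be exactly half of c1's (", d1[1], "x", d1[2], ")",
         call. = FALSE)
  }
  c2p <- agResizeBilinear(c2, d1[1], d1[2])
  x1 <- convFwd(br$conv1b, convFwd(br$conv1a, c2p))
  x2 <- convFwd(br$conv2b, convFwd(br$conv2a, c2p))
  a <- agSigmoid(agAdd(x1, x2))
  x <- agSpatialScale(c1, a)
  if (raw) list(x = dropTo3d(x$val), attention = dropTo3d(a$val))
  else list(x = x, attention = a)
}

#' Multi-scale context information extraction
#'
#' Four parallel branches over the input: a 1x1 convolution preserving the
#' original information and three 3x3 dilated convolutions at strictly
#' increasing rates (default 3, 5, 7; kernel spans 7, 11, 15 pixels). Each
#' branch emits C/4 channels and the outputs are channel-concatenated, 1x1
#' branch first then ascending dilation, so the output shape equals the
#' input shape.
#'
#' @param channels Input/output channel count; must be divisible by 4.
#' @param rates Three strictly increasing dilation rates.
#' @param init Weight initialisation scheme.
#' @return An MCIE layer for [mcieForward()].
#' @export
mcieModule <- function(channels, rates = c(3L, 5L, 7L), init = "he") {
  channels <- as.integer(channels)
  if (channels %% 4L != 0L) {
    stop("MCIE needs a channel count divisible by 4 (got ", channels,
         "); choose base_channels as a multiple of 4", call. = FALSE)
  }
  rates <- as.integer(rates)
  if (length(rates) != 3L || any(diff(rates) <= 0L) || any(rates <= 0L)) {
    stop("dilation rates must be three strictly increasing positive integers",
         call. = FALSE)
  }
  cq <- channels %/% 4L
  list(kind = "mcie", rates = rates,
       conv1 = newConv(1L, 1L, channels, cq, init),
       convd = lapply(rates, function(r) newConv(3L, 3L, channels, cq, init)))
}

#' Run the multi-scale context block
#'
#' @param mcie Layer from [mcieModule()].
#' @param u Feature map `(H, W, C[, N])` with C the layer's channel count.
#' @return Feature map of the same shape as `u`.
#' @export
mcieForward <- function(mcie, u) {
  raw <- isRaw(u)
  u <- toNode4(u)
  if (any(!is.finite(u$val))) {
    stop("MCIE input contains non-finite values", call. = FALSE)
  }
  branches <- c(list(convFwd(mcie$conv1, u)),
                lapply(seq_along(mcie$rates), function(m) {
                  convFwd(mcie$convd[[m]], u, dil = mcie$rates[m])
                }))
  y <- agConcatC(branches)
  if (raw) dropTo3d(y$val) else y
}

#' Feature selection structure
#'
#' Selective-kernel-style channel attention over the three context branches.
#' The deeper branches are aligned to the shallowest one — an independent
#' 1x1 convolution maps each to a common channel count, followed by bilinear
#' upsampling — then summed elementwise to a fused map. Global average
#' pooling and two fully connected layers (hidden width
#' `max(C / reduction, 8)`) produce a 3C-vector that a per-channel three-way
#' softmax turns into convex weights `alpha`, `beta`, `gamma`
#' (`alpha_i + beta_i + gamma_i = 1` by construction). The output is the
#' weighted per-channel combination of the aligned branches.
#'
#' @param channels Integer triple: channel counts of the block-3/4/5 inputs;
#'   the first entry is also the common (output) channel count.
#' @param reduction Bottleneck ratio of the fully connected pair, default 16.
#' @param init Weight initialisation scheme.
#' @return An FS layer for [fsForward()].
#' @export
fsModule <- function(channels, reduction = 16L, init = "he") {
  channels <- as.integer(channels)
  stopifnot(length(channels) == 3L)
  cc <- channels[1]
  hidden <- max(cc %/% as.integer(reduction), 8L)
  list(kind = "fs", channels = cc,
       proj4 = newConv(1L, 1L, channels[2], cc, init),
       proj5 = newConv(1L, 1L, channels[3], cc, init),
       fc1 = newDense(cc, hidden, init),
       fc2 = newDense(hidden, 3L * cc, init))
}

agBranchOf3 <- function(s, b) {
  d <- dim(s$val)
  v <- matrix(s$val[b, , ], d[2], d[3])
  agNode(v, list(s), function(g) {
    gs <- array(0, d)
    gs[b, , ] <- g
    list(gs)
  })
}

# Core of the FS structure on tape nodes; `select = FALSE` bypasses the
# attention (plain branch sum), which is the FS-ablated path.
fsForwardNode <- function(fs, u3, u4, u5, select = TRUE) {
  for (nm in c("u3", "u4", "u5")) {
    v <- get(nm)
    if (any(!is.finite(v$val))) {
      stop("FS input ", nm, " contains non-finite values", call. = FALSE)
    }
  }
  d3 <- dim(u3$val)
  b3 <- u3
  b4 <- agResizeBilinear(convFwd(fs$proj4, u4), d3[1], d3[2])
  b5 <- agResizeBilinear(convFwd(fs$proj5, u5), d3[1], d3[2])
  ubar <- agAdd(agAdd(b3, b4), b5)
  if (!select) {
    return(list(v = ubar, alpha = NULL, beta = NULL, gamma = NULL))
  }
  z <- agGap(ubar)
  h <- agRelu(denseFwd(fs$fc1, z))
  s <- denseFwd(fs$fc2, h)                       # (3C, N)
  s3 <- agNode(array(s$val, c(3L, fs$channels, dim(s$val)[2])), list(s),
               function(g) list(matrix(g, nrow = 3L * fs$channels)))
  w <- agSoftmax3(s3)
  alpha <- agBranchOf3(w, 1L)
  beta <- agBranchOf3(w, 2L)
  gamma <- agBranchOf3(w, 3L)
  v <- agAdd(agAdd(agChannelScale(b3, alpha), agChannelScale(b4, beta)),
             agChannelScale(b5, gamma))
  list(v = v, alpha = alpha, beta = beta, gamma = gamma)
}

#' Run the feature selection structure
#'
#' @param fs Layer from [fsModule()].
#' @param u3,u4,u5 Context-branch feature maps (the multi-scale block outputs
#'   of encoder blocks 3-5); different spatial scales are allowed.
#' @return List with `v` (the selected map, u3's shape) and the per-channel
#'   weight matrices `alpha`, `beta`, `gamma` (channels x batch).
#' @export
fsForward <- function(fs, u3, u4, u5) {
  raw <- isRaw(u3, u4, u5)
  out <- fsForwardNode(fs, toNode4(u3), toNode4(u4), toNode4(u5))
  if (raw) {
    list(v = dropTo3d(out$v$val), alpha = out$alpha$val,
         beta = out$beta$val, gamma = out$gamma$val)
  } else {
    out
  }
}

#' Dual-path feature fusion module
#'
#' Fuses the context-path map `H` with the spatial-path map `L`. After
#' alignment (bilinear upsampling of `H` to `L`'s grid and a 1x1 channel
#' projection), the two maps are channel-concatenated and passed through a
#' 3x3 convolution, batch normalisation and ReLU to give `x`; the attention
#' vector is `a = sigmoid(relu(GAP(x)))`, one weight per channel, and the
#' output is `M = a * L + H` (channel-wise broadcast of `a` over `L`).
#'
#' @param high_channels Channel count of the context-path input `H`.
#' @param low_channels Channel count of the spatial-path input `L` (and of
#'   the fused output).
#' @param init Weight initialisation scheme.
#' @return A DFF layer for [dffForward()].
#' @export
dffModule <- function(high_channels, low_channels, init = "he") {
  list(kind = "dff",
       projH = newConv(1L, 1L, as.integer(high_channels),
                       as.integer(low_channels), init),
       convx = newConv(3L, 3L, 2L * as.integer(low_channels),
                       as.integer(low_channels), init),
       bn = newBatchNorm(as.integer(low_channels)))
}

dffForwardNode <- function(dff, h, l, training = FALSE, fuse = TRUE) {
  dl <- dim(l$val)
  h2 <- convFwd(dff$projH, agResizeBilinear(h, dl[1], dl[2]))
  if (dim(h2$val)[3] != dl[3]) {
    stop("DFF channel mismatch after alignment: H has ", dim(h2$val)[3],
         " channels, L has ", dl[3], call. = FALSE)
  }
  if (!fuse) {
    return(list(m = agAdd(h2, l), attention = NULL))
  }
  x <- agRelu(bnFwd(dff$bn, convFwd(dff$convx, agConcatC(list(h2, l))),
                    training = training))
  a <- agSigmoid(agRelu(agGap(x)))
  m <- agAdd(agChannelScale(l, a), h2)
  list(m = m, attention = a)
}

#' Run the dual-path fusion module
#'
#' @param dff Layer from [dffModule()].
#' @param h Context-path feature map (any spatial scale at or below `l`'s).
#' @param l Spatial-path feature map `(H, W, C[, N])`.
#' @param training Logical; use batch statistics (and update running
#'   statistics) in the batch-normalisation step.
#' @return List with `m` (fused map, `l`'s shape) and `attention` (the
#'   per-channel gate, channels x batch).
#' @export
dffForward <- function(dff, h, l, training = FALSE) {
  raw <- isRaw(h, l)
  out <- dffForwardNode(dff, toNode4(h), toNode4(l), training = training)
  if (raw) list(m = dropTo3d(out$m$val), attention = out$attention$val)
  else out
}
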