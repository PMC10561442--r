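# Brute-force oracles kept deliberately independent of the package's
# compiled kernels: plain nested loops and step-by-step arithmetic.

# Internal tape/layer helpers used by white-box tests.
agConst <- adffnet:::agConst
agParam <- adffnet:::agParam
agConv2d <- adffnet:::agConv2d
agResizeBilinear <- adffnet:::agResizeBilinear
agBackward <- adffnet:::agBackward
collectParams <- adffnet:::collectParams
convFwd <- adffnet:::convFwd
ensure4d <- adffnet:::ensure4d
dropTo3d <- adffnet:::dropTo3d

# Nested-loop 2-D convolution with zero padding and dilation.
# x: (H, W, Cin), w: (kh, kw, Cin, Cout), b: length Cout.
oracleConv <- function(x, w, b, pad = c(0L, 0L), dil = c(1L, 1L)) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  pad <- rep(pad, length.out = 2); dil <- rep(dil, length.out = 2)
  Ho <- H + 2 * pad[1] - dil[1] * (kh - 1)
  Wo <- W + 2 * pad[2] - dil[2] * (kw - 1)
  y <- array(0, c(Ho, Wo, Cout))
  for (co in seq_len(Cout)) {
    for (io in seq_len(Ho)) {
      for (jo in seq_len(Wo)) {
        acc <- b[co]
        for (ci in seq_len(Cin)) {
          for (ki in seq_len(kh)) {
            for (kj in seq_len(kw)) {
              i <- io - pad[1] + dil[1] * (ki - 1)
              j <- jo - pad[2] + dil[2] * (kj - 1)
              if (i >= 1 && i <= H && j >= 1 && j <= W) {
                acc <- acc + x[i, j, ci] * w[ki, kj, ci, co]
              }
            }
          }
        }
        y[io, jo, co] <- acc
      }
    }
  }
  y
}

# GAP -> FC -> ReLU -> FC -> per-channel 3-way softmax, by hand.
# ubar: (H, W, C); w1: (d, C); b1: d; w2: (3C, d); b2: 3C.
oracleFsWeights <- function(ubar, w1, b1, w2, b2) {
  C <- dim(ubar)[3]
  z <- apply(ubar, 3, mean)
  h <- pmax(as.numeric(w1 %*% z + b1), 0)
  s <- as.numeric(w2 %*% h + b2)
  s3 <- matrix(s, nrow = 3)            # (3, C): branch-major layout
  w <- apply(s3, 2, function(col) {
    e <- exp(col - max(col))
    e / sum(e)
  })
  list(alpha = w[1, ], beta = w[2, ], gamma = w[3, ])
}

# AUC as the fraction of correctly ordered (positive, negative) score
# pairs, ties counted one half.
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) {
    for (sn in neg) {
      tot <- tot + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  tot / (length(pos) * length(neg))
}

# Laplacian edge map by hand: zero-padded 3x3 convolution, tanh, relu.
oracleLaplaceEdge <- function(t) {
  k <- matrix(c(-1, -1, -1, -1, 8, -1, -1, -1, -1), 3, 3)
  H <- nrow(t); W <- ncol(t)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          v <- if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) t[ii, jj] else 0
          acc <- acc + v * k[di + 2, dj + 2]
        }
      }
      out[i, j] <- max(tanh(acc), 0)
    }
  }
  out
}

randArray <- function(dims, seed) {
  set.seed(seed)
  array(stats::rnorm(prod(dims)), dims)
}

# Default model/train settings used by the small training tests.
deskModelConfig <- function(...) {
  modelConfig(input_size = 64L, base_channels = 8L, ...)
}
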