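# Reverse-mode autodiff tape over dense arrays in (H, W, C, N) layout.
# Nodes are environments; each op records its parents and a closure that maps
# the output adjoint to parent adjoints. Heavy kernels (convolution, pooling,
# resize) live in src/nn_kernels.cpp; everything else is vectorised base R.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

agNextId <- function() {
  .ag$id <- .ag$id + 1L
  .ag$id
}

#' @noRd
agNode <- function(value, parents = list(), backward = NULL, track = NULL) {
  if (is.null(track)) {
    track <- any(vapply(parents, function(p) p$track, logical(1)))
  }
  node <- new.env(parent = emptyenv())
  node$val <- value
  node$parents <- parents
  node$bw <- backward
  node$track <- track
  node$id <- agNextId()
  class(node) <- "agNode"
  node
}

agParam <- function(value) agNode(value, track = TRUE)

agConst <- function(value) agNode(value, track = FALSE)

asNode <- function(x) if (inherits(x, "agNode")) x else agConst(x)

agValue <- function(x) if (inherits(x, "agNode")) x$val else x

# Topologically ordered reverse sweep; returns adjoints for the `wrt` leaves.
agBackward <- function(root, wrt, seed_grad = 1) {
  topo <- vector("list", 256L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$expanded) {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- node
      next
    }
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    stack[[length(stack) + 1L]] <- list(node = node, expanded = TRUE)
    for (p in node$parents) {
      if (p$track && is.null(seen[[as.character(p$id)]])) {
        stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
      }
    }
  }
  grads <- new.env(parent = emptyenv())
  grads[[as.character(root$id)]] <- seed_grad
  for (k in seq_len(ntopo)) {
    node <- topo[[ntopo - k + 1L]]
    g <- grads[[as.character(node$id)]]
    if (is.null(g) || is.null(node$bw)) next
    pg <- node$bw(g)
    for (m in seq_along(node$parents)) {
      p <- node$parents[[m]]
      if (!p$track || is.null(pg[[m]])) next
      key <- as.character(p$id)
      cur <- grads[[key]]
      grads[[key]] <- if (is.null(cur)) pg[[m]] else cur + pg[[m]]
    }
  }
  lapply(wrt, function(p) {
    g <- grads[[as.character(p$id)]]
    if (is.null(g)) p$val * 0 else g
  })
}

# ---- elementwise ----

agAdd <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  agNode(a$val + b$val, list(a, b), function(g) list(g, g))
}

agSub <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  agNode(a$val - b$val, list(a, b), function(g) list(g, -g))
}

agMul <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  agNode(a$val * b$val, list(a, b), function(g) list(g * b$val, g * a$val))
}

agScale <- function(x, k) {
  x <- asNode(x)
  agNode(x$val * k, list(x), function(g) list(g * k))
}

agRelu <- function(x) {
  x <- asNode(x)
  m <- x$val > 0
  agNode(x$val * m, list(x), function(g) list(g * m))
}

agSigmoid <- function(x) {
  x <- asNode(x)
  s <- 1 / (1 + exp(-x$val))
  agNode(s, list(x), function(g) list(g * s * (1 - s)))
}

agTanh <- function(x) {
  x <- asNode(x)
  t <- tanh(x$val)
  agNode(t, list(x), function(g) list(g * (1 - t * t)))
}

agLog <- function(x) {
  x <- asNode(x)
  agNode(log(x$val), list(x), function(g) list(g / x$val))
}

# Clip; adjoint passes only where x was strictly inside the bounds.
agClip <- function(x, lo, hi) {
  x <- asNode(x)
  inside <- x$val > lo & x$val < hi
  agNode(pmin(pmax(x$val, lo), hi), list(x), function(g) list(g * inside))
}

agSum <- function(x) {
  x <- asNode(x)
  d <- dim(x$val)
  agNode(sum(x$val), list(x), function(g) list(array(g, d)))
}

agMean <- function(x) {
  x <- asNode(x)
  d <- dim(x$val)
  n <- length(x$val)
  agNode(sum(x$val) / n, list(x), function(g) list(array(g / n, d)))
}

# ---- structured ops on (H, W, C, N) tensors ----

agConv2d <- function(x, w, b, pad = c(0L, 0L), dil = c(1L, 1L)) {
  x <- asNode(x); w <- asNode(w); b <- asNode(b)
  xd <- dim(x$val); wd <- dim(w$val)
  pad <- rep(as.integer(pad), length.out = 2)
  dil <- rep(as.integer(dil), length.out = 2)
  y <- conv2d_fw(x$val, xd, w$val, wd, b$val, pad[1], pad[2], dil[1], dil[2])
  xv <- x$val
  agNode(y, list(x, w, b), function(g) {
    gx <- if (x$track) {
      conv2d_bw_x(g, xd, w$val, wd, pad[1], pad[2], dil[1], dil[2])
    }
    if (w$track || b$track) {
      gwb <- conv2d_bw_w(xv, xd, g, wd, pad[1], pad[2], dil[1], dil[2])
      list(gx, gwb$gw, gwb$gb)
    } else {
      list(gx, NULL, NULL)
    }
  })
}

# Stride-1 "same" padding for an odd kernel at dilation d.
samePad <- function(k, d = 1L) as.integer(d * (k - 1L) / 2L)

agMaxPool2 <- function(x) {
  x <- asNode(x)
  xd <- dim(x$val)
  out <- maxpool2_fw(x$val, xd)
  agNode(out$y, list(x), function(g) list(maxpool2_bw(g, out$idx, xd)))
}

agResizeBilinear <- function(x, ho, wo) {
  x <- asNode(x)
  xd <- dim(x$val)
  if (xd[1] == ho && xd[2] == wo) return(x)
  y <- resize_bilinear_fw(x$val, xd, as.integer(ho), as.integer(wo))
  agNode(y, list(x), function(g) {
    list(resize_bilinear_bw(g, xd, as.integer(ho), as.integer(wo)))
  })
}

agConcatC <- function(xs) {
  xs <- lapply(xs, asNode)
  ds <- lapply(xs, function(x) dim(x$val))
  cs <- vapply(ds, `[`, integer(1), 3L)
  d0 <- ds[[1]]
  y <- array(0, c(d0[1], d0[2], sum(cs), d0[4]))
  at <- 0L
  for (m in seq_along(xs)) {
    y[, , at + seq_len(cs[m]), ] <- xs[[m]]$val
    at <- at + cs[m]
  }
  agNode(y, xs, function(g) {
    at <- 0L
    out <- vector("list", length(xs))
    for (m in seq_along(xs)) {
      out[[m]] <- g[, , at + seq_len(cs[m]), , drop = FALSE]
      at <- at + cs[m]
    }
    out
  })
}

# Global average pool: (H, W, C, N) -> (C, N).
agGap <- function(x) {
  x <- asNode(x)
  d <- dim(x$val)
  hw <- d[1] * d[2]
  y <- matrix(colMeans(matrix(x$val, nrow = hw)), d[3], d[4])
  agNode(y, list(x), function(g) {
    list(array(rep(as.numeric(g) / hw, each = hw), d))
  })
}

# Dense layer on (in, N) matrices: y = W z + b.
agDense <- function(z, w, b) {
  z <- asNode(z); w <- asNode(w); b <- asNode(b)
  y <- w$val %*% z$val + b$val
  agNode(y, list(z, w, b), function(g) {
    list(crossprod(w$val, g), tcrossprod(g, z$val), rowSums(g))
  })
}

# Softmax over the first margin of a (3, C, N) array.
agSoftmax3 <- function(x) {
  x <- asNode(x)
  d <- dim(x$val)
  m <- matrix(x$val, nrow = d[1])
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  s <- array(sweep(m, 2, colSums(m), "/"), d)
  agNode(s, list(x), function(g) {
    gm <- matrix(g, nrow = d[1]) ; sm <- matrix(s, nrow = d[1])
    dot <- colSums(gm * sm)
    list(array(sm * sweep(gm, 2, dot), d))
  })
}

# Multiply (H, W, C, N) by a per-channel gate a of shape (C, N).
agChannelScale <- function(x, a) {
  x <- asNode(x); a <- asNode(a)
  d <- dim(x$val)
  hw <- d[1] * d[2]
  aa <- array(rep(as.numeric(a$val), each = hw), d)
  agNode(x$val * aa, list(x, a), function(g) {
    ga <- matrix(colSums(matrix(g * x$val, nrow = hw)), d[3], d[4])
    list(g * aa, ga)
  })
}

# Multiply (H, W, C, N) by a single-channel map a of shape (H, W, 1, N).
agSpatialScale <- function(x, a) {
  x <- asNode(x); a <- asNode(a)
  d <- dim(x$val)
  aa <- array(apply(a$val, 4, function(m) rep(m, d[3])), d)
  agNode(x$val * aa, list(x, a), function(g) {
    ga <- array(apply(g * x$val, 4, function(v) {
      rowSums(matrix(v, ncol = d[3]))
    }), dim(a$val))
    list(g * aa, ga)
  })
}

# Batch normalisation over (H, W, N) per channel. `state` is an environment
# holding running_mean / running_var, updated as a side effect in training.
agBatchNorm <- function(x, gamma, beta, state, training = TRUE,
                        eps = 1e-5, momentum = 0.1) {
  x <- asNode(x); gamma <- asNode(gamma); beta <- asNode(beta)
  d <- dim(x$val)
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  xp <- matrix(aperm(x$val, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(xp)
    va <- colMeans(xp^2) - mu^2
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xp, 2, mu), 2, inv, "*")
  yp <- sweep(sweep(xhat, 2, as.numeric(gamma$val), "*"), 2,
              as.numeric(beta$val), "+")
  y <- aperm(array(yp, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  agNode(y, list(x, gamma, beta), function(g) {
    gp <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
    dgamma <- colSums(gp * xhat)
    dbeta <- colSums(gp)
    gx <- if (x$track) {
      dxhat <- sweep(gp, 2, as.numeric(gamma$val), "*")
      if (training) {
        t1 <- sweep(dxhat, 2, colMeans(dxhat))
        t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
        gxp <- sweep(t1 - t2, 2, inv, "*")
      } else {
        gxp <- sweep(dxhat, 2, inv, "*")
      }
      aperm(array(gxp, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    }
    list(gx, dgamma, dbeta)
  })
}
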