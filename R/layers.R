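# Parameterised layer constructors. A layer is a plain list whose agNode
# parameters can be inspected or overwritten (they are environments, so
# `layer$w$val <- ...` takes effect in-place) — tests rely on this to pin
# weights against brute-force oracles.

initSd <- function(fan_in, init) {
  switch(init, he = sqrt(2 / fan_in), standard_gaussian = 1,
         stop("unknown init: ", init))
}

newConv <- function(kh, kw, cin, cout, init = "he") {
  sd <- initSd(kh * kw * cin, init)
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout))
  list(kind = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       w = agParam(w), b = agParam(rep(0, cout)))
}

convFwd <- function(layer, x, dil = 1L) {
  agConv2d(x, layer$w, layer$b,
           pad = c(samePad(layer$kh, dil), samePad(layer$kw, dil)),
           dil = c(dil, dil))
}

newDense <- function(cin, cout, init = "he") {
  w <- matrix(stats::rnorm(cout * cin, sd = initSd(cin, init)), cout, cin)
  list(kind = "dense", w = agParam(w), b = agParam(rep(0, cout)))
}

denseFwd <- function(layer, z) agDense(z, layer$w, layer$b)

newBatchNorm <- function(channels) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- rep(0, channels)
  state$running_var <- rep(1, channels)
  list(kind = "bn", gamma = agParam(rep(1, channels)),
       beta = agParam(rep(0, channels)), state = state)
}

bnFwd <- function(layer, x, training = TRUE) {
  agBatchNorm(x, layer$gamma, layer$beta, layer$state, training = training)
}

# Recursively gather every agNode parameter in a (nested) layer structure,
# named by path.
collectParams <- function(x, prefix = "") {
  if (inherits(x, "agNode")) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    nms <- names(x) %||% rep("", length(x))
    for (k in seq_along(x)) {
      nm <- if (nzchar(nms[k])) nms[k] else as.character(k)
      if (nm %in% c("state", "kind", "kh", "kw", "cin", "cout")) next
      out <- c(out, collectParams(x[[k]],
                                  if (nzchar(prefix)) paste0(prefix, ".", nm)
                                  else nm))
    }
    return(out)
  }
  list()
}

# Nearest-neighbour resize (linear scatter/gather), used by the optional
# nearest prediction head.
agResizeNearest <- function(x, ho, wo) {
  x <- asNode(x)
  d <- dim(x$val)
  if (d[1] == ho && d[2] == wo) return(x)
  ri <- pmin(pmax(floor((seq_len(ho) - 0.5) * d[1] / ho) + 1, 1), d[1])
  rj <- pmin(pmax(floor((seq_len(wo) - 0.5) * d[2] / wo) + 1, 1), d[2])
  y <- x$val[ri, rj, , , drop = FALSE]
  agNode(y, list(x), function(g) {
    gx <- array(0, d)
    for (a in seq_len(ho)) {
      for (b in seq_len(wo)) {
        gx[ri[a], rj[b], , ] <- gx[ri[a], rj[b], , ] + g[a, b, , ]
      }
    }
    list(gx)
  })
}

ensure4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array with dim attribute", call. = FALSE)
  if (length(d) == 2L) {
    x <- array(x, c(d, 1L, 1L))
  } else if (length(d) == 3L) {
    x <- array(x, c(d, 1L))
  } else if (length(d) != 4L) {
    stop("expected a rank 2-4 array, got rank ", length(d), call. = FALSE)
  }
  x
}

dropTo3d <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4] == 1L) array(x, d[1:3]) else x
}
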