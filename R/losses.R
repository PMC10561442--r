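# The multivariate loss: Laplacian semantic-boundary extraction, the
# boundary-oriented class-weighted cross-entropy, mean binary cross-entropy,
# the two-sided smoothed Dice loss, and their weighted total. Exported
# functions operate on plain arrays; the training loop uses the tape
# versions below so the total is differentiable end-to-end in p.

laplaceKernel <- function() {
  array(c(-1, -1, -1, -1, 8, -1, -1, -1, -1), c(3L, 3L, 1L, 1L))
}

asMask4 <- function(t, what = "mask") {
  d <- dim(t)
  if (is.null(d)) stop(what, " must be an array", call. = FALSE)
  if (length(d) == 2L) t <- array(t, c(d, 1L, 1L))
  else if (length(d) == 3L) t <- array(t, c(d, 1L))
  d <- dim(t)
  if (d[3] != 1L) {
    stop(what, " must be single-channel, got ", d[3], " channels",
         call. = FALSE)
  }
  t
}

# Tape version: x is a single-channel (H, W, 1, N) node.
agLaplaceEdge <- function(x) {
  agRelu(agTanh(agConv2d(x, agConst(laplaceKernel()), agConst(0),
                         pad = c(1L, 1L))))
}

#' Laplacian semantic-boundary map
#'
#' Convolves a single-channel mask (binary ground truth or continuous
#' probability) with the fixed 3x3 Laplacian kernel (centre 8, neighbours
#' -1; zero padding, same size), then applies tanh and ReLU. The result is
#' zero wherever the input is locally constant and lies in \[0, 1).
#'
#' @param t Single-channel array `(H, W)`, `(H, W, 1)` or `(H, W, 1, N)`
#'   with values in \[0, 1\].
#' @return Edge map of the same shape as `t`.
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 1
#' laplaceEdgeMap(m)[3, 3]   # tanh(8) clipped by ReLU
#' @export
laplaceEdgeMap <- function(t) {
  d0 <- dim(t)
  e <- agLaplaceEdge(agConst(asMask4(t, "edge-map input")))$val
  array(e, d0)
}

#' Boundary weight
#'
#' The ratio of summed boundary-map activations to summed mask pixels,
#' `W = sum(E_t) / sum(T)`; always in \[0, 1\] because each mask pixel's edge
#' activation is at most tanh(8) < 1 and interior pixels contribute 0.
#' An empty mask yields `W = 0` with a warning.
#'
#' @param e_t Edge map derived from `t` via [laplaceEdgeMap()].
#' @param t Binary ground-truth mask of the same shape.
#' @return Scalar weight in \[0, 1\].
#' @export
boundaryWeight <- function(e_t, t) {
  st <- sum(t)
  if (st == 0) {
    warning("empty ground-truth mask: boundary weight set to 0")
    return(0)
  }
  sum(e_t) / st
}

clipProb <- function(p, clip) pmin(pmax(p, clip), 1 - clip)

#' Boundary-oriented loss
#'
#' Class-weighted cross-entropy between the predicted and true boundary
#' maps, with the boundary weight `w` balancing the sparse edge class:
#' `-mean(w * E_t * log(E_p) + (1 - w) * (1 - E_t) * log(1 - E_p))`.
#' `e_p` is clipped to `[clip, 1 - clip]` before the logarithms.
#'
#' @param e_p Predicted boundary map.
#' @param e_t True boundary map, same shape.
#' @param w Boundary weight from [boundaryWeight()].
#' @param clip Clipping bound, default 1e-7.
#' @return Nonnegative finite scalar.
#' @export
boundaryLoss <- function(e_p, e_t, w, clip = 1e-7) {
  if (!identical(dim(e_p), dim(e_t))) {
    stop("e_p and e_t shapes differ", call. = FALSE)
  }
  ep <- clipProb(e_p, clip)
  -mean(w * e_t * log(ep) + (1 - w) * (1 - e_t) * log(1 - ep))
}

#' Binary cross-entropy loss
#'
#' Mean pixelwise `-(T log P + (1 - T) log(1 - P))` with `p` clipped to
#' `[clip, 1 - clip]`.
#'
#' @param p Probability mask in \[0, 1\].
#' @param t Binary mask, same shape.
#' @param clip Clipping bound, default 1e-7.
#' @return Nonnegative finite scalar.
#' @export
bceLoss <- function(p, t, clip = 1e-7) {
  if (!identical(dim(p), dim(t))) stop("p and t shapes differ", call. = FALSE)
  pc <- clipProb(p, clip)
  -mean(t * log(pc) + (1 - t) * log(1 - pc))
}

#' Two-sided smoothed Dice loss
#'
#' `1 - (sum(PT) + eps) / (sum(P + T) + eps)
#'    - (sum((1-P)(1-T)) + eps) / (sum(2 - P - T) + eps)`.
#' With the default `eps = 1` the loss can be slightly negative on tiny
#' inputs (bounded below by -1); it approaches 0 for perfect balanced
#' predictions as N grows.
#'
#' @param p Probability mask.
#' @param t Binary mask, same shape.
#' @param epsilon Smoothing constant, default 1.
#' @return Scalar in \[-1, 1\].
#' @export
diceLoss <- function(p, t, epsilon = 1) {
  if (!identical(dim(p), dim(t))) stop("p and t shapes differ", call. = FALSE)
  stopifnot(epsilon > 0)
  1 - (sum(p * t) + epsilon) / (sum(p + t) + epsilon) -
    (sum((1 - p) * (1 - t)) + epsilon) / (sum(2 - p - t) + epsilon)
}

# ---- tape versions for training ----

agSlice4 <- function(x, n) {
  d <- dim(x$val)
  v <- x$val[, , , n, drop = FALSE]
  agNode(v, list(x), function(g) {
    gx <- array(0, d)
    gx[, , , n] <- g
    list(gx)
  })
}

agDiv <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  agNode(a$val / b$val, list(a, b), function(g) {
    list(g / b$val, -g * a$val / b$val^2)
  })
}

# p: (H, W, 1, N) node; t: (H, W, 1, N) array. Returns scalar nodes for the
# total and each component; the boundary weight is computed per sample.
agTotalLoss <- function(p, t, cfg = lossConfig()) {
  d <- dim(t)
  n <- d[4]
  et <- agLaplaceEdge(agConst(t))$val
  ep <- agClip(agLaplaceEdge(p), cfg$clip, 1 - cfg$clip)
  pc <- agClip(p, cfg$clip, 1 - cfg$clip)
  ws <- numeric(n)
  le <- NULL
  ld <- NULL
  for (m in seq_len(n)) {
    tm <- t[, , , m, drop = FALSE]
    st <- sum(tm)
    w <- if (st > 0) sum(et[, , , m]) / st else 0
    ws[m] <- w
    epm <- agSlice4(ep, m)
    etm <- agConst(et[, , , m, drop = FALSE])
    term <- agAdd(agScale(agMul(etm, agLog(epm)), w),
                  agScale(agMul(agSub(1, etm), agLog(agSub(1, epm))),
                          1 - w))
    lem <- agScale(agMean(term), -1)
    le <- if (is.null(le)) lem else agAdd(le, lem)
    # two-sided Dice, per sample
    pm <- agSlice4(p, m)
    tmn <- agConst(tm)
    spt <- agSum(agMul(pm, tmn))
    sp <- agSum(pm)
    fg <- agDiv(agAdd(spt, cfg$epsilon),
                agAdd(agAdd(sp, sum(tm)), cfg$epsilon))
    sqt <- agSum(agMul(agSub(1, pm), agConst(1 - tm)))
    bg <- agDiv(agAdd(sqt, cfg$epsilon),
                agAdd(agSub(2 * prod(d[1:3]) - sum(tm), sp), cfg$epsilon))
    ldm <- agSub(agSub(1, fg), bg)
    ld <- if (is.null(ld)) ldm else agAdd(ld, ldm)
  }
  le <- agScale(le, 1 / n)
  ld <- agScale(ld, 1 / n)
  tn <- agConst(t)
  lbce <- agScale(agMean(agAdd(agMul(tn, agLog(pc)),
                               agMul(agSub(1, tn), agLog(agSub(1, pc))))),
                  -1)
  total <- agAdd(agAdd(agScale(le, cfg$lambda1), agScale(lbce, cfg$lambda2)),
                 agScale(ld, cfg$lambda3))
  list(total = total, l_e = le, l_bce = lbce, l_dice = ld, w = ws)
}

#' Multivariate total loss
#'
#' Computes the weighted total
#' `lambda1 * L_E + lambda2 * L_BCE + lambda3 * L_Dice` of the boundary,
#' cross-entropy and two-sided Dice components. The true and predicted
#' boundary maps are derived internally with [laplaceEdgeMap()] (the
#' predicted map from the continuous probabilities, keeping the loss
#' differentiable), and the boundary weight is computed per sample.
#'
#' @param p Probability mask `(H, W)`, `(H, W, 1)` or `(H, W, 1, N)`.
#' @param t Binary mask of the same shape.
#' @param cfg A [lossConfig()].
#' @param grad If `TRUE`, also return the gradient of the total with respect
#'   to `p` (reverse-mode, same shape as `p`).
#' @return List with `total`, `components` (named numeric: `l_e`, `l_bce`,
#'   `l_dice`), `w` (per-sample boundary weights) and, if requested, `grad`.
#' @examples
#' t <- matrix(0, 8, 8); t[3:6, 3:6] <- 1
#' p <- 0.5 * (t + 0.5 * (1 - t))
#' totalLoss(p, t)$components
#' @export
totalLoss <- function(p, t, cfg = lossConfig(), grad = FALSE) {
  if (!identical(dim(p), dim(t))) stop("p and t shapes differ", call. = FALSE)
  d0 <- dim(p)
  p4 <- asMask4(p, "probability mask")
  t4 <- asMask4(t, "ground-truth mask")
  pn <- if (grad) agParam(p4) else agConst(p4)
  out <- agTotalLoss(pn, t4, cfg)
  res <- list(total = out$total$val,
              components = c(l_e = out$l_e$val, l_bce = out$l_bce$val,
                             l_dice = out$l_dice$val),
              w = out$w)
  if (grad) {
    res$grad <- array(agBackward(out$total, list(pn))[[1]], d0)
  }
  res
}

#' Dice coefficient
#'
#' `2 * sum(P T) / (sum(P) + sum(T))` with a small smoothing constant; the
#' validation metric monitored during training.
#'
#' @param p Probability mask.
#' @param t Binary mask, same shape.
#' @param epsilon Smoothing constant, default 1e-7.
#' @return Scalar in \[0, 1\].
#' @export
diceCoefficient <- function(p, t, epsilon = 1e-7) {
  if (!identical(dim(p), dim(t))) stop("p and t shapes differ", call. = FALSE)
  (2 * sum(p * t) + epsilon) / (sum(p) + sum(t) + epsilon)
}
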