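# The tape and its structured ops: forward values against brute force,
# adjoints against finite differences and transpose identities.

test_that("compiled convolution agrees with the nested-loop oracle", {
  set.seed(1)
  cases <- list(
    list(x = c(9, 9, 2), w = c(3, 3, 2, 3), pad = c(1, 1), dil = c(1, 1)),
    list(x = c(7, 8, 1), w = c(1, 3, 1, 2), pad = c(0, 1), dil = c(1, 1)),
    list(x = c(8, 7, 2), w = c(3, 1, 2, 1), pad = c(1, 0), dil = c(1, 1)),
    list(x = c(9, 9, 1), w = c(3, 3, 1, 1), pad = c(5, 5), dil = c(5, 5)))
  for (cs in cases) {
    x <- array(rnorm(prod(cs$x)), cs$x)
    w <- array(rnorm(prod(cs$w)), cs$w)
    b <- rnorm(cs$w[4])
    got <- agConv2d(agConst(ensure4d(x)), agConst(w), agConst(b),
                    pad = cs$pad, dil = cs$dil)$val
    expect_equal(dropTo3d(got), oracleConv(x, w, b, cs$pad, cs$dil),
                 tolerance = 1e-10)
  }
})

test_that("convolution adjoints pass the finite-difference check", {
  set.seed(2)
  x <- agParam(array(rnorm(6 * 6 * 2), c(6, 6, 2, 1)))
  w <- agParam(array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2)))
  b <- agParam(rnorm(2))
  loss <- function() {
    y <- agConv2d(x, w, b, pad = c(1, 1))
    adffnet:::agSum(adffnet:::agMul(y, y))
  }
  root <- loss()
  g <- agBackward(root, list(x, w, b))
  eps <- 1e-6
  for (k in 1:3) {
    target <- list(x, w, b)[[k]]
    idx <- sample(length(target$val), min(5, length(target$val)))
    for (i in idx) {
      v0 <- target$val[i]
      target$val[i] <- v0 + eps; fp <- loss()$val
      target$val[i] <- v0 - eps; fm <- loss()$val
      target$val[i] <- v0
      expect_equal(g[[k]][i], (fp - fm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("max pooling takes block maxima and routes gradients to them", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  out <- adffnet:::agMaxPool2(agParam(x))
  expect_equal(as.numeric(out$val),
               c(max(x[1:2, 1:2, 1, 1]), max(x[3:4, 1:2, 1, 1]),
                 max(x[1:2, 3:4, 1, 1]), max(x[3:4, 3:4, 1, 1])))
  xp <- agParam(x)
  y <- adffnet:::agMaxPool2(xp)
  g <- agBackward(adffnet:::agSum(y), list(xp))[[1]]
  expect_equal(sum(g), 4)           # one unit per pooled window
  for (pos in list(c(2, 2), c(4, 2), c(2, 4), c(4, 4))) {
    expect_equal(g[pos[1], pos[2], 1, 1], 1)   # gradient hits each argmax
  }
})

test_that("bilinear resize is linear with a true transpose adjoint", {
  set.seed(3)
  x <- array(rnorm(5 * 5), c(5, 5, 1, 1))
  y <- array(rnorm(9 * 9), c(9, 9, 1, 1))
  xp <- agParam(x)
  fwd <- agResizeBilinear(xp, 9, 9)
  # <A x, y> == <x, A' y>
  lhs <- sum(fwd$val * y)
  node <- agResizeBilinear(xp, 9, 9)
  aty <- agBackward(adffnet:::agSum(adffnet:::agMul(node, agConst(y))),
                    list(xp))[[1]]
  expect_equal(lhs, sum(x * aty), tolerance = 1e-10)
  # interpolation preserves constants and the value range
  cst <- agResizeBilinear(agConst(array(2.5, c(4, 4, 1, 1))), 7, 7)$val
  expect_true(all(abs(cst - 2.5) < 1e-12))
  r <- agResizeBilinear(agConst(ensure4d(matrix(runif(16), 4, 4))), 8, 8)$val
  expect_gte(min(r), 0); expect_lte(max(r), 1)
})

test_that("batch normalisation normalises and backpropagates correctly", {
  set.seed(4)
  bn <- adffnet:::newBatchNorm(3)
  x <- agParam(array(rnorm(6 * 6 * 3 * 2, mean = 2, sd = 3), c(6, 6, 3, 2)))
  y <- adffnet:::bnFwd(bn, x, training = TRUE)
  for (c in 1:3) {
    vals <- y$val[, , c, ]
    expect_lt(abs(mean(vals)), 1e-10)
    expect_equal(stats::var(as.numeric(vals)) * (length(vals) - 1) /
                   length(vals), 1, tolerance = 1e-3)
  }
  # finite differences through the batch statistics
  loss <- function() {
    yy <- adffnet:::bnFwd(bn, x, training = TRUE)
    adffnet:::agSum(adffnet:::agMul(yy, agConst(w)))
  }
  w <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  g <- agBackward(loss(), list(x, bn$gamma, bn$beta))
  eps <- 1e-5
  for (i in sample(length(x$val), 4)) {
    v0 <- x$val[i]
    x$val[i] <- v0 + eps; fp <- loss()$val
    x$val[i] <- v0 - eps; fm <- loss()$val
    x$val[i] <- v0
    expect_equal(g[[1]][i], (fp - fm) / (2 * eps), tolerance = 1e-3)
  }
})

test_that("softmax over three branches is a proper simplex map", {
  set.seed(5)
  s <- agParam(array(rnorm(3 * 4 * 2), c(3, 4, 2)))
  w <- adffnet:::agSoftmax3(s)
  expect_true(all(abs(apply(w$val, c(2, 3), sum) - 1) < 1e-12))
  expect_true(all(w$val > 0 & w$val < 1))
  # gradient check
  tgt <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  loss <- function() adffnet:::agSum(adffnet:::agMul(
    adffnet:::agSoftmax3(s), agConst(tgt)))
  g <- agBackward(loss(), list(s))[[1]]
  eps <- 1e-6
  for (i in sample(length(s$val), 5)) {
    v0 <- s$val[i]
    s$val[i] <- v0 + eps; fp <- loss()$val
    s$val[i] <- v0 - eps; fm <- loss()$val
    s$val[i] <- v0
    expect_equal(g[i], (fp - fm) / (2 * eps), tolerance = 1e-5)
  }
})
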