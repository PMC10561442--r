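# The bespoke blocks against brute-force oracles and their closed-form
# degenerate cases.

zeroParams <- function(layer) {
  for (p in collectParams(layer)) p$val <- p$val * 0
  layer
}

test_that("BR strip convolutions match the nested-loop oracle", {
  set.seed(42)
  br <- brModule(channels = 1, k = 3)
  c1 <- randArray(c(10, 10, 1), 1)
  c2 <- randArray(c(5, 5, 1), 2)
  out <- brForward(br, c1, c2)
  # recompute by hand: upsample, two strip-conv branches, sigmoid, gate
  c2p <- resizeImage(matrix(c2, 5, 5), 10, "bilinear")
  x1 <- oracleConv(oracleConv(array(c2p, c(10, 10, 1)),
                              br$conv1a$w$val, br$conv1a$b$val,
                              pad = c(0, 1)),
                   br$conv1b$w$val, br$conv1b$b$val, pad = c(1, 0))
  x2 <- oracleConv(oracleConv(array(c2p, c(10, 10, 1)),
                              br$conv2a$w$val, br$conv2a$b$val,
                              pad = c(1, 0)),
                   br$conv2b$w$val, br$conv2b$b$val, pad = c(0, 1))
  a <- 1 / (1 + exp(-(x1 + x2)))
  expect_equal(out$attention, array(a, c(10, 10, 1)), tolerance = 1e-6)
  expect_equal(out$x, array(c1 * as.numeric(a), c(10, 10, 1)),
               tolerance = 1e-6)
})

test_that("BR with zero parameters gives A = 0.5 and X = C1 / 2", {
  br <- zeroParams(brModule(channels = 3, k = 3))
  c1 <- randArray(c(8, 8, 2), 3)
  c2 <- randArray(c(4, 4, 3), 4)
  out <- brForward(br, c1, c2)
  expect_equal(as.numeric(out$attention), rep(0.5, 64))
  expect_equal(out$x, c1 * 0.5)
})

test_that("BR attention is bounded and |X| <= |C1| elementwise", {
  set.seed(7)
  for (rep in 1:5) {
    br <- brModule(channels = 4, k = 5)
    c1 <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
    c2 <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
    out <- brForward(br, c1, c2)
    expect_true(all(out$attention > 0 & out$attention < 1))
    expect_true(all(abs(out$x) <= abs(c1)))
  }
})

test_that("BR rejects even kernels and non-half-scale inputs", {
  expect_error(brModule(channels = 2, k = 4), "odd")
  br <- brModule(channels = 2, k = 3)
  expect_error(brForward(br, randArray(c(8, 8, 2), 1),
                         randArray(c(8, 8, 2), 2)), "half")
})

test_that("dilated convolution matches the brute-force oracle on 9x9", {
  x <- randArray(c(9, 9, 1), 5)
  w <- array(1, c(3, 3, 1, 1))   # rate-3 3x3 kernel of ones
  b <- 0
  got <- agConv2d(agConst(array(x, c(9, 9, 1, 1))), agConst(w), agConst(b),
                  pad = c(3, 3), dil = c(3, 3))$val
  expect_equal(array(got, c(9, 9, 1)), oracleConv(x, w, b, c(3, 3), c(3, 3)),
               tolerance = 1e-10)
  # random kernel too
  w2 <- randArray(c(3, 3, 1, 2), 6)
  got2 <- agConv2d(agConst(array(x, c(9, 9, 1, 1))), agConst(w2),
                   agConst(c(0.3, -0.2)), pad = c(3, 3), dil = c(3, 3))$val
  expect_equal(array(got2, c(9, 9, 2)),
               oracleConv(x, w2, c(0.3, -0.2), c(3, 3), c(3, 3)),
               tolerance = 1e-10)
})

test_that("MCIE preserves shape, fixes branch order, and needs C %% 4 == 0", {
  expect_error(mcieModule(channels = 6), "divisible by 4")
  set.seed(8)
  mc <- mcieModule(channels = 8)
  u <- randArray(c(12, 12, 8), 9)
  y <- mcieForward(mc, u)
  expect_identical(dim(y), dim(u))
  # branch order: zeroing all but the 1x1 branch leaves only channels 1-2
  mc0 <- mcieModule(channels = 8)
  for (m in 1:3) {
    mc0$convd[[m]]$w$val <- mc0$convd[[m]]$w$val * 0
  }
  y0 <- mcieForward(mc0, u)
  expect_true(all(abs(y0[, , 3:8]) < 1e-12))
  expect_true(any(abs(y0[, , 1:2]) > 0))
  # full MCIE against the composed oracle
  manual <- array(0, dim(u))
  manual[, , 1:2] <- oracleConv(u, mc$conv1$w$val, mc$conv1$b$val)
  for (m in 1:3) {
    r <- mc$rates[m]
    manual[, , (2 * m + 1):(2 * m + 2)] <-
      oracleConv(u, mc$convd[[m]]$w$val, mc$convd[[m]]$b$val,
                 pad = c(r, r), dil = c(r, r))
  }
  expect_equal(y, manual, tolerance = 1e-8)
})

test_that("MCIE of a constant input is constant per channel in the interior", {
  set.seed(10)
  mc <- mcieModule(channels = 4)
  u <- array(0.7, c(18, 18, 4))
  y <- mcieForward(mc, u)
  # interior pixels whose widest dilated tap (offset max rate) stays inside
  r <- max(mc$rates)
  inner <- y[(r + 1):(18 - r), (r + 1):(18 - r), , drop = FALSE]
  for (c in seq_len(dim(inner)[3])) {
    expect_lt(diff(range(inner[, , c])), 1e-10)
  }
})

test_that("MCIE rejects non-finite input naming the problem", {
  mc <- mcieModule(channels = 4)
  u <- array(1, c(8, 8, 4)); u[1] <- NA
  expect_error(mcieForward(mc, u), "non-finite")
})

test_that("FS weights are convex per channel and reproduce the FC oracle", {
  set.seed(11)
  fs <- fsModule(channels = c(8, 8, 8))
  u3 <- randArray(c(6, 6, 8), 12)
  u4 <- randArray(c(3, 3, 8), 13)
  u5 <- randArray(c(3, 3, 8), 14)
  out <- fsForward(fs, u3, u4, u5)
  sums <- out$alpha + out$beta + out$gamma
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(out$alpha >= 0 & out$alpha <= 1))
  # oracle on the actual aligned sum
  b4 <- resizeImage(oracleConv(u4, fs$proj4$w$val, fs$proj4$b$val), 6,
                    "bilinear")
  b5 <- resizeImage(oracleConv(u5, fs$proj5$w$val, fs$proj5$b$val), 6,
                    "bilinear")
  ubar <- u3 + b4 + b5
  ow <- oracleFsWeights(ubar, fs$fc1$w$val, fs$fc1$b$val,
                        fs$fc2$w$val, fs$fc2$b$val)
  expect_equal(as.numeric(out$alpha), ow$alpha, tolerance = 1e-6)
  expect_equal(as.numeric(out$beta), ow$beta, tolerance = 1e-6)
  expect_equal(as.numeric(out$gamma), ow$gamma, tolerance = 1e-6)
  # V lies in the elementwise convex hull of the aligned branches
  v <- out$v
  lo <- pmin(u3, b4, b5); hi <- pmax(u3, b4, b5)
  expect_true(all(v >= lo - 1e-10 & v <= hi + 1e-10))
})

test_that("FS with identical aligned branches returns the branch exactly", {
  set.seed(15)
  fs <- fsModule(channels = c(4, 4, 4))
  # identity projections
  for (nm in c("proj4", "proj5")) {
    w <- fs[[nm]]$w$val * 0
    for (i in 1:4) w[1, 1, i, i] <- 1
    fs[[nm]]$w$val <- w
    fs[[nm]]$b$val <- fs[[nm]]$b$val * 0
  }
  u <- randArray(c(5, 5, 4), 16)
  out <- fsForward(fs, u, u, u)
  expect_equal(out$v, u, tolerance = 1e-8)
})

test_that("FS weights match a hand-evaluated GAP-FC-softmax chain", {
  fs <- fsModule(channels = c(8, 8, 8))
  ubar <- randArray(c(4, 4, 8), 17)
  ow <- oracleFsWeights(ubar, fs$fc1$w$val, fs$fc1$b$val,
                        fs$fc2$w$val, fs$fc2$b$val)
  # run the same chain through the package path by feeding ubar as u3 with
  # zeroed deeper branches
  fs$proj4$w$val <- fs$proj4$w$val * 0
  fs$proj5$w$val <- fs$proj5$w$val * 0
  out <- fsForward(fs, ubar, ubar, ubar)
  expect_equal(as.numeric(out$alpha), ow$alpha, tolerance = 1e-6)
  expect_equal(as.numeric(out$gamma), ow$gamma, tolerance = 1e-6)
})

test_that("DFF matches a step-by-step oracle of the fusion chain", {
  set.seed(18)
  dff <- dffModule(high_channels = 2, low_channels = 2)
  h <- randArray(c(4, 4, 2), 19)
  l <- randArray(c(4, 4, 2), 20)
  out <- dffForward(dff, h, l, training = TRUE)
  # oracle: proj, concat, conv, batch norm (batch stats), relu, gap chain
  h2 <- oracleConv(h, dff$projH$w$val, dff$projH$b$val)
  cat2 <- array(c(h2, l), c(4, 4, 4))
  xc <- oracleConv(cat2, dff$convx$w$val, dff$convx$b$val, pad = c(1, 1))
  mu <- apply(xc, 3, mean)
  va <- apply(xc, 3, function(m) mean((m - mean(m))^2))
  xb <- xc
  for (c in 1:2) xb[, , c] <- (xc[, , c] - mu[c]) / sqrt(va[c] + 1e-5)
  xr <- pmax(xb, 0)
  a <- 1 / (1 + exp(-pmax(apply(xr, 3, mean), 0)))
  m <- xb * 0
  for (c in 1:2) m[, , c] <- a[c] * l[, , c] + h2[, , c]
  expect_equal(as.numeric(out$attention), a, tolerance = 1e-5)
  expect_equal(out$m, m, tolerance = 1e-5)
  expect_true(all(out$attention > 0 & out$attention < 1))
})

test_that("DFF with zero fusion weights reduces to M = 0.5 L + H", {
  set.seed(21)
  dff <- dffModule(high_channels = 2, low_channels = 3)
  dff$convx$w$val <- dff$convx$w$val * 0
  h <- randArray(c(4, 4, 2), 22)
  l <- randArray(c(8, 8, 3), 23)
  out <- dffForward(dff, h, l, training = TRUE)
  h2node <- convFwd(dff$projH,
                    agResizeBilinear(agConst(ensure4d(h)), 8, 8))
  expect_equal(as.numeric(out$attention), rep(0.5, 3))
  expect_equal(out$m, dropTo3d(h2node$val) + 0.5 * l, tolerance = 1e-10)
})
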