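# Loss components against closed forms and brute-force summation oracles.

test_that("Laplacian edge map has the stated kernel behaviour", {
  # single centre spike on a 5x5 grid vs the nested-loop oracle
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  expect_equal(laplaceEdgeMap(m), oracleLaplaceEdge(m), tolerance = 1e-10)
  expect_equal(laplaceEdgeMap(m)[3, 3], tanh(8))
  # constant masks (all 0, all 1) give identically zero edges
  expect_true(all(laplaceEdgeMap(matrix(0, 7, 7)) == 0))
  expect_true(all(laplaceEdgeMap(matrix(1, 9, 9))[2:8, 2:8] == 0))
  # edges only within one pixel of a value change
  sq <- matrix(0, 12, 12); sq[4:9, 4:9] <- 1
  e <- laplaceEdgeMap(sq)
  expect_true(all(e >= 0 & e < 1))
  dist1 <- matrix(FALSE, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    nb <- sq[max(1, i - 1):min(12, i + 1), max(1, j - 1):min(12, j + 1)]
    dist1[i, j] <- length(unique(as.numeric(nb))) > 1
  }
  expect_true(all(e[!dist1] == 0))
  # random masks vs oracle
  set.seed(1)
  r <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_equal(laplaceEdgeMap(r), oracleLaplaceEdge(r), tolerance = 1e-10)
  expect_error(laplaceEdgeMap(array(0, c(4, 4, 2))), "single-channel")
})

test_that("boundary weight is the edge/mass ratio and stays in [0, 1]", {
  # degenerate: e_t = t gives 1; e_t = 0 gives 0
  t <- matrix(0, 6, 6); t[3, 3] <- 1
  expect_equal(boundaryWeight(t, t), 1)
  expect_equal(boundaryWeight(t * 0, t), 0)
  expect_warning(w0 <- boundaryWeight(matrix(0, 4, 4), matrix(0, 4, 4)),
                 "empty")
  expect_equal(w0, 0)
  # 8x8 centred 4x4 square: every mask pixel borders the background,
  # so the numerator is the sum of 16 per-pixel tanh activations
  sq <- matrix(0, 8, 8); sq[3:6, 3:6] <- 1
  e <- laplaceEdgeMap(sq)
  expect_equal(boundaryWeight(e, sq), sum(e) / 16)
  # corner pixels lose 3 neighbours (lap = 8-5*1 = 3... enumerate by hand:
  # corner keeps 3 foreground neighbours -> 8 - 3 = 5; edge pixel keeps 5
  expect_equal(e[3, 3], tanh(5))
  expect_equal(e[3, 4], tanh(3))
  expect_true(all(e[4:5, 4:5] == 0))
  # random masks: W in [0, 1]
  set.seed(2)
  for (rep in 1:20) {
    m <- matrix(rbinom(100, 1, runif(1, 0.05, 0.9)), 10, 10)
    if (sum(m) == 0) next
    w <- boundaryWeight(laplaceEdgeMap(m), m)
    expect_gte(w, 0); expect_lte(w, 1)
  }
})

test_that("boundary loss matches closed forms and the summation oracle", {
  # perfect binary prediction: loss ~ 0 up to clip effects
  e <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_lt(boundaryLoss(e, e, w = 0.4), 1e-6)
  # e_t = 0, e_p = 0.5 -> (1 - w) log 2
  for (w in c(0, 0.3, 1)) {
    expect_equal(boundaryLoss(matrix(0.5, 3, 3), matrix(0, 3, 3), w),
                 (1 - w) * log(2), tolerance = 1e-12)
  }
  # random 6x6 instance vs the double-loop oracle
  set.seed(3)
  et <- matrix(runif(36), 6, 6)
  ep <- matrix(runif(36, 0.05, 0.95), 6, 6)
  w <- 0.3
  acc <- 0
  for (i in 1:6) for (j in 1:6) {
    acc <- acc - (w * et[i, j] * log(ep[i, j]) +
                  (1 - w) * (1 - et[i, j]) * log(1 - ep[i, j]))
  }
  expect_equal(boundaryLoss(ep, et, w), acc / 36, tolerance = 1e-8)
  expect_error(boundaryLoss(matrix(0.5, 2, 2), matrix(0, 3, 3), 0.5),
               "differ")
})

test_that("BCE matches closed forms and a direct summation oracle", {
  t <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(bceLoss(t, t), 1e-5)
  expect_equal(bceLoss(matrix(0.5, 4, 4), matrix(rbinom(16, 1, 0.5), 4, 4)),
               log(2), tolerance = 1e-12)
  set.seed(4)
  p <- matrix(runif(16, 0.01, 0.99), 4, 4)
  tt <- matrix(rbinom(16, 1, 0.5), 4, 4)
  acc <- -sum(tt * log(p) + (1 - tt) * log(1 - p)) / 16
  expect_equal(bceLoss(p, tt), acc, tolerance = 1e-10)
})

test_that("BCE over constant predictions is minimised at the foreground rate", {
  set.seed(5)
  t <- matrix(rbinom(400, 1, 0.3), 20, 20)
  rate <- mean(t)
  grid <- seq(0.02, 0.98, by = 0.02)
  losses <- vapply(grid, function(p) {
    bceLoss(matrix(p, 20, 20), t)
  }, numeric(1))
  best <- grid[which.min(losses)]
  expect_lt(abs(best - rate), 0.021)
  expect_gte(bceLoss(matrix(0.9, 20, 20), t), bceLoss(matrix(rate, 20, 20), t))
})

test_that("two-sided Dice loss evaluates exactly and vanishes in the limit", {
  # all-ones 2x2 with eps = 1: 1 - 5/9 - 1 = -5/9
  p <- matrix(1, 2, 2)
  expect_equal(diceLoss(p, p, epsilon = 1), 1 - 5 / 9 - 1)
  # perfect balanced prediction at large N tends to 0
  n <- 80
  t <- matrix(0, n, n); t[1:(n / 2), ] <- 1
  expect_lt(abs(diceLoss(t, t, epsilon = 1)), 1e-3)
  expect_gte(diceLoss(t, 1 - t, epsilon = 1), 0.9)
  # never below -1
  set.seed(6)
  for (rep in 1:10) {
    pp <- matrix(runif(9), 3, 3); tt <- matrix(rbinom(9, 1, 0.5), 3, 3)
    expect_gte(diceLoss(pp, tt), -1)
  }
})

test_that("total loss is the stated weighted sum with per-sample weights", {
  set.seed(7)
  t <- matrix(0, 8, 8); t[3:6, 3:6] <- 1
  p <- matrix(runif(64, 0.1, 0.9), 8, 8)
  out <- totalLoss(p, t)
  et <- laplaceEdgeMap(t)
  w <- boundaryWeight(et, t)
  expect_equal(out$w, w)
  expect_equal(out$components[["l_e"]],
               boundaryLoss(laplaceEdgeMap(p), et, w), tolerance = 1e-10)
  expect_equal(out$components[["l_bce"]], bceLoss(p, t), tolerance = 1e-12)
  expect_equal(out$components[["l_dice"]], diceLoss(p, t), tolerance = 1e-12)
  expect_equal(out$total,
               0.2 * out$components[["l_e"]] + out$components[["l_bce"]] +
                 out$components[["l_dice"]], tolerance = 1e-12)
  # custom weights scale linearly
  cfg <- lossConfig(lambda1 = 2, lambda2 = 0.5, lambda3 = 0)
  out2 <- totalLoss(p, t, cfg)
  expect_equal(out2$total, 2 * out$components[["l_e"]] +
                 0.5 * out$components[["l_bce"]], tolerance = 1e-12)
})

test_that("total loss gradient agrees with central finite differences", {
  set.seed(8)
  t <- matrix(rbinom(16, 1, 0.4), 4, 4)
  p <- matrix(runif(16, 0.2, 0.8), 4, 4)
  g <- totalLoss(p, t, grad = TRUE)$grad
  expect_true(all(is.finite(g)))
  eps <- 1e-6
  fd <- p * 0
  for (i in 1:4) for (j in 1:4) {
    pp <- p; pp[i, j] <- pp[i, j] + eps
    pm <- p; pm[i, j] <- pm[i, j] - eps
    fd[i, j] <- (totalLoss(pp, t)$total - totalLoss(pm, t)$total) / (2 * eps)
  }
  expect_lt(max(abs(fd - g)) / max(abs(fd)), 1e-3)
})

test_that("dice coefficient gives the expected values on binary fixtures", {
  t <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2, 4)
  expect_equal(diceCoefficient(t, t), 1, tolerance = 1e-6)
  expect_lt(diceCoefficient(t, 1 - t), 1e-6)
  # tp = 3, fp = 1, fn = 1 -> 2*3 / (4 + 4)
  p <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  tt <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  dim(p) <- c(10, 1); dim(tt) <- c(10, 1)
  expect_equal(diceCoefficient(p, tt), 0.75, tolerance = 1e-6)
})
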