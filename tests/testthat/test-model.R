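# Network architecture: parameter accounting, forward well-posedness,
# determinism, and exact layer gradients.

test_that("parameter totals and per-block subtotals match the design", {
  net3 <- buildCnn3d()
  expect_equal(countParameters(net3), 1757267)
  tab <- paramCountTable(net3)
  expect_equal(tab$n_params[match(c("b1", "b2", "b3", "b4", "head"),
                                  tab$part)],
               c(14290, 83072, 332032, 1327616, 257))
  net2 <- buildCnn2d()
  expect_equal(countParameters(net2), 388547)
  tab2 <- paramCountTable(net2)
  expect_equal(tab2$n_params[tab2$part == "head"], 257)
  # regression and classification heads share every parameter shape
  reg <- buildCnn3d("regression")
  expect_identical(lapply(netParams(reg), dim),
                   lapply(netParams(net3), dim))
})

test_that("the head weight alone accounts for 256 weights plus bias", {
  p <- netParams(buildCnn2d())
  expect_equal(length(p$head_w) + length(p$head_b), 257)
})

test_that("forward passes are finite, shape-agnostic and deterministic", {
  net3 <- buildCnn3d(initSeed = 3)
  # the standard full-size input
  o <- netForward(net3, list(array(0, c(90, 75, 75))))$out
  expect_length(o, 1)
  expect_true(is.finite(o))
  # any admissible size yields one scalar per sample
  set.seed(1)
  vols <- lapply(1:3, function(i) array(rnorm(16 * 20 * 18),
                                        c(16, 20, 18)))
  o2 <- netForward(net3, vols)$out
  expect_length(o2, 3)
  expect_true(all(is.finite(o2)))
  # eval-mode forward is deterministic
  expect_identical(o2, netForward(net3, vols)$out)
  # batching does not change the per-sample outputs
  expect_equal(o2, sapply(vols, function(v)
    netForward(net3, list(v))$out), tolerance = 1e-10)

  net2 <- buildCnn2d(initSeed = 3)
  o3 <- netForward(net2, list(matrix(0, 75, 75)))$out
  expect_true(is.finite(o3))
  expect_error(netForward(net3, list(array(0, c(8, 20, 20)))), "16")
  expect_error(netForward(net3, list(matrix(0, 20, 20))), "3-D")
})

test_that("initialization is reproducible per seed", {
  expect_identical(netParams(buildCnn3d(initSeed = 5)),
                   netParams(buildCnn3d(initSeed = 5)))
  expect_false(identical(netParams(buildCnn3d(initSeed = 5)),
                         netParams(buildCnn3d(initSeed = 6))))
})

test_that("external encoder weights can be loaded by name", {
  net <- buildCnn3d(initSeed = 1)
  w <- netParams(net)$b1u1_conv_w
  w[] <- 0.25
  net2 <- loadEncoderWeights(net, list(b1u1_conv_w = w))
  expect_true(all(netParams(net2)$b1u1_conv_w == 0.25))
  expect_error(loadEncoderWeights(net, list(nope = w)), "unknown")
  expect_error(loadEncoderWeights(net, list(b1u1_conv_w = matrix(0, 2, 2))),
               "shape")
})

# ---- exact layer gradients against central differences -------------------

relerr <- function(a, b) abs(a - b) / pmax(1e-8, abs(a) + abs(b))

test_that("convolution gradients match finite differences exactly", {
  eps <- 1e-6
  set.seed(1)
  for (case in list(list(spdim = c(3, 4, 5), K = 27),
                    list(spdim = c(5, 6), K = 9))) {
    spdim <- case$spdim; S <- prod(spdim); N <- 2
    Cin <- 3; Cout <- 2
    x <- matrix(rnorm(S * N * Cin), S * N, Cin)
    W <- matrix(rnorm(case$K * Cin * Cout) * 0.2, case$K * Cin, Cout)
    b <- rnorm(Cout)
    R <- matrix(rnorm(S * N * Cout), S * N, Cout)
    loss <- function(x, W, b)
      sum(cellcyclekit:::.nnConvFwd(x, W, b, spdim, N, FALSE)$y * R)
    fw <- cellcyclekit:::.nnConvFwd(x, W, b, spdim, N, TRUE)
    bw <- cellcyclekit:::.nnConvBwd(R, W, fw$P, spdim, N)
    mx <- 0
    for (t in 1:25) {
      i <- sample(length(x), 1)
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      mx <- max(mx, relerr((loss(xp, W, b) - loss(xm, W, b)) / (2 * eps),
                           bw$dx[i]))
    }
    for (t in 1:25) {
      i <- sample(length(W), 1)
      Wp <- W; Wp[i] <- Wp[i] + eps
      Wm <- W; Wm[i] <- Wm[i] - eps
      mx <- max(mx, relerr((loss(x, Wp, b) - loss(x, Wm, b)) / (2 * eps),
                           bw$dW[i]))
    }
    expect_lt(mx, 1e-5)
  }
})

test_that("both conv backward routes (scatter and gather) agree", {
  set.seed(2)
  spdim <- c(4, 5, 6); S <- prod(spdim); N <- 2
  # Cin > Cout forces the gather route; transpose the task for scatter
  Cin <- 4; Cout <- 2
  x <- matrix(rnorm(S * N * Cin), S * N, Cin)
  W <- matrix(rnorm(27 * Cin * Cout) * 0.2, 27 * Cin, Cout)
  dy <- matrix(rnorm(S * N * Cout), S * N, Cout)
  fw <- cellcyclekit:::.nnConvFwd(x, W, NULL, spdim, N, TRUE)
  bwGather <- cellcyclekit:::.nnConvBwd(dy, W, fw$P, spdim, N)
  # numerical dx as ground truth for the gather route
  eps <- 1e-6
  for (t in 1:10) {
    i <- sample(length(x), 1)
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (sum(cellcyclekit:::.nnConvFwd(xp, W, NULL, spdim, N,
                                          FALSE)$y * dy) -
            sum(cellcyclekit:::.nnConvFwd(xm, W, NULL, spdim, N,
                                          FALSE)$y * dy)) / (2 * eps)
    expect_lt(relerr(num, bwGather$dx[i]), 1e-5)
  }
})

test_that("group normalization gradients match finite differences", {
  eps <- 1e-6
  set.seed(3)
  spdim <- c(3, 4, 5); S <- prod(spdim); N <- 2
  C <- 8; ng <- 4
  x <- matrix(rnorm(S * N * C), S * N, C)
  gam <- runif(C, 0.5, 1.5); bet <- rnorm(C)
  R <- matrix(rnorm(S * N * C), S * N, C)
  loss <- function(x, gam, bet)
    sum(cellcyclekit:::.nnGnFwd(x, gam, bet, ng, S, N)$y * R)
  fg <- cellcyclekit:::.nnGnFwd(x, gam, bet, ng, S, N)
  bg <- cellcyclekit:::.nnGnBwd(R, fg, gam, ng, S, N)
  mx <- 0
  for (t in 1:40) {
    i <- sample(length(x), 1)
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    mx <- max(mx, relerr((loss(xp, gam, bet) - loss(xm, gam, bet)) /
                           (2 * eps), bg$dx[i]))
  }
  for (i in seq_len(C)) {
    gp <- gam; gp[i] <- gp[i] + eps; gm <- gam; gm[i] <- gm[i] - eps
    mx <- max(mx, relerr((loss(x, gp, bet) - loss(x, gm, bet)) / (2 * eps),
                         bg$dgamma[i]))
    bp <- bet; bp[i] <- bp[i] + eps; bm <- bet; bm[i] <- bm[i] - eps
    mx <- max(mx, relerr((loss(x, gam, bp) - loss(x, gam, bm)) / (2 * eps),
                         bg$dbeta[i]))
  }
  expect_lt(mx, 1e-5)
})

test_that("max-pooling equals blockwise maxima and routes gradients to them", {
  set.seed(4)
  spdim <- c(5, 4, 6); S <- prod(spdim); N <- 2; C <- 3
  x <- matrix(sample(seq_len(S * N * C)) * 0.37, S * N, C)  # no ties
  fp <- cellcyclekit:::.nnPoolFwd(x, spdim, N)
  arr <- array(x[seq_len(S), 1], spdim)
  y <- array(fp$y[seq_len(prod(spdim %/% 2)), 1], spdim %/% 2)
  for (z in 1:2) for (yy in 1:2) for (xx in 1:3)
    expect_equal(y[z, yy, xx],
                 max(arr[(2 * z - 1):(2 * z), (2 * yy - 1):(2 * yy),
                         (2 * xx - 1):(2 * xx)]))
  R <- matrix(rnorm(length(fp$y)), nrow(fp$y), C)
  bp <- cellcyclekit:::.nnPoolBwd(R, fp, N)
  eps <- 1e-6
  for (t in 1:40) {
    i <- sample(length(x), 1)
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (sum(cellcyclekit:::.nnPoolFwd(xp, spdim, N)$y * R) -
            sum(cellcyclekit:::.nnPoolFwd(xm, spdim, N)$y * R)) / (2 * eps)
    expect_lt(relerr(num, bp[i]), 1e-5)
  }
})
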