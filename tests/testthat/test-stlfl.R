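test_that("scatter building blocks match hand arithmetic", {
  # 1-channel, 1-sample epochs {class1: 0, 2; class2: 4, 6}
  arr <- array(c(0, 2, 4, 6), dim = c(4, 1, 1))
  ep <- epoch_set(arr, labels = c(1L, 1L, 2L, 2L), fs = 1)
  sc <- compute_scatters(ep)
  expect_equal(drop(sc$m1), 1)
  expect_equal(drop(sc$m2), 5)
  expect_equal(drop(sc$m), 3)
  expect_equal(drop(sc$Db1), -2)
  expect_equal(drop(sc$Db2), 2)
  expect_equal(drop(sc$Dw), c(-1, 1, -1, 1))
})

test_that("within-class differences vanish when epochs equal their class mean", {
  base <- matrix(rnorm(6), 2, 3)
  arr <- array(0, dim = c(4, 2, 3))
  arr[1, , ] <- base; arr[2, , ] <- base          # class 1
  arr[3, , ] <- -base; arr[4, , ] <- -base        # class 2
  sc <- compute_scatters(epoch_set(arr, c(1L, 1L, 2L, 2L), fs = 1))
  expect_equal(max(abs(sc$Dw)), 0)
  # balanced classes: the grand mean is the midpoint
  expect_equal(sc$Db1 + sc$Db2, matrix(0, 2, 3))
  one <- epoch_set(arr[1:2, , , drop = FALSE], c(1L, 1L), fs = 1)
  expect_error(compute_scatters(one), "both classes")
})

test_that("the LFL pencil solves scalar and degenerate cases exactly", {
  sol <- lfl_direction(matrix(8), matrix(2), beta = 0, h = 1)
  expect_equal(sol$values, 4, tolerance = 1e-5)
  expect_equal(abs(drop(sol$vectors)), 1)

  # identical pencil: every eigenvalue is 1
  S <- rand_psd(5, seed = 3)
  sol2 <- lfl_direction(S, S, beta = 0, h = 5)
  expect_equal(sol2$values, rep(1, 5), tolerance = 1e-4)

  expect_error(lfl_direction(matrix(1:4, 2), rand_psd(2, 1), h = 1),
               "symmetric")
  expect_error(lfl_direction(rand_psd(3, 1), rand_psd(3, 2), h = 4),
               "exceeds")
})

test_that("returned eigenpairs satisfy the generalized eigen equation", {
  for (seed in 1:10) {
    d <- 6
    SW <- rand_psd(d, seed = seed)
    SB <- rand_psd(d, seed = seed + 100, rank = 2)
    beta <- 0.3
    ridge <- 1e-6
    sol <- lfl_direction(SB, SW, beta = beta, h = 3, ridge_eps = ridge)
    eps <- ridge * sum(diag(SW)) / d
    A <- SB - beta * SW
    B <- SW + diag(eps, d)
    for (j in 1:3) {
      w <- sol$vectors[, j]
      resid <- A %*% w - sol$values[j] * (B %*% w)
      expect_lt(sqrt(sum(resid^2)), 1e-8 * sqrt(sum(w^2)))
    }
  }
})

test_that("LFL with alpha = 1, beta = 0 recovers the classic Fisher direction", {
  for (seed in 1:25) {
    fx <- make_planted_epochs(n_per_class = 30, C = 5, T_ = 1,
                              strength = 1.5, seed = seed)
    sc <- compute_scatters(fx$epochs)
    Dw <- matrix(sc$Dw[, , 1], dim(sc$Dw)[1], dim(sc$Dw)[2])
    SW <- crossprod(Dw)
    SB_N <- tcrossprod(sc$Db1[, 1]) + tcrossprod(sc$Db2[, 1])
    w <- drop(lfl_direction(SB_N, SW, beta = 0, h = 1)$vectors)
    # closed-form Fisher direction for a rank-1 between-class scatter
    eps <- 1e-6 * sum(diag(SW)) / nrow(SW)
    w_fld <- solve(SW + diag(eps, nrow(SW)),
                   drop(sc$m2[, 1] - sc$m1[, 1]))
    expect_gte(abs(stlfl:::.cosine(w, w_fld)), 1 - 1e-6)
  }
})

test_that("balanced classes make the numerator proportional to the FLD pencil", {
  fx <- make_planted_epochs(n_per_class = 20, C = 4, T_ = 6, seed = 5)
  sc <- compute_scatters(fx$epochs)
  V <- diag(6)[, 1:2]
  SB <- stlfl:::.stlfl_pencils(sc, V, "spatial", alpha = 1)$SB
  dmv <- (sc$m2 - sc$m1) %*% V
  expect_equal(SB, tcrossprod(dmv) / 2, tolerance = 1e-10)
})

test_that("the alternating fit recovers planted spatial/temporal structure", {
  fx <- make_planted_epochs(n_per_class = 120, C = 6, T_ = 14,
                            strength = 4, noise_sd = 1, seed = 2)
  m <- stlfl(fx$epochs, alpha = 1, beta = 0, h = 2)
  expect_true(m$converged)
  expect_gte(abs(stlfl:::.cosine(m$W[, 1], fx$a)), 0.95)
  expect_gte(abs(stlfl:::.cosine(m$V[, 1], fx$b)), 0.95)
})

test_that("fits are deterministic and scale-invariant", {
  fx <- make_planted_epochs(n_per_class = 25, C = 5, T_ = 8, seed = 3)
  m1 <- stlfl(fx$epochs, h = 3)
  m2 <- stlfl(fx$epochs, h = 3)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$V, m2$V)

  scaled <- fx$epochs
  scaled$data <- scaled$data * 7
  m3 <- stlfl(scaled, h = 3)
  expect_equal(m3$W, m1$W, tolerance = 1e-6)
  expect_equal(m3$V, m1$V, tolerance = 1e-6)
})

test_that("identical classes yield no discriminative projection", {
  stlfl:::with_seed(10, {
    arr <- array(rnorm(400 * 4 * 6), dim = c(400, 4, 6))
    ep <- epoch_set(arr, labels = rep(1:2, 200), fs = 10)
    m <- stlfl(ep, alpha = 1, beta = 0, h = 2, max_iter = 50)
    f <- predict(m, ep)
    expect_lt(biserial_r2(f$features[, 1], f$labels), 0.1)
  })
})

test_that("feature projection is vec(W'XV), column-major, h^2-dimensional", {
  fx <- make_planted_epochs(n_per_class = 5, C = 5, T_ = 7, seed = 4)
  m <- stlfl(fx$epochs, h = 2, max_iter = 5)
  f <- predict(m, fx$epochs)
  expect_equal(ncol(f$features), 4L)
  X1 <- matrix(fx$epochs$data[3, , ], 5, 7)
  expect_equal(f$features[3, ],
               as.vector(t(m$W) %*% X1 %*% m$V), tolerance = 1e-12)

  # identity projections slice out the leading block
  m$W <- diag(5)[, 1:2]; m$V <- diag(7)[, 1:2]
  f2 <- predict(m, fx$epochs)
  expect_equal(f2$features[3, ], as.vector(X1[1:2, 1:2]))

  zero <- fx$epochs
  zero$data[] <- 0
  expect_equal(max(abs(predict(m, zero)$features)), 0)

  m4 <- stlfl(fx$epochs, h = 4, max_iter = 5)
  expect_equal(ncol(predict(m4, fx$epochs)$features), 16L)
  bad <- make_planted_epochs(n_per_class = 3, C = 4, T_ = 7, seed = 1)
  expect_error(predict(m, bad$epochs), "dimensions")
})

test_that("STLFL with averaging temporal projection reduces to FLD in time-mean space", {
  fx <- make_planted_epochs(n_per_class = 40, C = 5, T_ = 8,
                            strength = 2, seed = 6)
  sc <- compute_scatters(fx$epochs)
  v_avg <- matrix(1 / sqrt(8), 8, 1)
  p <- stlfl:::.stlfl_pencils(sc, v_avg, "spatial", alpha = 1)
  w <- drop(lfl_direction(p$SB, p$SW, beta = 0, h = 1)$vectors)
  # classic FLD on time-averaged epochs
  Xavg <- apply(fx$epochs$data, c(1, 2), mean)
  f <- fld(Xavg, labels = fx$epochs$labels)
  expect_gte(abs(stlfl:::.cosine(w, f$direction)), 1 - 1e-6)
})

test_that("the vectorized Fisher baseline separates simple classes", {
  stlfl:::with_seed(11, {
    X <- rbind(matrix(rnorm(500, 2), 250, 2), matrix(rnorm(500, 0), 250, 2))
    y <- rep(1:2, each = 250)
    f <- fld(X, labels = y)
    sc <- predict(f, X)
    expect_gt(mean(sc[y == 1]), mean(sc[y == 2]))
  })
  # equals lfl_direction with alpha = 1, beta = 0 on the same scatters
  fx <- make_planted_epochs(n_per_class = 50, C = 3, T_ = 4, seed = 8)
  f <- fld(fx$epochs)
  d <- dim(fx$epochs$data)
  X <- matrix(fx$epochs$data, d[1], d[2] * d[3])
  m1 <- colMeans(X[fx$epochs$labels == 1, ]);
  m2 <- colMeans(X[fx$epochs$labels == 2, ])
  Xc <- X
  Xc[fx$epochs$labels == 1, ] <- sweep(X[fx$epochs$labels == 1, ], 2, m1)
  Xc[fx$epochs$labels == 2, ] <- sweep(X[fx$epochs$labels == 2, ], 2, m2)
  w2 <- drop(lfl_direction(tcrossprod(m2 - m1), crossprod(Xc), beta = 0,
                           h = 1)$vectors)
  expect_gte(abs(stlfl:::.cosine(f$direction, w2)), 1 - 1e-8)
})

test_that("the alternating iteration converges on planted rank-1 problems", {
  conv <- vapply(1:50, function(i) {
    fx <- make_planted_epochs(n_per_class = 100, C = 6, T_ = 14,
                              strength = 2, seed = 400 + i)
    stlfl(fx$epochs, alpha = 1, beta = 0, h = 4)$converged
  }, logical(1))
  expect_gte(mean(conv), 0.95)
})

test_that("infeasible projection rank is rejected", {
  fx <- make_planted_epochs(n_per_class = 5, C = 3, T_ = 6, seed = 1)
  expect_error(stlfl(fx$epochs, h = 4), "exceeds")
  nas <- fx$epochs
  nas$data[1, 1, 1] <- NA
  expect_error(epoch_set(nas$data, nas$labels, fs = 1), "NA")
})
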