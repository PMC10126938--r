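test_that("closed-form posterior matches symmetry and bias limits", {
  par <- list(W = matrix(0, 4, 3), U = matrix(0, 2, 3), b_v = rep(0, 4),
              c_h = rep(0, 3), d_y = c(0, 0))
  X <- matrix(rnorm(20), 5, 4)
  P <- stlfl:::.drbm_posterior(par, X)
  expect_equal(P, matrix(0.5, 5, 2), ignore_attr = TRUE)

  par$d_y <- c(10, -10)
  P2 <- stlfl:::.drbm_posterior(par, X)
  expect_true(all(P2[, 1] > 0.999999))
})

test_that("posterior equals brute-force enumeration over hidden states", {
  for (seed in 1:6) {
    par <- rand_drbm_par(d = 4, H = 3, seed = seed)
    X <- stlfl:::with_seed(seed + 50, matrix(rnorm(6 * 4), 6, 4))
    P <- stlfl:::.drbm_posterior(par, X)
    P_ref <- enum_drbm_posterior(par, X)
    expect_lt(max(abs(P - P_ref)), 1e-10)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  }
})

test_that("label permutation permutes posterior columns exactly", {
  par <- rand_drbm_par(d = 3, H = 4, seed = 2)
  X <- stlfl:::with_seed(9, matrix(rnorm(15), 5, 3))
  P <- stlfl:::.drbm_posterior(par, X)
  par_sw <- par
  par_sw$U <- par$U[2:1, ]
  par_sw$d_y <- par$d_y[2:1]
  P_sw <- stlfl:::.drbm_posterior(par_sw, X)
  expect_equal(P, P_sw[, 2:1], tolerance = 1e-14)
})

test_that("analytic discriminative gradient matches central finite differences", {
  par <- rand_drbm_par(d = 3, H = 2, seed = 4)
  X <- stlfl:::with_seed(13, matrix(rnorm(5 * 3), 5, 3))
  y <- c(1L, 2L, 1L, 2L, 2L)
  g <- stlfl:::.drbm_disc_grad(par, X, y)
  eps <- 1e-6
  for (nm in c("W", "U", "c_h", "d_y")) {
    v <- par[[nm]]
    for (i in seq_along(v)) {
      pp <- par; pm <- par
      pp[[nm]][i] <- pp[[nm]][i] + eps
      pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (stlfl:::.drbm_disc_negloglik(pm, X, y) -
               stlfl:::.drbm_disc_negloglik(pp, X, y)) / (2 * eps)
      denom <- max(abs(fd), abs(g[[nm]][i]), 1e-8)
      expect_lt(abs(fd - g[[nm]][i]) / denom, 1e-4)
    }
  }
})

test_that("a small DRBM learns linearly separable blobs", {
  dat <- stlfl:::with_seed(21, {
    X <- rbind(matrix(rnorm(200, 2, 0.5), 100, 2),
               matrix(rnorm(200, -2, 0.5), 100, 2))
    list(X = X, y = rep(1:2, each = 100))
  })
  m <- drbm(dat$X, dat$y, n_hidden = 5, generative_weight = 0,
            n_epochs = 200, seed = 5)
  acc <- mean(predict(m, dat$X, type = "class") == dat$y)
  expect_gte(acc, 0.98)
  # loss decreased over training
  expect_lt(tail(m$trace, 1), m$trace[1])
})

test_that("training is deterministic given the seed", {
  dat <- stlfl:::with_seed(22, {
    list(X = matrix(rnorm(200), 50, 4), y = rep(1:2, 25))
  })
  m1 <- drbm(dat$X, dat$y, n_epochs = 20, seed = 9)
  m2 <- drbm(dat$X, dat$y, n_epochs = 20, seed = 9)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$d_y, m2$d_y)
  m3 <- drbm(dat$X, dat$y, n_epochs = 20, seed = 10)
  expect_false(identical(m1$W, m3$W))
  expect_error(drbm(dat$X, dat$y, n_epochs = 5), "seed")
})

test_that("scores are posterior target probabilities with exact complements", {
  dat <- stlfl:::with_seed(23, {
    list(X = matrix(rnorm(120), 30, 4), y = rep(1:2, 15))
  })
  m <- drbm(dat$X, dat$y, n_epochs = 30, seed = 2)
  P <- predict(m, dat$X, type = "prob")
  s <- score_p300(m, dat$X)
  expect_equal(s, P[, 1])
  expect_true(all(s > 0 & s < 1))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_error(predict(m, dat$X[, 1:2]), "mismatch")
})

test_that("the hybrid generative term keeps training stable and seeded", {
  dat <- stlfl:::with_seed(24, {
    X <- rbind(matrix(rnorm(80, 1.5), 40, 2),
               matrix(rnorm(80, -1.5), 40, 2))
    list(X = X, y = rep(1:2, each = 40))
  })
  m1 <- drbm(dat$X, dat$y, generative_weight = 0.05, n_epochs = 250,
             seed = 31)
  m2 <- drbm(dat$X, dat$y, generative_weight = 0.05, n_epochs = 250,
             seed = 31)
  expect_identical(m1$W, m2$W)
  expect_true(all(is.finite(m1$trace)))
  acc <- mean(predict(m1, dat$X, type = "class") == dat$y)
  expect_gte(acc, 0.95)
})

test_that("pipeline features at high SNR separate target scores", {
  s <- make_rcp_session(n_characters = 3, n_repetitions = 5, snr_db = 10,
                        seed = 15)
  ep <- preprocess_session(s, dataset_profile("bci_comp"), balance = TRUE,
                           seed = 1)
  mod <- stlfl(ep, h = 4)
  f <- predict(mod, ep)
  clf <- drbm(f, n_epochs = 80, seed = 3)
  sc <- score_p300(clf, f)
  expect_gt(mean(sc[f$labels == 1]), mean(sc[f$labels == 2]))
})
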