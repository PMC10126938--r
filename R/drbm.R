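# Hybrid discriminative restricted Boltzmann machine over real-valued
# features. Energy (Gaussian visible units x, binary hidden h, 1-of-K
# class y):  E = ||x - b||^2/2 - c'h - x'Wh - d_y - h'U_y.
# The class posterior is available in closed form and does not involve the
# Gaussian term:  p(y|x) prop exp(d_y) prod_j (1 + exp(c_j + U[y,j] + (W'x)_j)).

# log(1 + exp(z)) without overflow
.softplus <- function(z) {
  out <- z
  small <- z < 30
  out[small] <- log1p(exp(z[small]))
  out
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Exact class posterior for a parameter list (W d x H, U K x H, c_h H,
# d_y K) and standardized features X (n x d). Returns n x K, rows sum to 1.
.drbm_posterior <- function(par, X) {
  K <- length(par$d_y)
  n <- nrow(X)
  XW <- X %*% par$W                                    # n x H
  logpot <- matrix(NA_real_, n, K)
  for (y in seq_len(K)) {
    O <- sweep(XW, 2L, par$c_h + par$U[y, ], "+")
    logpot[, y] <- par$d_y[y] + rowSums(.softplus(O))
  }
  mx <- apply(logpot, 1L, max)
  P <- exp(logpot - mx)
  P / rowSums(P)
}

# Total discriminative negative log-likelihood.
.drbm_disc_negloglik <- function(par, X, y) {
  P <- .drbm_posterior(par, X)
  -sum(log(pmax(P[cbind(seq_len(nrow(X)), y)], 1e-300)))
}

# Analytic gradient of the summed log p(y|x) w.r.t. all parameters
# (b_v does not enter the posterior).
.drbm_disc_grad <- function(par, X, y) {
  K <- length(par$d_y)
  n <- nrow(X)
  H <- ncol(par$W)
  XW <- X %*% par$W
  S <- vector("list", K)
  logpot <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    O <- sweep(XW, 2L, par$c_h + par$U[k, ], "+")
    S[[k]] <- .sigmoid(O)
    logpot[, k] <- par$d_y[k] + rowSums(.softplus(O))
  }
  mx <- apply(logpot, 1L, max)
  P <- exp(logpot - mx)
  P <- P / rowSums(P)

  Strue <- matrix(NA_real_, n, H)
  for (k in seq_len(K)) {
    idx <- which(y == k)
    if (length(idx)) Strue[idx, ] <- S[[k]][idx, , drop = FALSE]
  }
  Sbar <- matrix(0, n, H)
  for (k in seq_len(K)) Sbar <- Sbar + P[, k] * S[[k]]
  R <- Strue - Sbar                                    # n x H
  Y1 <- matrix(0, n, K)
  Y1[cbind(seq_len(n), y)] <- 1
  D <- Y1 - P
  gU <- matrix(0, K, H)
  for (k in seq_len(K)) {
    gU[k, ] <- colSums(D[, k] * S[[k]])
  }
  list(W = crossprod(X, R), U = gU, c_h = colSums(R), d_y = colSums(D),
       b_v = rep(0, nrow(par$W)))
}

#' Fit a hybrid discriminative restricted Boltzmann machine
#'
#' A three-layer energy model — Gaussian visible units for the (z-scored)
#' features, `n_hidden` binary hidden units, and a 1-of-K class layer —
#' trained by seeded mini-batch gradient ascent on the hybrid objective
#' `sum log p(y|x) + gamma * sum log p(x, y)`: the discriminative term by
#' its exact gradient (the posterior is closed-form), the generative term
#' by contrastive divergence (CD-k).
#'
#' @param x Feature matrix `n x d` or an `stlfl_features` object.
#' @param y Labels in `{1, 2}` (1 = target/P300); taken from `x` when it is
#'   an `stlfl_features` object.
#' @param n_hidden Number of hidden units (default 5).
#' @param learning_rate Step size.
#' @param n_epochs Training epochs (full passes).
#' @param batch_size Mini-batch size.
#' @param generative_weight `gamma >= 0` mixing in the generative CD term;
#'   0 gives a purely discriminative model.
#' @param cd_steps Gibbs steps for CD (default 1).
#' @param seed Mandatory seed: determines initialization, batch order, and
#'   CD sampling.
#' @param weight_init_sd SD of the Gaussian weight initialization.
#' @param standardize Z-score features with training mean/SD (stored and
#'   re-applied at prediction time).
#' @return An object of class `drbm` with the parameter list (`W`, `U`,
#'   `b_v`, `c_h`, `d_y`), the standardizer, the config, and the
#'   per-epoch mean discriminative loss trace.
#' @export
drbm <- function(x, y = NULL, n_hidden = 5L, learning_rate = 0.05,
                 n_epochs = 500L, batch_size = 32L,
                 generative_weight = 0.01, cd_steps = 1L, seed,
                 weight_init_sd = 0.01, standardize = TRUE) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (inherits(x, "stlfl_features")) {
    if (is.null(y)) y <- x$labels
    x <- x$features
  }
  X <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("labels do not match feature rows",
                                 call. = FALSE)
  if (!all(y %in% c(1L, 2L)) || length(unique(y)) < 2L) {
    stop("labels must be in {1, 2} with both classes present",
         call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) stop("features must be finite",
                                           call. = FALSE)
  n_hidden <- .check_count(n_hidden, "n_hidden")
  n_epochs <- .check_count(n_epochs, "n_epochs")
  batch_size <- .check_count(batch_size, "batch_size")
  cd_steps <- .check_count(cd_steps, "cd_steps")
  learning_rate <- .check_scalar(learning_rate, "learning_rate", 1e-12)
  gamma <- .check_scalar(generative_weight, "generative_weight", 0)
  seed <- .check_count(seed, "seed", min = 0L)

  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  if (standardize) X <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  d <- ncol(X); K <- 2L; H <- n_hidden
  n <- nrow(X)

  trace <- numeric(n_epochs)
  par <- with_seed(seed, {
    par <- list(
      W = matrix(stats::rnorm(d * H, 0, weight_init_sd), d, H),
      U = matrix(stats::rnorm(K * H, 0, weight_init_sd), K, H),
      b_v = rep(0, d), c_h = rep(0, H), d_y = rep(0, K)
    )
    for (ep in seq_len(n_epochs)) {
      ord <- sample.int(n)
      starts <- seq.int(1L, n, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        nb <- length(idx)
        g <- .drbm_disc_grad(par, Xb, yb)
        if (gamma > 0) {
          gg <- .drbm_cd_grad(par, Xb, yb, cd_steps)
          for (nm in names(g)) g[[nm]] <- g[[nm]] + gamma * gg[[nm]]
        }
        step <- learning_rate / nb
        par$W <- par$W + step * g$W
        par$U <- par$U + step * g$U
        par$b_v <- par$b_v + step * g$b_v
        par$c_h <- par$c_h + step * g$c_h
        par$d_y <- par$d_y + step * g$d_y
      }
      loss <- .drbm_disc_negloglik(par, X, y) / n
      if (!is.finite(loss)) {
        stop(sprintf("DRBM training diverged at epoch %d (loss not finite)",
                     ep), call. = FALSE)
      }
      trace[ep] <- loss
    }
    par
  })
  structure(list(
    W = par$W, U = par$U, b_v = par$b_v, c_h = par$c_h, d_y = par$d_y,
    n_hidden = H, n_classes = K,
    standardizer = list(mean = mu, sd = sdv, enabled = standardize),
    config = list(learning_rate = learning_rate, n_epochs = n_epochs,
                  batch_size = batch_size, generative_weight = gamma,
                  cd_steps = cd_steps, seed = seed,
                  weight_init_sd = weight_init_sd),
    trace = trace, call = match.call()
  ), class = "drbm")
}

# CD-k gradient of log p(x, y) for one mini-batch, Gaussian visibles.
# Mean-field reconstruction for x and y; hidden states sampled.
.drbm_cd_grad <- function(par, Xb, yb, k) {
  nb <- nrow(Xb); H <- ncol(par$W); K <- length(par$d_y)
  Y0 <- matrix(0, nb, K)
  Y0[cbind(seq_len(nb), yb)] <- 1
  ph0 <- .sigmoid(sweep(Xb %*% par$W, 2L, par$c_h, "+") + Y0 %*% par$U)
  Xk <- Xb; Yk <- Y0; phk <- ph0
  for (step in seq_len(k)) {
    hs <- matrix(stats::rbinom(nb * H, 1L, phk), nb, H)
    Xk <- sweep(hs %*% t(par$W), 2L, par$b_v, "+")
    ly <- sweep(hs %*% t(par$U), 2L, par$d_y, "+")
    ly <- ly - apply(ly, 1L, max)
    Yk <- exp(ly); Yk <- Yk / rowSums(Yk)
    phk <- .sigmoid(sweep(Xk %*% par$W, 2L, par$c_h, "+") + Yk %*% par$U)
  }
  list(W = crossprod(Xb, ph0) - crossprod(Xk, phk),
       U = crossprod(Y0, ph0) - crossprod(Yk, phk),
       b_v = colSums(Xb) - colSums(Xk),
       c_h = colSums(ph0) - colSums(phk),
       d_y = colSums(Y0) - colSums(Yk))
}

#' @export
print.drbm <- function(x, ...) {
  cat(sprintf("<drbm> %d visible, %d hidden, %d classes\n",
              nrow(x$W), x$n_hidden, x$n_classes))
  cat(sprintf("  hybrid objective: gamma = %g, CD-%d; %d epochs, final loss %.4f\n",
              x$config$generative_weight, x$config$cd_steps,
              x$config$n_epochs, utils::tail(x$trace, 1L)))
  invisible(x)
}

#' @export
summary.drbm <- function(object, ...) {
  print(object)
  cat(sprintf("  |W| range: [%.3g, %.3g], class biases: %s\n",
              min(object$W), max(object$W),
              paste(signif(object$d_y, 3), collapse = ", ")))
  invisible(object)
}

#' @export
plot.drbm <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "epoch", ylab = "mean discriminative loss",
                 main = "DRBM training", ...)
  invisible(x)
}

#' Class posteriors, P300 scores, or hard labels from a fitted DRBM
#'
#' @param object A fitted [drbm()].
#' @param x Feature matrix or `stlfl_features` (standardized internally
#'   with the training statistics).
#' @param type `"score"` returns `p(target | x)` per epoch (in (0, 1)),
#'   `"prob"` the full `n x 2` posterior (rows sum to 1), `"class"` the
#'   argmax label in `{1, 2}`.
#' @param ... Unused.
#' @return Numeric vector, matrix, or integer vector per `type`.
#' @export
predict.drbm <- function(object, x, type = c("score", "prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(x, "stlfl_features")) x <- x$features
  X <- as.matrix(x)
  if (ncol(X) != nrow(object$W)) stop("feature dimension mismatch",
                                      call. = FALSE)
  if (anyNA(object$W)) stop("model parameters contain NA", call. = FALSE)
  if (object$standardizer$enabled) {
    X <- sweep(sweep(X, 2L, object$standardizer$mean), 2L,
               object$standardizer$sd, "/")
  }
  P <- .drbm_posterior(object, X)
  switch(type,
         prob = P,
         score = P[, 1L],
         class = max.col(P, ties.method = "first"))
}

#' P300 scores from any scorer
#'
#' Small convenience wrapper: `score_p300(model, features)` returns the
#' per-epoch target score for a `drbm` (posterior probability of the target
#' class) or an `fld` (projection onto the discriminant, higher = more
#' target-like).
#'
#' @param model A fitted `drbm` or `fld`.
#' @param features Features/epochs matching the model.
#' @return Numeric score per epoch.
#' @export
score_p300 <- function(model, features) {
  if (inherits(model, "drbm")) {
    predict(model, features, type = "score")
  } else if (inherits(model, "fld")) {
    predict(model, features)
  } else {
    stop("unsupported model type", call. = FALSE)
  }
}
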