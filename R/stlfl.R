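#' Class-mean and difference (scatter building-block) matrices
#'
#' Computes the per-class mean matrices `m1` (target), `m2` (non-target),
#' the grand mean `m`, the between-class difference matrices
#' `Db_i = m_i - m`, and the per-epoch within-class differences
#' `Dw_n = X_n - m_class(n)`. Outer products (the actual scatters) are
#' formed later, per projection step, because the bilinear iteration
#' sandwiches these differences with the current projection of the other
#' domain.
#'
#' @param epochs An `epoch_set` containing both classes
#'   (label 1 = target/P300).
#' @return An object of class `stlfl_scatters` with fields `m1`, `m2`, `m`,
#'   `Db1`, `Db2`, `Dw` (array `n x C x T`), `n1`, `n2`.
#' @export
compute_scatters <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  i1 <- which(epochs$labels == 1L)
  i2 <- which(epochs$labels == 2L)
  if (length(i1) == 0L || length(i2) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  mean_over <- function(idx) {
    apply(epochs$data[idx, , , drop = FALSE], c(2L, 3L), mean)
  }
  m1 <- mean_over(i1)
  m2 <- mean_over(i2)
  m <- apply(epochs$data, c(2L, 3L), mean)
  Dw <- epochs$data
  for (i in i1) Dw[i, , ] <- Dw[i, , ] - m1
  for (i in i2) Dw[i, , ] <- Dw[i, , ] - m2
  structure(list(m1 = m1, m2 = m2, m = m, Db1 = m1 - m, Db2 = m2 - m,
                 Dw = Dw, n1 = length(i1), n2 = length(i2)),
            class = "stlfl_scatters")
}

# Sum_n A_n G A_n' for a stack A (n x C x T) and G = P P' (T x h projector),
# fully vectorized: contract over time, then over (epoch, component).
# side = "spatial" contracts P against time; "temporal" against channels.
.sandwich_sum <- function(A, P, side = c("spatial", "temporal")) {
  side <- match.arg(side)
  d <- dim(A)
  n <- d[1L]; C <- d[2L]; T_ <- d[3L]
  h <- ncol(P)
  if (side == "spatial") {
    # Q[n,c,j] = sum_t A[n,c,t] P[t,j];  result[c,c'] = sum_{n,j} Q Q
    Q <- matrix(A, n * C, T_) %*% P              # (n*C) x h
    Z <- matrix(aperm(array(Q, c(n, C, h)), c(2L, 1L, 3L)), C, n * h)
    tcrossprod(Z)
  } else {
    # Q[n,t,j] = sum_c A[n,c,t] P[c,j];  result[t,t'] = sum_{n,j} Q Q
    At <- aperm(A, c(1L, 3L, 2L))                # n x T x C
    Q <- matrix(At, n * T_, C) %*% P             # (n*T) x h
    Z <- matrix(aperm(array(Q, c(n, T_, h)), c(2L, 1L, 3L)), T_, n * h)
    tcrossprod(Z)
  }
}

#' Solve the linear feature learning (LFL) generalized eigenproblem
#'
#' The LFL criterion modifies the Fisher ratio in two ways: the between-class
#' scatter is split per class around the grand mean and one class's term is
#' reweighted by `alpha` (absorbed into `SB_N` by the caller), and a
#' `-beta * SW` penalty is moved into the numerator. The directions maximize
#' `w'(SB_N - beta SW)w / (w'SW w)` and are found from the symmetric pencil
#' `(SB_N - beta SW) w = lambda (SW + eps I) w`, with a small relative ridge
#' `eps = ridge_eps * tr(SW)/d` making the right-hand side positive
#' definite.
#'
#' @param SB_N Symmetric numerator scatter (`d x d`), class terms already
#'   combined.
#' @param SW Symmetric within-class scatter (`d x d`).
#' @param beta Within-class penalty weight in the numerator (>= 0).
#' @param h Number of directions (top eigenvalues) to return.
#' @param ridge_eps Relative ridge multiplier (default `1e-6`).
#' @return List with `vectors` (`d x h`, unit columns, deterministic sign:
#'   largest-magnitude entry positive) and `values` (top `h` eigenvalues,
#'   descending).
#' @export
lfl_direction <- function(SB_N, SW, beta = 0, h = 1L, ridge_eps = 1e-6) {
  SB_N <- as.matrix(SB_N); SW <- as.matrix(SW)
  d <- nrow(SB_N)
  if (ncol(SB_N) != d || any(dim(SW) != d)) {
    stop("SB_N and SW must be square matrices of equal dimension",
         call. = FALSE)
  }
  h <- .check_count(h, "h")
  if (h > d) stop("h exceeds the pencil dimension", call. = FALSE)
  sym_tol <- 1e-8 * max(1, max(abs(SB_N)), max(abs(SW)))
  if (max(abs(SB_N - t(SB_N))) > sym_tol || max(abs(SW - t(SW))) > sym_tol) {
    stop("scatter matrices must be symmetric", call. = FALSE)
  }
  SB_N <- (SB_N + t(SB_N)) / 2
  SW <- (SW + t(SW)) / 2
  eps <- ridge_eps * sum(diag(SW)) / d
  if (eps <= 0) eps <- ridge_eps
  A <- SB_N - beta * SW
  B <- SW + diag(eps, d)
  U <- tryCatch(chol(B), error = function(e) {
    stop("within-class scatter not positive definite after ridge; ",
         "increase ridge_eps", call. = FALSE)
  })
  Ui <- backsolve(U, diag(d))
  M <- crossprod(Ui, A %*% Ui)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)   # descending eigenvalues
  W <- .fix_signs(Ui %*% es$vectors[, seq_len(h), drop = FALSE])
  list(vectors = W, values = es$values[seq_len(h)])
}

# Align a fresh eigenvector matrix with the previous iterate before the
# convergence norm is taken. Within a cluster of near-degenerate
# eigenvalues any orthonormal basis of the eigenspace is an equally valid
# solution, so each cluster is rotated onto the reference by orthogonal
# Procrustes (singletons reduce to a sign flip); only identifiable change
# — subspace drift and movement of well-separated eigenvectors — then
# counts toward the stopping rule.
.align_columns <- function(M, values, ref) {
  h <- ncol(M)
  gaps <- abs(diff(values))
  scale_ <- pmax(abs(values[-h]), abs(values[-1L]), 1e-12)
  new_cluster <- c(TRUE, gaps > 0.1 * scale_)
  cluster <- cumsum(new_cluster)
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    sv <- svd(crossprod(M[, idx, drop = FALSE], ref[, idx, drop = FALSE]))
    M[, idx] <- M[, idx, drop = FALSE] %*% (sv$u %*% t(sv$v))
  }
  list(vectors = M, values = values)
}

# Numerator and denominator pencils for one side of the bilinear
# iteration. `P` is the fixed projection of the other domain. `cache`
# (optional) holds the two unfoldings of the within-class difference
# stack, which are constant across iterations:
#   spatial  (n*C) x T  and  temporal (n*T) x C.
.stlfl_pencils <- function(scat, P, side, alpha, cache = NULL) {
  SB <- .sandwich_sum(array(scat$Db1, c(1L, dim(scat$Db1))), P, side) +
    alpha * .sandwich_sum(array(scat$Db2, c(1L, dim(scat$Db2))), P, side)
  d <- dim(scat$Dw)
  n <- d[1L]
  if (is.null(cache)) {
    SW <- .sandwich_sum(scat$Dw, P, side) / n
  } else {
    h <- ncol(P)
    if (side == "spatial") {
      Q <- cache$spatial %*% P
      Z <- matrix(aperm(array(Q, c(n, d[2L], h)), c(2L, 1L, 3L)),
                  d[2L], n * h)
    } else {
      Q <- cache$temporal %*% P
      Z <- matrix(aperm(array(Q, c(n, d[3L], h)), c(2L, 1L, 3L)),
                  d[3L], n * h)
    }
    SW <- tcrossprod(Z) / n
  }
  list(SB = SB, SW = SW)
}

#' Fit the spatial-temporal linear feature learning (STLFL) model
#'
#' Learns a spatial projection `W` (`C x h`) and a temporal projection `V`
#' (`T x h`) for two-class event-related-potential epochs by alternating
#' generalized eigendecompositions of the LFL criterion. With `V` fixed, the
#' spatial numerator is built from the class-mean differences sandwiched
#' with `VV'` (`sum_i alpha_i Db_i VV' Db_i'`, `alpha_1 = 1`,
#' `alpha_2 = alpha`) and the denominator from the ensemble average of
#' `Dw_n VV' Dw_n'`; the temporal step transposes the roles. `V` is
#' initialized to the first `h` columns of the identity, and the iteration
#' stops when both `||W - W_prev||_2` and `||V - V_prev||_2` (after sign
#' alignment) fall below `tol`, or at `max_iter`.
#'
#' Epochs are mapped to features `vec(W' X V)` (column-major, `h^2`
#' values) by [predict.stlfl()].
#'
#' @param epochs An `epoch_set` with both classes (label 1 = target).
#' @param alpha Reweighting of the non-target between-class term (>= 0).
#'   `alpha_on = "target"` applies it to the target term instead.
#' @param beta Within-class penalty in the numerator (>= 0).
#' @param h Projection rank (`h <= min(C, T)`); `h = 4` gives 16-dim
#'   features.
#' @param tol Convergence tolerance on the projection-change spectral norm.
#' @param max_iter Maximum number of alternating iterations.
#' @param ridge_eps Relative ridge for the denominator pencils.
#' @param alpha_on Which class's between-class term `alpha` multiplies.
#' @return An object of class `stlfl` with `W`, `V`, `eigvals_spatial`,
#'   `eigvals_temporal`, `n_iter`, `converged`, a per-iteration `trace`,
#'   and the hyperparameters.
#' @export
stlfl <- function(epochs, alpha = 1, beta = 0.01, h = 4L, tol = 1e-5,
                  max_iter = 500L, ridge_eps = 1e-6,
                  alpha_on = c("nontarget", "target")) {
  stopifnot(inherits(epochs, "epoch_set"))
  alpha <- .check_scalar(alpha, "alpha", lower = 0)
  beta <- .check_scalar(beta, "beta", lower = 0)
  tol <- .check_scalar(tol, "tol", lower = 1e-300)
  max_iter <- .check_count(max_iter, "max_iter")
  alpha_on <- match.arg(alpha_on)
  d <- dim(epochs$data)
  C <- d[2L]; T_ <- d[3L]
  h <- .check_count(h, "h")
  if (h > min(C, T_)) {
    stop(sprintf("h = %d exceeds min(channels, samples) = %d", h,
                 min(C, T_)), call. = FALSE)
  }
  scat <- compute_scatters(epochs)
  if (alpha_on == "target") {
    # swap roles: alpha multiplies the target class term
    scat_eff <- scat
    scat_eff$Db1 <- scat$Db2
    scat_eff$Db2 <- scat$Db1
    scat <- scat_eff
  }

  d3 <- dim(scat$Dw)
  cache <- list(
    spatial = matrix(scat$Dw, d3[1L] * C, T_),
    temporal = matrix(aperm(scat$Dw, c(1L, 3L, 2L)), d3[1L] * T_, C)
  )

  V <- diag(T_)[, seq_len(h), drop = FALSE]
  W <- matrix(0, C, h)
  ev_s <- ev_t <- rep(NA_real_, h)
  trace <- matrix(NA_real_, 0L, 2L, dimnames = list(NULL, c("dW", "dV")))
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    ps <- .stlfl_pencils(scat, V, "spatial", alpha, cache)
    sol_s <- lfl_direction(ps$SB, ps$SW, beta, h, ridge_eps)
    W_new <- sol_s$vectors
    ev_s <- sol_s$values
    pt <- .stlfl_pencils(scat, W_new, "temporal", alpha, cache)
    sol_t <- lfl_direction(pt$SB, pt$SW, beta, h, ridge_eps)
    V_new <- sol_t$vectors
    ev_t <- sol_t$values
    # convergence norms on column-aligned copies: order within
    # near-degenerate eigenvalue clusters is arbitrary and must not count
    # as change
    dW <- if (it == 1L) Inf else
      norm(.align_columns(W_new, ev_s, W)$vectors - W, type = "2")
    dV <- if (it == 1L) Inf else
      norm(.align_columns(V_new, ev_t, V)$vectors - V, type = "2")
    trace <- rbind(trace, c(dW, dV))
    W <- W_new
    V <- V_new
    if (dW < tol && dV < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    W = W, V = V, alpha = alpha, beta = beta, h = h,
    eigvals_spatial = ev_s, eigvals_temporal = ev_t,
    n_iter = n_iter, converged = converged, tol = tol,
    ridge_eps = ridge_eps, alpha_on = alpha_on,
    trace = trace, dims = c(C = C, T = T_),
    channel_names = epochs$channel_names, fs = epochs$fs,
    call = match.call()
  ), class = "stlfl")
}

#' @export
print.stlfl <- function(x, ...) {
  cat(sprintf("<stlfl> C=%d channels, T=%d samples, h=%d (features: %d)\n",
              x$dims["C"], x$dims["T"], x$h, x$h^2))
  cat(sprintf("  alpha=%g (on %s class), beta=%g\n", x$alpha, x$alpha_on,
              x$beta))
  cat(sprintf("  %s in %d iteration(s) (tol %g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$tol))
  invisible(x)
}

#' @export
summary.stlfl <- function(object, ...) {
  cat("Spatial-temporal linear feature learning fit\n")
  print(object)
  cat("  top spatial eigenvalues:  ",
      paste(signif(object$eigvals_spatial, 4), collapse = ", "), "\n")
  cat("  top temporal eigenvalues: ",
      paste(signif(object$eigvals_temporal, 4), collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.stlfl <- function(object, ...) {
  list(W = object$W, V = object$V)
}

#' Project epochs into the learned bilinear feature space
#'
#' Each epoch `X` (`C x T`) is mapped to `vec(W' X V)` — the `h x h`
#' projected matrix flattened column-major into an `h^2` vector.
#'
#' @param object A fitted [stlfl()] model.
#' @param epochs An `epoch_set` with matching `(C, T)`.
#' @param ... Unused.
#' @return An object of class `stlfl_features`: a list with `features`
#'   (`n x h^2` matrix), `labels`, and the hyperparameter provenance.
#' @export
predict.stlfl <- function(object, epochs, ...) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[2L] != object$dims["C"] || d[3L] != object$dims["T"]) {
    stop("epoch dimensions do not match the fitted model", call. = FALSE)
  }
  n <- d[1L]
  h <- object$h
  # (n*C) x T %*% V  -> reshape -> contract channels with W
  Q <- matrix(epochs$data, n * d[2L], d[3L]) %*% object$V   # (n*C) x h
  Qa <- aperm(array(Q, c(n, d[2L], h)), c(2L, 1L, 3L))      # C x n x h
  Fmat <- matrix(NA_real_, n, h * h)
  WT <- t(object$W)
  for (j in seq_len(h)) {
    # column block j of W' X V for all epochs at once
    Fmat[, (j - 1L) * h + seq_len(h)] <- t(WT %*% matrix(Qa[, , j],
                                                         d[2L], n))
  }
  structure(list(features = Fmat, labels = epochs$labels,
                 provenance = list(alpha = object$alpha, beta = object$beta,
                                   h = h)),
            class = "stlfl_features")
}

#' @export
print.stlfl_features <- function(x, ...) {
  cat(sprintf("<stlfl_features> %d x %d (h=%d)\n", nrow(x$features),
              ncol(x$features), x$provenance$h))
  invisible(x)
}

#' @export
plot.stlfl <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  tr <- x$trace
  if (nrow(tr) > 1L) {
    graphics::matplot(seq_len(nrow(tr)), tr, type = "b", log = "y", pch = 1,
                      xlab = "iteration", ylab = "projection change (norm)",
                      main = "STLFL convergence", ...)
    graphics::abline(h = x$tol, lty = 3)
    graphics::legend("topright", legend = c("dW", "dV"), col = 1:2, lty = 1:2,
                     bty = "n")
  } else {
    graphics::plot.new()
  }
  graphics::matplot(seq_len(nrow(x$W)), x$W, type = "l",
                    xlab = "channel", ylab = "weight",
                    main = "spatial filters W")
  invisible(x)
}

#' Classic Fisher linear discriminant on vectorized epochs
#'
#' The ratio-of-scatters baseline: epochs are flattened to `C*T` vectors and
#' the direction maximizing `w'SB w / w'SW w` (with
#' `SB = (m2 - m1)(m2 - m1)'` and pooled within-class `SW`) is found from
#' the same ridge-regularized pencil used by [lfl_direction()]. Serves both
#' as the no-feature-learning baseline scorer and as the limiting case of
#' the LFL criterion at `alpha = 1`, `beta = 0`.
#'
#' @param epochs An `epoch_set`, or a numeric matrix `n x d` with `labels`.
#' @param labels Required when `epochs` is a matrix.
#' @param ridge_eps Relative ridge (see [lfl_direction()]).
#' @return An object of class `fld`: `direction` (unit vector), `threshold`
#'   (midpoint of projected class means, oriented so targets score higher),
#'   and the projected class means.
#' @export
fld <- function(epochs, labels = NULL, ridge_eps = 1e-6) {
  if (inherits(epochs, "epoch_set")) {
    d <- dim(epochs$data)
    X <- matrix(epochs$data, d[1L], d[2L] * d[3L])
    labels <- epochs$labels
  } else {
    X <- as.matrix(epochs)
    if (is.null(labels)) stop("`labels` required for matrix input",
                              call. = FALSE)
    labels <- as.integer(labels)
  }
  i1 <- which(labels == 1L); i2 <- which(labels == 2L)
  if (length(i1) == 0L || length(i2) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[i2, , drop = FALSE])
  Xc <- X
  Xc[i1, ] <- sweep(X[i1, , drop = FALSE], 2L, m1)
  Xc[i2, ] <- sweep(X[i2, , drop = FALSE], 2L, m2)
  SW <- crossprod(Xc)
  SB <- tcrossprod(m2 - m1)
  sol <- lfl_direction(SB, SW, beta = 0, h = 1L, ridge_eps = ridge_eps)
  w <- drop(sol$vectors)
  # orient so that class 1 (target) projects higher
  if (sum(w * m1) < sum(w * m2)) w <- -w
  structure(list(direction = w, value = sol$values[1L],
                 mean_target = sum(w * m1), mean_nontarget = sum(w * m2),
                 dims = dim(X)[2L]),
            class = "fld")
}

#' @export
print.fld <- function(x, ...) {
  cat(sprintf("<fld> %d-dimensional Fisher discriminant (lambda = %.4g)\n",
              x$dims, x$value))
  invisible(x)
}

#' @export
predict.fld <- function(object, epochs, ...) {
  if (inherits(epochs, "epoch_set")) {
    d <- dim(epochs$data)
    X <- matrix(epochs$data, d[1L], d[2L] * d[3L])
  } else {
    X <- as.matrix(epochs)
  }
  if (ncol(X) != object$dims) stop("feature dimension mismatch",
                                   call. = FALSE)
  drop(X %*% object$direction)
}
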