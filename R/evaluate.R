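#' Character selection time for the matrix speller
#'
#' `T = 2.5 + 2.1 * rep` seconds: a 2.5 s pause between character epochs
#' plus 2.1 s per repetition (12 flashes x 175 ms).
#'
#' @param rep Repetition count, 1-15.
#' @return Selection time in seconds.
#' @export
selection_time <- function(rep) {
  rep <- .check_count(rep, "rep")
  if (rep > 15L) stop("`rep` must be between 1 and 15", call. = FALSE)
  2.5 + 2.1 * rep
}

#' Information transfer rate in bits per minute
#'
#' Wolpaw-style bits per selection,
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`, scaled to
#' bits per minute by `60 / T_char`. The `x log2 x` limits at `P = 0` and
#' `P = 1` are handled by continuity; at chance (`P = 1/N`) the rate is 0.
#'
#' @param P Character recognition accuracy in `[0, 1]`.
#' @param N Alphabet size (36 for the 6x6 matrix speller).
#' @param T_char Seconds per character selection (see [selection_time()]).
#' @return Bits per minute.
#' @export
itr_bpm <- function(P, N = 36L, T_char) {
  N <- .check_count(N, "N", min = 2L)
  T_char <- .check_scalar(T_char, "T_char", lower = 1e-12)
  vapply(P, function(p) {
    .check_scalar(p, "P", 0, 1)
    xlog2 <- function(x) if (x <= 0) 0 else x * log2(x)
    bits <- log2(N) + xlog2(p) + (1 - p) *
      (if (p >= 1) 0 else log2((1 - p) / (N - 1)))
    bits * 60 / T_char
  }, numeric(1L))
}

#' Pointwise biserial discriminability of a feature
#'
#' `r = sqrt(N1 N2) / (N1 + N2) * (mean_1 - mean_2) / sd_all`, where
#' `sd_all` is the population SD over both classes pooled; returns `r^2`,
#' the usual separability index for single features (identical to the
#' squared Pearson correlation between the feature and the class label).
#'
#' @param feature Numeric feature value per sample.
#' @param labels Class labels in `{1, 2}`.
#' @return `r^2` in `[0, 1]`.
#' @export
biserial_r2 <- function(feature, labels) {
  labels <- as.integer(labels)
  stopifnot(length(feature) == length(labels))
  n1 <- sum(labels == 1L); n2 <- sum(labels == 2L)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present",
                                 call. = FALSE)
  n <- n1 + n2
  sd_all <- sqrt(sum((feature - mean(feature))^2) / n)
  if (sd_all <= 0) stop("pooled SD is zero", call. = FALSE)
  r <- sqrt(n1 * n2) / n *
    (mean(feature[labels == 1L]) - mean(feature[labels == 2L])) / sd_all
  r^2
}

#' Accuracy table across sessions
#'
#' Mean and sample SD (`n - 1` convention) of the decoding accuracy per
#' repetition budget, across a list of decoded sessions.
#'
#' @param decode_results A list of [decode_session()] results (or a single
#'   one).
#' @param budgets Budgets to tabulate (default: those present in the first
#'   result).
#' @return Data frame with `budget`, `mean_accuracy`, `sd_accuracy`, `n`.
#' @export
accuracy_table <- function(decode_results, budgets = NULL) {
  if (inherits(decode_results, "decode_result")) {
    decode_results <- list(decode_results)
  }
  if (length(decode_results) == 0L) stop("no decode results", call. = FALSE)
  if (is.null(budgets)) {
    budgets <- decode_results[[1L]]$accuracy_by_repetition$budget
  }
  rows <- lapply(budgets, function(b) {
    accs <- vapply(decode_results, function(dr) {
      tab <- dr$accuracy_by_repetition
      i <- match(b, tab$budget)
      if (is.na(i)) stop(sprintf("budget %d missing from a session", b),
                         call. = FALSE)
      tab$accuracy[i]
    }, numeric(1L))
    data.frame(budget = b, mean_accuracy = mean(accs),
               sd_accuracy = if (length(accs) > 1L) stats::sd(accs) else 0,
               n = length(accs))
  })
  do.call(rbind, rows)
}

#' Hyperparameter search for the STLFL pipeline
#'
#' Grid search over `(alpha, beta)` scored by character-selection accuracy,
#' with k-fold cross-validation stratified at the character-trial level
#' (all flashes of one character stay in the same fold, so no flash of a
#' validation character is ever seen in training). The winning pair — ties
#' broken toward smaller `beta`, then smaller `alpha` — is refit on all
#' the training data.
#'
#' @param epochs Training `epoch_set` (unbalanced; balancing happens inside
#'   each training fold).
#' @param paradigm The [build_paradigm()] spec.
#' @param truth Ground-truth symbol per character trial in `epochs`.
#' @param alpha_grid,beta_grid Candidate values. Defaults follow the
#'   conventional search ranges: `alpha` in `seq(1, 5, by = 0.2)`, `beta`
#'   in `{0, 1e-4, 1e-3, 0.01, 0.1, 0.3, 0.5, 0.7, 1, 1.5, 2}`.
#' @param k_folds Number of CV folds (e.g. 5 or 3).
#' @param h,tol,max_iter STLFL settings passed through.
#' @param drbm_args List of arguments forwarded to [drbm()] (e.g.
#'   `n_epochs`, `learning_rate`).
#' @param budget Repetition budget used for validation accuracy (default:
#'   all available repetitions).
#' @param seed Seed for fold assignment, balancing and classifier training.
#' @return An object of class `stlfl_tune`: `alpha`, `beta`, `cv_table`
#'   (one row per grid point with the mean validation accuracy), `folds`
#'   (character-to-fold map), and `model`/`classifier` refit on all data.
#' @export
tune_stlfl <- function(epochs, paradigm, truth,
                       alpha_grid = seq(1, 5, by = 0.2),
                       beta_grid = c(0, 1e-4, 1e-3, 0.01, 0.1, 0.3, 0.5,
                                     0.7, 1, 1.5, 2),
                       k_folds = 5L, h = 4L, tol = 1e-5, max_iter = 500L,
                       drbm_args = list(), budget = NULL, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(paradigm, "paradigm_spec"))
  if (length(alpha_grid) == 0L || length(beta_grid) == 0L) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  k_folds <- .check_count(k_folds, "k_folds")
  chars <- sort(unique(epochs$char_index))
  if (length(chars) < k_folds) {
    stop("fewer character trials than folds", call. = FALSE)
  }
  if (length(truth) != length(chars)) {
    stop("`truth` must give one symbol per character trial", call. = FALSE)
  }
  fold_of <- with_seed(seed, {
    sample(rep_len(seq_len(k_folds), length(chars)))
  })
  if (is.null(budget)) budget <- max(epochs$repetition_index)

  grid <- expand.grid(alpha = alpha_grid, beta = beta_grid)
  fit_score <- function(a, b, train_chars, val_chars) {
    tr <- .subset_epochs(epochs, which(epochs$char_index %in% train_chars))
    va <- .subset_epochs(epochs, which(epochs$char_index %in% val_chars))
    trb <- balance_classes(tr, seed = seed)
    model <- stlfl(trb, alpha = a, beta = b, h = h, tol = tol,
                   max_iter = max_iter)
    clf <- do.call(drbm, c(list(x = predict(model, trb), seed = seed),
                           drbm_args))
    sc <- score_p300(clf, predict(model, va))
    # re-index validation character trials to 1..n for decoding
    va$char_index <- match(va$char_index, sort(unique(va$char_index)))
    dr <- decode_session(va, sc, paradigm,
                         truth[match(sort(val_chars), chars)],
                         budgets = budget)
    dr$accuracy_by_repetition$accuracy[1L]
  }

  cv <- vapply(seq_len(nrow(grid)), function(g) {
    accs <- vapply(seq_len(k_folds), function(f) {
      fit_score(grid$alpha[g], grid$beta[g],
                chars[fold_of != f], chars[fold_of == f])
    }, numeric(1L))
    mean(accs)
  }, numeric(1L))
  cv_table <- cbind(grid, mean_val_accuracy = cv)
  ord <- order(-cv_table$mean_val_accuracy, cv_table$beta, cv_table$alpha)
  best <- cv_table[ord[1L], ]

  balanced <- balance_classes(epochs, seed = seed)
  model <- stlfl(balanced, alpha = best$alpha, beta = best$beta, h = h,
                 tol = tol, max_iter = max_iter)
  clf <- do.call(drbm, c(list(x = predict(model, balanced), seed = seed),
                         drbm_args))
  structure(list(alpha = best$alpha, beta = best$beta, cv_table = cv_table,
                 folds = data.frame(char_index = chars, fold = fold_of),
                 model = model, classifier = clf, budget = budget),
            class = "stlfl_tune")
}

#' @export
print.stlfl_tune <- function(x, ...) {
  cat(sprintf("<stlfl_tune> best alpha = %g, beta = %g (val. accuracy %.1f%%)\n",
              x$alpha, x$beta,
              100 * max(x$cv_table$mean_val_accuracy)))
  cat(sprintf("  grid: %d point(s), %d fold(s), budget %d repetition(s)\n",
              nrow(x$cv_table), max(x$folds$fold), x$budget))
  invisible(x)
}
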