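#' End-to-end P300 speller pipeline
#'
#' Runs the full detection chain on a training and a test session:
#' band-pass filter, epoch, decimate (per the dataset profile), balance the
#' training classes by replication, fit the STLFL projections, train the
#' classifier on the projected features, score the (unbalanced) test
#' epochs, and decode characters per repetition budget. For RCP sessions an
#' ITR column (bits/min, matrix-speller timing) is added to the accuracy
#' curve.
#'
#' @param train_session,test_session `speller_session` objects sharing the
#'   paradigm.
#' @param profile A [dataset_profile()] (default `"bci_comp"` for RCP,
#'   `"hybrid_rsvp"` for RSVP).
#' @param method `"stlfl_drbm"` (STLFL features + DRBM classifier) or
#'   `"fld"` (vectorized Fisher discriminant on the same preprocessed
#'   epochs — the no-feature-learning baseline).
#' @param alpha,beta,h,tol,max_iter STLFL hyperparameters.
#' @param drbm_args List of arguments forwarded to [drbm()].
#' @param budgets Repetition budgets for decoding.
#' @param seed Seed for balancing and classifier training.
#' @return An object of class `p300_pipeline`: the fitted `model` and
#'   `classifier`, the test `decode` result, and `accuracy` (data frame
#'   with `budget`, `accuracy`, and `itr_bpm` for RCP).
#' @export
p300_pipeline <- function(train_session, test_session, profile = NULL,
                          method = c("stlfl_drbm", "fld"),
                          alpha = 1, beta = 0.01, h = 4L, tol = 1e-5,
                          max_iter = 500L, drbm_args = list(),
                          budgets = NULL, seed = 1L) {
  stopifnot(inherits(train_session, "speller_session"),
            inherits(test_session, "speller_session"))
  method <- match.arg(method)
  paradigm <- train_session$paradigm
  if (is.null(profile)) {
    profile <- dataset_profile(
      if (paradigm$kind == "RCP") "bci_comp" else "hybrid_rsvp")
  }
  # fail fast on an infeasible projection rank before any filtering
  C <- nrow(train_session$signal)
  T_post <- floor(profile$epoch_window * train_session$fs) %/%
    profile$decimation_factor
  if (method == "stlfl_drbm" && h > min(C, T_post)) {
    stop(sprintf("h = %d exceeds min(channels, samples) = %d after %s",
                 h, min(C, T_post), "preprocessing"), call. = FALSE)
  }

  train <- preprocess_session(train_session, profile, balance = TRUE,
                              seed = seed)
  test <- preprocess_session(test_session, profile, balance = FALSE)

  if (method == "stlfl_drbm") {
    model <- stlfl(train, alpha = alpha, beta = beta, h = h, tol = tol,
                   max_iter = max_iter)
    clf <- do.call(drbm, c(list(x = predict(model, train), seed = seed),
                           drbm_args))
    scores <- score_p300(clf, predict(model, test))
  } else {
    model <- fld(train)
    clf <- NULL
    scores <- predict(model, test)
  }
  dec <- decode_session(test, scores, paradigm, test_session$truth,
                        budgets = budgets)
  acc <- dec$accuracy_by_repetition
  if (paradigm$kind == "RCP") {
    acc$itr_bpm <- vapply(seq_len(nrow(acc)), function(i) {
      itr_bpm(acc$accuracy[i], N = length(paradigm$alphabet),
              T_char = selection_time(acc$budget[i]))
    }, numeric(1L))
  }
  structure(list(method = method, profile = profile, model = model,
                 classifier = clf, decode = dec, accuracy = acc,
                 seed = seed),
            class = "p300_pipeline")
}

#' @export
print.p300_pipeline <- function(x, ...) {
  cat(sprintf("<p300_pipeline> method = %s, profile = %s\n", x$method,
              x$profile$name))
  print(x$accuracy, row.names = FALSE)
  invisible(x)
}
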