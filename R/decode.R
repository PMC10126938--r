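#' Aggregate per-flash P300 scores over repetitions
#'
#' For each candidate flash code `j`, sums the scores of its flashes within
#' the first `m` repetitions, `C(j) = sum_k S_j(k)` — with one flash per
#' code per repetition this is argmax-equivalent to averaging.
#'
#' @param scores Numeric score per flash epoch.
#' @param codes Flash code per epoch.
#' @param repetition_index Repetition index per epoch.
#' @param m Repetition budget (use the first `m` repetitions).
#' @param candidates The full candidate code set (default: sorted unique
#'   codes); every candidate must flash at least once within budget.
#' @return Named numeric vector `C(j)` over the candidates.
#' @export
aggregate_scores <- function(scores, codes, repetition_index, m,
                             candidates = sort(unique(codes))) {
  stopifnot(length(scores) == length(codes),
            length(scores) == length(repetition_index))
  m <- .check_count(m, "m")
  keep <- repetition_index <= m
  out <- vapply(candidates, function(j) {
    idx <- keep & codes == j
    if (!any(idx)) {
      stop(sprintf(
        "candidate code %s has no flashes in the first %d repetition(s)",
        j, m), call. = FALSE)
    }
    sum(scores[idx])
  }, numeric(1L))
  names(out) <- candidates
  out
}

#' Select the spelled character from row and column scores (RCP)
#'
#' The predicted character sits at the intersection of the highest-scoring
#' row and the highest-scoring column of the row-major 6x6 matrix. Ties go
#' to the lowest code index.
#'
#' @param C_rows Aggregated scores for the 6 row codes.
#' @param C_cols Aggregated scores for the 6 column codes.
#' @param alphabet The 36-symbol row-major layout.
#' @return A single symbol.
#' @export
select_character_rcp <- function(C_rows, C_cols,
                                 alphabet = c(LETTERS, as.character(1:9),
                                              "_")) {
  if (length(C_rows) != 6L || length(C_cols) != 6L) {
    stop("need 6 row and 6 column candidates", call. = FALSE)
  }
  if (length(alphabet) != 36L) stop("alphabet must have 36 symbols",
                                    call. = FALSE)
  r <- which.max(C_rows)
  cc <- which.max(C_cols)
  alphabet[(r - 1L) * 6L + cc]
}

#' Select the attended group from group scores (RSVP)
#'
#' @param C_groups Aggregated scores for the 9 group codes.
#' @return The argmax group index (ties to the lowest index).
#' @export
select_group_rsvp <- function(C_groups) {
  if (length(C_groups) != 9L) stop("need 9 group candidates", call. = FALSE)
  which.max(C_groups)
}

#' Decode a spelled session from per-epoch P300 scores
#'
#' Per character trial and per repetition budget: aggregate the flash
#' scores, select the character (RCP: row x column intersection) or group
#' (RSVP), and compare with the ground truth.
#'
#' @param epochs The test `epoch_set` (codes, char and repetition indices
#'   must be present; never class-balanced).
#' @param scores One P300 score per epoch, aligned with `epochs`.
#' @param paradigm The [build_paradigm()] spec.
#' @param truth Ground-truth symbol per character trial.
#' @param budgets Repetition budgets to evaluate (default
#'   `c(1, 5, 10, 15)` intersected with the available repetitions).
#' @return An object of class `decode_result`: `per_character` (character
#'   matrix, trials x budgets; RSVP predictions are group indices),
#'   `accuracy_by_repetition` (data frame `budget`, `accuracy`),
#'   `scores_table` (candidate scores at the largest budget), `truth`.
#' @export
decode_session <- function(epochs, scores, paradigm, truth,
                           budgets = NULL) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(paradigm, "paradigm_spec"))
  if (length(scores) != length(epochs$labels)) {
    stop("scores are not aligned with the epochs", call. = FALSE)
  }
  R <- max(epochs$repetition_index)
  if (is.null(budgets)) budgets <- intersect(c(1L, 5L, 10L, 15L),
                                             seq_len(R))
  budgets <- sort(unique(vapply(budgets, function(b)
    .check_count(b, "budget"), integer(1L))))
  if (any(budgets > R)) stop("budget exceeds available repetitions",
                             call. = FALSE)
  chars <- sort(unique(epochs$char_index))
  if (length(truth) != length(chars)) {
    stop("`truth` must give one symbol per character trial", call. = FALSE)
  }
  rcp <- paradigm$kind == "RCP"
  truth_cmp <- if (rcp) truth else
    vapply(truth, function(s) target_codes(paradigm, s), integer(1L))

  pred <- matrix(NA_character_, length(chars), length(budgets),
                 dimnames = list(NULL, paste0("rep", budgets)))
  scores_table <- vector("list", length(chars))
  for (ci in seq_along(chars)) {
    idx <- which(epochs$char_index == chars[ci])
    for (bi in seq_along(budgets)) {
      m <- budgets[bi]
      if (rcp) {
        rows <- idx[epochs$codes[idx] %in% 1:6]
        cols <- idx[epochs$codes[idx] %in% 7:12]
        Cr <- aggregate_scores(scores[rows], epochs$codes[rows],
                               epochs$repetition_index[rows], m,
                               candidates = 1:6)
        Cc <- aggregate_scores(scores[cols], epochs$codes[cols],
                               epochs$repetition_index[cols], m,
                               candidates = 7:12)
        pred[ci, bi] <- select_character_rcp(Cr, Cc, paradigm$alphabet)
        if (bi == length(budgets)) scores_table[[ci]] <- c(Cr, Cc)
      } else {
        Cg <- aggregate_scores(scores[idx], epochs$codes[idx],
                               epochs$repetition_index[idx], m,
                               candidates = 1:9)
        pred[ci, bi] <- as.character(select_group_rsvp(Cg))
        if (bi == length(budgets)) scores_table[[ci]] <- Cg
      }
    }
  }
  truth_chr <- as.character(truth_cmp)
  acc <- vapply(seq_along(budgets), function(bi) {
    mean(pred[, bi] == truth_chr)
  }, numeric(1L))
  structure(list(
    per_character = pred,
    accuracy_by_repetition = data.frame(budget = budgets, accuracy = acc),
    scores_table = do.call(rbind, scores_table),
    truth = truth_chr, paradigm_kind = paradigm$kind
  ), class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %s, %d character trial(s)\n",
              x$paradigm_kind, nrow(x$per_character)))
  a <- x$accuracy_by_repetition
  cat(paste0("  ", sprintf("rep %2d: %5.1f%%", a$budget, 100 * a$accuracy),
             collapse = "\n"), "\n")
  invisible(x)
}
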