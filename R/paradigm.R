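#' Build a speller paradigm specification
#'
#' Describes the stimulus bookkeeping of an oddball speller: either the
#' classic row-column paradigm (RCP) with a 6x6 alphanumeric matrix whose 6
#' rows and 6 columns flash once per repetition (12 intensifications), or a
#' rapid-serial-visual-presentation (RSVP) speller in which 9 groups of 3
#' letters are shown sequentially, one pass of all 9 groups per repetition.
#'
#' Default timings are the conventional ones for each paradigm: RCP flashes
#' last 100 ms with a 75 ms inter-stimulus interval (so one repetition of 12
#' flashes takes 2.1 s) and characters are separated by a 2.5 s pause; RSVP
#' stimuli last 230 ms with no inter-stimulus interval.
#'
#' @param kind `"RCP"` or `"RSVP"`.
#' @param n_repetitions Number of complete flash passes per character (1-15).
#' @param seed Integer seed controlling the randomized flash order.
#' @param flash_duration,isi,pause_between_chars Timing overrides in seconds;
#'   `NULL` selects the paradigm default.
#' @param alphabet Ordered symbol vector; `NULL` selects the standard layout
#'   (RCP: row-major `A`-`Z`, `1`-`9`, `_`; RSVP: `A`-`Z`, `_` in 9 groups
#'   of 3).
#' @return An object of class `paradigm_spec`.
#' @examples
#' p <- build_paradigm("RCP", n_repetitions = 15, seed = 1)
#' p$codes_per_repetition * p$n_repetitions  # 180 flashes per character
#' @export
build_paradigm <- function(kind = c("RCP", "RSVP"), n_repetitions = 15L,
                           seed = 1L, flash_duration = NULL, isi = NULL,
                           pause_between_chars = NULL, alphabet = NULL) {
  kind <- match.arg(kind)
  n_repetitions <- .check_count(n_repetitions, "n_repetitions")
  if (n_repetitions > 15L) {
    stop("`n_repetitions` must be between 1 and 15", call. = FALSE)
  }
  seed <- .check_count(seed, "seed", min = 0L)
  if (kind == "RCP") {
    if (is.null(flash_duration)) flash_duration <- 0.100
    if (is.null(isi)) isi <- 0.075
    if (is.null(pause_between_chars)) pause_between_chars <- 2.5
    if (is.null(alphabet)) alphabet <- c(LETTERS, as.character(1:9), "_")
    if (length(alphabet) != 36L) {
      stop("RCP alphabet must have 36 symbols (6x6 matrix)", call. = FALSE)
    }
    spec <- list(kind = kind, n_rows = 6L, n_cols = 6L, n_groups = NA_integer_,
                 codes_per_repetition = 12L)
  } else {
    if (is.null(flash_duration)) flash_duration <- 0.230
    if (is.null(isi)) isi <- 0
    # 45 stimuli x 230 ms = 10.35 s; a short 0.15 s pause rounds the trial to
    # the nominal 10.5 s per character at 5 repetitions.
    if (is.null(pause_between_chars)) pause_between_chars <- 0.15
    if (is.null(alphabet)) alphabet <- c(LETTERS, "_")
    if (length(alphabet) != 27L) {
      stop("RSVP alphabet must have 27 symbols (9 groups of 3)", call. = FALSE)
    }
    spec <- list(kind = kind, n_rows = NA_integer_, n_cols = NA_integer_,
                 n_groups = 9L, codes_per_repetition = 9L)
  }
  spec$n_repetitions <- n_repetitions
  spec$flash_duration <- .check_scalar(flash_duration, "flash_duration", 0)
  spec$isi <- .check_scalar(isi, "isi", 0)
  spec$pause_between_chars <-
    .check_scalar(pause_between_chars, "pause_between_chars", 0)
  spec$alphabet <- as.character(alphabet)
  spec$seed <- seed
  structure(spec, class = "paradigm_spec")
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat(sprintf("<paradigm_spec> %s speller\n", x$kind))
  if (x$kind == "RCP") {
    cat(sprintf("  matrix: %d x %d (%d symbols), 12 flash codes/repetition\n",
                x$n_rows, x$n_cols, length(x$alphabet)))
  } else {
    cat(sprintf("  groups: %d x 3 symbols, 9 flash codes/repetition\n",
                x$n_groups))
  }
  cat(sprintf("  repetitions: %d (%d flashes per character)\n",
              x$n_repetitions, x$n_repetitions * x$codes_per_repetition))
  cat(sprintf("  flash %d ms, ISI %d ms, inter-character pause %.2f s\n",
              round(1000 * x$flash_duration), round(1000 * x$isi),
              x$pause_between_chars))
  invisible(x)
}

#' Row/column/group membership of a symbol
#'
#' For RCP, flash codes 1-6 are rows and 7-12 are columns of the row-major
#' 6x6 matrix; for RSVP, codes 1-9 are the letter groups.
#'
#' @param paradigm A `paradigm_spec`.
#' @param symbol A single symbol from the paradigm alphabet.
#' @return Integer vector of the flash codes that contain `symbol`
#'   (length 2 for RCP: row code then column code; length 1 for RSVP).
#' @export
target_codes <- function(paradigm, symbol) {
  stopifnot(inherits(paradigm, "paradigm_spec"))
  idx <- match(symbol, paradigm$alphabet)
  if (is.na(idx)) stop("symbol not in paradigm alphabet", call. = FALSE)
  if (paradigm$kind == "RCP") {
    row <- ((idx - 1L) %/% paradigm$n_cols) + 1L
    col <- ((idx - 1L) %% paradigm$n_cols) + 1L
    c(row, 6L + col)
  } else {
    ((idx - 1L) %/% 3L) + 1L
  }
}

#' Randomized flash schedule for a session
#'
#' Enumerates the flash codes for `n_characters` character trials: every
#' repetition contains each code exactly once in a seeded random order
#' (12 codes for RCP: rows 1-6, columns 7-12; 9 group codes for RSVP).
#'
#' @param paradigm A `paradigm_spec`.
#' @param n_characters Number of character trials.
#' @return A data frame with columns `char_index`, `repetition_index`,
#'   `flash_index` (position within the character trial) and `code`.
#' @export
flash_schedule <- function(paradigm, n_characters) {
  stopifnot(inherits(paradigm, "paradigm_spec"))
  n_characters <- .check_count(n_characters, "n_characters")
  K <- paradigm$codes_per_repetition
  R <- paradigm$n_repetitions
  codes <- with_seed(paradigm$seed, {
    unlist(lapply(seq_len(n_characters * R), function(i) sample.int(K)))
  })
  data.frame(
    char_index = rep(seq_len(n_characters), each = K * R),
    repetition_index = rep(rep(seq_len(R), each = K), times = n_characters),
    flash_index = rep(seq_len(K * R), times = n_characters),
    code = codes
  )
}
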