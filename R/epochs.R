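#' Construct a labeled epoch container
#'
#' The universal currency between pipeline stages: an `n x C x T` array of
#' stimulus-locked EEG segments (`C` channels, `T` samples) with one binary
#' label per epoch (1 = target/P300, 2 = non-target), the flash code that
#' elicited it, and character-trial / repetition bookkeeping.
#'
#' @param data Numeric array `n_epochs x C x T`.
#' @param labels Integer vector in `{1, 2}`; 1 marks target (P300) epochs.
#' @param codes Stimulus code per epoch.
#' @param char_index Character-trial index per epoch.
#' @param repetition_index Repetition index per epoch.
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional channel labels (defaults `ch1`, `ch2`, ...).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, codes = NULL, char_index = NULL,
                      repetition_index = NULL, fs, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be an n_epochs x channels x samples array",
         call. = FALSE)
  }
  if (anyNA(data)) stop("`data` contains NA/NaN values", call. = FALSE)
  n <- dim(data)[1L]
  if (n < 1L) stop("need at least one epoch", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != n || !all(labels %in% c(1L, 2L))) {
    stop("`labels` must have one value in {1, 2} per epoch", call. = FALSE)
  }
  fs <- .check_scalar(fs, "fs", lower = 1e-9)
  fill <- function(x, default) {
    if (is.null(x)) return(default)
    if (length(x) != n) stop("per-epoch metadata length mismatch",
                             call. = FALSE)
    as.integer(x)
  }
  codes <- fill(codes, rep(NA_integer_, n))
  char_index <- fill(char_index, rep(NA_integer_, n))
  repetition_index <- fill(repetition_index, rep(NA_integer_, n))
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(dim(data)[2L]))
  }
  structure(
    list(data = data, labels = labels, codes = codes, char_index = char_index,
         repetition_index = repetition_index, fs = fs,
         channel_names = as.character(channel_names)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs, %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  targets: %d, non-targets: %d\n",
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

# Subset an epoch_set by epoch index (internal).
.subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
            epochs$codes[idx], epochs$char_index[idx],
            epochs$repetition_index[idx], epochs$fs, epochs$channel_names)
}

#' Write / read an epoch container as CSV + JSON sidecar
#'
#' `write_epochs()` stores the epoch array as a flat delimited table
#' (`<path>_data.csv`, one row per epoch-channel, columns `epoch`,
#' `channel`, `t1..tT`) and all metadata as a JSON sidecar
#' (`<path>_meta.json`). `read_epochs()` restores a lossless `epoch_set`.
#'
#' @param epochs An `epoch_set`.
#' @param path Base path (without suffix) for the file pair.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns an `epoch_set`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
  tab <- data.frame(
    epoch = rep(seq_len(d[1L]), each = d[2L]),
    channel = rep(seq_len(d[2L]), times = d[1L])
  )
  colnames(flat) <- paste0("t", seq_len(d[3L]))
  utils::write.csv(cbind(tab, as.data.frame(flat)),
                   paste0(path, "_data.csv"), row.names = FALSE)
  meta <- list(
    n_epochs = d[1L], n_channels = d[2L], n_samples = d[3L],
    labels = epochs$labels, codes = epochs$codes,
    char_index = epochs$char_index,
    repetition_index = epochs$repetition_index,
    fs = epochs$fs, channel_names = epochs$channel_names
  )
  jsonlite::write_json(meta, paste0(path, "_meta.json"), digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  data_file <- paste0(path, "_data.csv")
  meta_file <- paste0(path, "_meta.json")
  for (f in c(data_file, meta_file)) {
    if (!file.exists(f)) stop(sprintf("missing file: %s", f), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (field in c("n_epochs", "n_channels", "n_samples", "labels", "fs")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("epoch container schema error: missing field \"%s\"",
                   field), call. = FALSE)
    }
  }
  tab <- utils::read.csv(data_file)
  d <- c(meta$n_epochs, meta$n_channels, meta$n_samples)
  flat <- as.matrix(tab[, paste0("t", seq_len(d[3L])), drop = FALSE])
  arr <- aperm(array(flat, dim = c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
  to_int_or_null <- function(x) if (is.null(x)) NULL else as.integer(x)
  epoch_set(arr, meta$labels, to_int_or_null(meta$codes),
            to_int_or_null(meta$char_index),
            to_int_or_null(meta$repetition_index),
            meta$fs, meta$channel_names)
}
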