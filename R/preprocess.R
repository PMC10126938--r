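#' Dataset preprocessing profile
#'
#' Bundles the filtering/epoching/decimation parameters of a recording
#' protocol. Two presets are shipped:
#' \describe{
#'   \item{`"bci_comp"`}{6x6 matrix speller recordings at 240 Hz: 0.1-30 Hz
#'     third-order Butterworth band-pass, 667 ms epochs, decimation by 6
#'     (240 -> 40 Hz).}
#'   \item{`"hybrid_rsvp"`}{RSVP recordings at 512 Hz: 0.5-25 Hz linear-phase
#'     FIR band-pass, 1 s epochs, decimation by 10.}
#' }
#'
#' @param name Preset name (`"bci_comp"`, `"hybrid_rsvp"`) or a label for a
#'   custom profile.
#' @param band `c(low, high)` cutoff frequencies in Hz.
#' @param filter_kind `"butterworth"` or `"fir"`.
#' @param filter_order Filter order. For FIR profiles `NULL` selects
#'   `3 * fs / low` taps at filter time (long enough to resolve the low
#'   edge).
#' @param epoch_window Epoch length in seconds.
#' @param decimation_factor Integer subsampling factor.
#' @return An object of class `dataset_profile`.
#' @export
dataset_profile <- function(name = "custom", band, filter_kind = "butterworth",
                            filter_order = 3L, epoch_window,
                            decimation_factor = 1L) {
  if (name %in% c("bci_comp", "hybrid_rsvp") && missing(band)) {
    return(switch(name,
      bci_comp = dataset_profile("bci_comp", band = c(0.1, 30),
                                 filter_kind = "butterworth",
                                 filter_order = 3L, epoch_window = 0.667,
                                 decimation_factor = 6L),
      hybrid_rsvp = dataset_profile("hybrid_rsvp", band = c(0.5, 25),
                                    filter_kind = "fir", filter_order = NULL,
                                    epoch_window = 1.0,
                                    decimation_factor = 10L)
    ))
  }
  stopifnot(length(band) == 2L, band[1L] > 0, band[2L] > band[1L])
  filter_kind <- match.arg(filter_kind, c("butterworth", "fir"))
  structure(list(
    name = name, band = as.numeric(band), filter_kind = filter_kind,
    filter_order = if (is.null(filter_order)) NULL else
      .check_count(filter_order, "filter_order"),
    epoch_window = .check_scalar(epoch_window, "epoch_window", lower = 1e-9),
    decimation_factor = .check_count(decimation_factor, "decimation_factor")
  ), class = "dataset_profile")
}

#' @export
print.dataset_profile <- function(x, ...) {
  cat(sprintf(
    "<dataset_profile> %s: %g-%g Hz %s, %.3g s epochs, decimate /%d\n",
    x$name, x$band[1L], x$band[2L], x$filter_kind, x$epoch_window,
    x$decimation_factor))
  invisible(x)
}

# Zero-phase band-pass of a time x series matrix (internal).
.bandpass_matrix <- function(x, fs, profile) {
  nyq <- fs / 2
  if (profile$band[2L] >= nyq) {
    stop(sprintf("band edge %g Hz >= Nyquist (%g Hz)", profile$band[2L], nyq),
         call. = FALSE)
  }
  x <- as.matrix(x)
  if (profile$filter_kind == "butterworth") {
    bf <- signal::butter(profile$filter_order, profile$band / nyq,
                         type = "pass")
    apply(x, 2L, function(col) signal::filtfilt(bf, col))
  } else {
    ord <- profile$filter_order
    if (is.null(ord)) ord <- ceiling(3 * fs / profile$band[1L])
    ord <- min(ord, max(4L, nrow(x) - 2L))
    if (ord %% 2L == 1L) ord <- ord + 1L  # even order -> symmetric taps
    kern <- signal::fir1(ord, profile$band / nyq, type = "pass")
    .fir_zerophase(x, kern)
  }
}

#' Zero-phase band-pass filtering
#'
#' Applies the profile's band-pass filter forward-backward (Butterworth) or
#' as a symmetric linear-phase FIR (zero phase either way, so ERP latencies
#' are preserved). Works on a continuous session (per channel) or on an
#' epoch container (per epoch and channel); the shape is preserved.
#'
#' @param x A `speller_session`, `epoch_set`, or time x series matrix.
#' @param profile A [dataset_profile()].
#' @param fs Sampling rate; only needed for the matrix method.
#' @return The same type as `x`, filtered.
#' @export
bandpass <- function(x, profile, fs = NULL) UseMethod("bandpass")

#' @export
bandpass.matrix <- function(x, profile, fs = NULL) {
  stopifnot(inherits(profile, "dataset_profile"), !is.null(fs))
  .bandpass_matrix(x, fs, profile)
}

#' @export
bandpass.speller_session <- function(x, profile, fs = NULL) {
  x$signal <- t(.bandpass_matrix(t(x$signal), x$fs, profile))
  x
}

#' @export
bandpass.epoch_set <- function(x, profile, fs = NULL) {
  d <- dim(x$data)
  # time x (epoch*channel) matrix so the filter runs once per series
  m <- t(matrix(x$data, d[1L] * d[2L], d[3L]))
  m <- .bandpass_matrix(m, x$fs, profile)
  x$data <- array(t(m), dim = d)
  x
}

#' Decimate epochs
#'
#' Anti-alias low-pass (symmetric FIR, zero phase, cutoff at the post-
#' decimation Nyquist) followed by keeping every `factor`-th sample starting
#' at the epoch onset. The new length is `floor(T / factor)` and `fs` is
#' divided by `factor`.
#'
#' @param epochs An `epoch_set`.
#' @param factor Integer decimation factor >= 1.
#' @return The decimated `epoch_set`.
#' @export
decimate_epochs <- function(epochs, factor) {
  stopifnot(inherits(epochs, "epoch_set"))
  factor <- .check_count(factor, "factor")
  d <- dim(epochs$data)
  if (factor > d[3L]) stop("decimation factor exceeds epoch length",
                           call. = FALSE)
  if (factor == 1L) return(epochs)
  new_T <- d[3L] %/% factor
  keep <- seq.int(1L, by = factor, length.out = new_T)
  m <- t(matrix(epochs$data, d[1L] * d[2L], d[3L]))   # T x (n*C)
  kern <- signal::fir1(min(20L * factor, 2L * ((d[3L] - 1L) %/% 2L)),
                       1 / factor)
  # zero-phase anti-alias + subsample as one dense operator: evaluate the
  # symmetric-FIR convolution (reflection-padded) only at the kept samples
  half <- (length(kern) - 1L) %/% 2L
  Tn <- d[3L]
  xp <- rbind(m[rev(seq_len(half) + 1L), , drop = FALSE], m,
              m[Tn - seq_len(half), , drop = FALSE])
  D <- matrix(0, new_T, Tn + 2L * half)
  for (k in seq_len(new_T)) {
    D[k, keep[k] + seq_along(kern) - 1L] <- kern
  }
  arr <- array(t(D %*% xp), dim = c(d[1L], d[2L], new_T))
  epoch_set(arr, epochs$labels, epochs$codes, epochs$char_index,
            epochs$repetition_index, epochs$fs / factor,
            epochs$channel_names)
}

#' Balance classes by replicating the minority class
#'
#' Appends whole copies of the minority-class epochs, plus a seeded draw
#' without replacement for the remainder, until both classes have equal
#' counts. All original epochs are retained; intended for training data
#' only (test data keeps the true flash stream).
#'
#' @param epochs An `epoch_set` containing both classes.
#' @param seed Seed for the remainder draw.
#' @return A balanced `epoch_set`.
#' @export
balance_classes <- function(epochs, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  n1 <- sum(epochs$labels == 1L)
  n2 <- sum(epochs$labels == 2L)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present",
                                 call. = FALSE)
  if (n1 == n2) return(epochs)
  minority <- if (n1 < n2) 1L else 2L
  mi <- which(epochs$labels == minority)
  deficit <- abs(n2 - n1)
  full <- deficit %/% length(mi)
  rem <- deficit %% length(mi)
  extra <- rep(mi, times = full)
  if (rem > 0L) {
    extra <- c(extra, with_seed(seed, sample(mi, rem)))
  }
  .subset_epochs(epochs, c(seq_along(epochs$labels), extra))
}

#' One-call preprocessing per profile
#'
#' Band-pass the continuous session, cut epochs at the profile window,
#' decimate, and (optionally) balance classes by replication — the standard
#' epoch preparation ahead of feature learning.
#'
#' @param session A `speller_session`.
#' @param profile A [dataset_profile()].
#' @param balance Replicate minority-class epochs to parity (training data
#'   only).
#' @param seed Seed for the balancing draw.
#' @return An `epoch_set`.
#' @export
preprocess_session <- function(session, profile, balance = FALSE, seed = 1L) {
  ep <- session_to_epochs(bandpass(session, profile), profile$epoch_window)
  ep <- decimate_epochs(ep, profile$decimation_factor)
  if (balance) ep <- balance_classes(ep, seed) else ep
}
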