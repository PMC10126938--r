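#' Parametric ERP template
#'
#' A separable (rank-1) space-time template for the target-evoked response:
#' a Gaussian bump in time centred ~300 ms post-stimulus times a unit-norm
#' spatial loading vector. The defaults mimic the P300 phenomenology — a
#' positive deflection around 300 ms concentrated on a posterior subset of
#' channels — without claiming physiological fidelity.
#'
#' @param latency Peak time post-stimulus in seconds.
#' @param width Gaussian SD in seconds.
#' @param amplitude Base amplitude in signal units (rescaled to the session
#'   SNR by [simulate_session()]); must be >= 0.
#' @param channel_weights Optional per-channel loading vector; normalized to
#'   unit norm. `NULL` defers to a raised-cosine profile over the last third
#'   of the channels, built when the channel count is known.
#' @return An object of class `erp_template`.
#' @export
erp_template <- function(latency = 0.300, width = 0.060, amplitude = 1,
                         channel_weights = NULL) {
  latency <- .check_scalar(latency, "latency", lower = 0)
  width <- .check_scalar(width, "width", lower = 1e-6)
  amplitude <- .check_scalar(amplitude, "amplitude", lower = 0)
  if (!is.null(channel_weights)) {
    channel_weights <- as.numeric(channel_weights)
    nv <- sqrt(sum(channel_weights^2))
    if (nv == 0) stop("channel_weights must be non-zero", call. = FALSE)
    channel_weights <- channel_weights / nv
  }
  structure(list(latency = latency, width = width, amplitude = amplitude,
                 channel_weights = channel_weights),
            class = "erp_template")
}

# Default spatial loading: raised cosine over the last third of channels.
.default_channel_weights <- function(n_channels) {
  k <- max(1L, ceiling(n_channels / 3))
  w <- rep(0, n_channels)
  idx <- seq.int(n_channels - k + 1L, n_channels)
  w[idx] <- 0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1L))
  w / sqrt(sum(w^2))
}

#' Synthetic session configuration
#'
#' @param n_channels Number of EEG channels.
#' @param fs Sampling rate in Hz (`NULL`: 240 Hz for RCP, 512 Hz for RSVP).
#' @param n_characters Number of character trials to simulate.
#' @param snr_db Epoch-level signal-to-noise ratio in dB: the ratio of mean
#'   ERP template power to mean background-noise power within the epoch
#'   window. `-Inf` (or a template amplitude of 0) injects no ERP.
#' @param ar_coeff AR(1) coefficient of the per-channel background noise,
#'   in `[0, 1)`.
#' @param latency_jitter_sd SD of the per-flash latency jitter (seconds).
#' @param amplitude_jitter_sd SD of the multiplicative amplitude jitter
#'   (fraction of the scaled amplitude).
#' @param seed Mandatory integer seed; fully determines the session.
#' @param template An [erp_template()].
#' @param epoch_window_s Window (seconds) over which the SNR is defined
#'   (`NULL`: 0.667 s for RCP, 1 s for RSVP).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 8L, fs = NULL, n_characters = 10L,
                         snr_db = -6, ar_coeff = 0.9,
                         latency_jitter_sd = 0.02, amplitude_jitter_sd = 0.1,
                         seed, template = erp_template(),
                         epoch_window_s = NULL) {
  if (missing(seed)) stop("`seed` is mandatory for synthetic sessions",
                          call. = FALSE)
  structure(list(
    n_channels = .check_count(n_channels, "n_channels"),
    fs = if (is.null(fs)) NULL else .check_scalar(fs, "fs", lower = 1e-9),
    n_characters = .check_count(n_characters, "n_characters"),
    snr_db = .check_scalar(snr_db, "snr_db", allow_infinite = TRUE),
    ar_coeff = .check_scalar(ar_coeff, "ar_coeff", 0, 1 - 1e-9),
    latency_jitter_sd = .check_scalar(latency_jitter_sd,
                                      "latency_jitter_sd", 0),
    amplitude_jitter_sd = .check_scalar(amplitude_jitter_sd,
                                        "amplitude_jitter_sd", 0),
    seed = .check_count(seed, "seed", min = 0L),
    template = template,
    epoch_window_s = if (is.null(epoch_window_s)) NULL else
      .check_scalar(epoch_window_s, "epoch_window_s", lower = 1e-9)
  ), class = "synth_config")
}

#' Simulate an oddball speller session
#'
#' Generates a continuous multichannel recording for a full spelling run:
#' seeded AR(1) background noise per channel, spatially mixed by a random
#' orthogonal matrix (seeded separately from the noise innovations, so the
#' spatial structure is reproducible across SNR sweeps), with the ERP
#' template added at every target flash onset with latency and amplitude
#' jitter. The template amplitude is rescaled so that the epoch-level SNR
#' matches `config$snr_db`. Overlapping ERPs from short inter-stimulus
#' intervals are summed linearly and flagged in the metadata.
#'
#' @param paradigm A [build_paradigm()] spec.
#' @param config A [synth_config()].
#' @param truth Optional ground-truth symbols (defaults to a seeded draw
#'   from the paradigm alphabet).
#' @return An object of class `speller_session` with fields `signal`
#'   (channels x samples), `events` (data frame: `sample`, `code`,
#'   `is_target`, `char_index`, `repetition_index`), `paradigm`, `truth`,
#'   `fs`, `config` and `metadata`.
#' @export
simulate_session <- function(paradigm, config, truth = NULL) {
  stopifnot(inherits(paradigm, "paradigm_spec"),
            inherits(config, "synth_config"))
  fs <- config$fs
  if (is.null(fs)) fs <- if (paradigm$kind == "RCP") 240 else 512
  win_s <- config$epoch_window_s
  if (is.null(win_s)) win_s <- if (paradigm$kind == "RCP") 0.667 else 1.0
  C <- config$n_channels
  n_char <- config$n_characters

  if (is.null(truth)) {
    truth <- with_seed(config$seed + 7L, {
      sample(paradigm$alphabet, n_char, replace = TRUE)
    })
  }
  if (length(truth) != n_char || !all(truth %in% paradigm$alphabet)) {
    stop("`truth` must give one alphabet symbol per character trial",
         call. = FALSE)
  }

  sched <- flash_schedule(paradigm, n_char)
  soa <- paradigm$flash_duration + paradigm$isi
  K <- paradigm$codes_per_repetition
  R <- paradigm$n_repetitions
  char_dur <- K * R * soa
  char_starts <- (seq_len(n_char) - 1L) * (char_dur + paradigm$pause_between_chars)
  onset_t <- char_starts[sched$char_index] + (sched$flash_index - 1L) * soa
  onset <- round(onset_t * fs) + 1L
  n_samples <- max(onset) + as.integer(ceiling((win_s + 0.5) * fs))

  tc <- lapply(seq_len(n_char), function(ci) target_codes(paradigm, truth[ci]))
  is_target <- mapply(function(ci, code) code %in% tc[[ci]],
                      sched$char_index, sched$code)

  # Background: independent unit-variance AR(1) per channel, then an
  # orthogonal spatial mixture (its own seed stream).
  noise <- with_seed(config$seed, {
    innov_sd <- sqrt(1 - config$ar_coeff^2)
    sapply(seq_len(C), function(ch) {
      as.numeric(stats::filter(stats::rnorm(n_samples, sd = innov_sd),
                               config$ar_coeff, method = "recursive"))
    })
  })
  Q <- with_seed(config$seed + 1L, {
    qr.Q(qr(matrix(stats::rnorm(C * C), C, C)))
  })
  sig <- Q %*% t(noise)  # channels x samples

  tmpl <- config$template
  cw <- tmpl$channel_weights
  if (is.null(cw)) cw <- .default_channel_weights(C)
  if (length(cw) != C) stop("channel_weights length != n_channels",
                            call. = FALSE)

  L <- max(1L, floor(win_s * fs))
  tgrid <- (seq_len(L) - 1L) / fs
  bump <- exp(-(tgrid - tmpl$latency)^2 / (2 * tmpl$width^2))
  # Scale so mean template power over the C x L epoch window divided by the
  # unit noise power matches snr_db.
  if (is.finite(config$snr_db) && tmpl$amplitude > 0) {
    amp <- sqrt(10^(config$snr_db / 10) * C * L / sum(bump^2))
  } else {
    amp <- 0
  }

  if (amp > 0) {
    tgt <- which(is_target)
    jit <- with_seed(config$seed + 2L, {
      list(lat = stats::rnorm(length(tgt), 0, config$latency_jitter_sd),
           amp = pmax(0, 1 + stats::rnorm(length(tgt), 0,
                                          config$amplitude_jitter_sd)))
    })
    for (k in seq_along(tgt)) {
      e <- tgt[k]
      b <- exp(-(tgrid - (tmpl$latency + jit$lat[k]))^2 / (2 * tmpl$width^2))
      idx <- onset[e] + seq_len(L) - 1L
      sig[, idx] <- sig[, idx] + (amp * jit$amp[k]) * cw %o% b
    }
  }

  events <- data.frame(sample = onset, code = sched$code,
                       is_target = as.logical(is_target),
                       char_index = sched$char_index,
                       repetition_index = sched$repetition_index)
  structure(list(
    signal = sig, events = events, paradigm = paradigm, truth = truth,
    fs = fs, config = config,
    metadata = list(
      erp_amplitude = amp, channel_weights = cw,
      epoch_window_s = win_s,
      overlapping_epochs = win_s > soa
    )
  ), class = "speller_session")
}

#' @export
print.speller_session <- function(x, ...) {
  cat(sprintf("<speller_session> %s, %d characters, %d events, %d ch @ %g Hz\n",
              x$paradigm$kind, length(x$truth), nrow(x$events),
              nrow(x$signal), x$fs))
  cat(sprintf("  truth: %s\n", paste(x$truth, collapse = "")))
  if (isTRUE(x$metadata$overlapping_epochs)) {
    cat("  note: epoch window exceeds flash spacing (overlapping ERPs)\n")
  }
  invisible(x)
}

#' Cut a continuous session into stimulus-locked epochs
#'
#' One epoch per flash event, time-locked to onset: sample 1 is the onset
#' sample and the window is half-open, `[0, window_s)`, containing
#' `floor(window_s * fs)` samples. Events too close to the end of the
#' recording are dropped with a warning.
#'
#' @param session A [simulate_session()] result (or compatible list).
#' @param window_s Epoch window in seconds (> 0).
#' @return An [epoch_set()] with labels 1 (target) / 2 (non-target).
#' @export
session_to_epochs <- function(session, window_s) {
  stopifnot(inherits(session, "speller_session"))
  window_s <- .check_scalar(window_s, "window_s", lower = 1e-12)
  L <- floor(window_s * session$fs)
  if (L < 1L) stop("`window_s` too short for the sampling rate",
                   call. = FALSE)
  n_total <- ncol(session$signal)
  ev <- session$events
  keep <- ev$sample + L - 1L <= n_total
  if (!all(keep)) {
    warning(sprintf("dropping %d event(s) too close to the recording end",
                    sum(!keep)))
    ev <- ev[keep, , drop = FALSE]
  }
  if (nrow(ev) == 0L) stop("no events fit within the recording",
                           call. = FALSE)
  n <- nrow(ev)
  C <- nrow(session$signal)
  arr <- array(0, dim = c(n, C, L))
  idx <- outer(ev$sample, seq_len(L) - 1L, "+")   # n x L gather index
  for (ch in seq_len(C)) {
    arr[, ch, ] <- session$signal[ch, ][idx]
  }
  epoch_set(arr, labels = ifelse(ev$is_target, 1L, 2L), codes = ev$code,
            char_index = ev$char_index,
            repetition_index = ev$repetition_index, fs = session$fs)
}

#' Write a simulated session to plain-text files
#'
#' Stores the events table as CSV, the continuous signal as CSV (one row
#' per sample, one column per channel) and the remaining metadata
#' (paradigm, truth, seed, sampling rate) as JSON, so a run is fully
#' reproducible from disk.
#'
#' @param session A `speller_session`.
#' @param path Base path (without suffix).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "speller_session"))
  utils::write.csv(session$events, paste0(path, "_events.csv"),
                   row.names = FALSE)
  sigdf <- as.data.frame(t(session$signal))
  names(sigdf) <- paste0("ch", seq_len(nrow(session$signal)))
  utils::write.csv(sigdf, paste0(path, "_signal.csv"), row.names = FALSE)
  meta <- list(
    paradigm = unclass(session$paradigm), truth = session$truth,
    fs = session$fs,
    config = unclass(session$config)[setdiff(names(session$config),
                                             "template")],
    template = unclass(session$config$template),
    metadata = session$metadata
  )
  jsonlite::write_json(meta, paste0(path, "_meta.json"), digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}
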