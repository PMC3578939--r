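# Feature extraction: raw multichannel physiological recordings -> the
# 29-feature epoch schema (EDA min/max/mean, RSP min/max/mean, ECG beat count
# and mean inter-beat interval, and theta/alpha/beta spectral power for the
# seven EEG sites Fp1, Fp2, Fz, Cz, Pz, O1, O2).

EEG_SITES <- c("Fp1", "Fp2", "Fz", "Cz", "Pz", "O1", "O2")

FREQ_BANDS <- list(theta = c(3.5, 7), alpha = c(7.5, 13.5), beta = c(13.5, 19.5))

#' Frozen 29-feature schema
#'
#' The fixed feature order produced by [assemble_feature_vector()]: the three
#' EDA amplitude summaries, the three RSP amplitude summaries, the two ECG
#' features, then for each EEG site in the order Fp1, Fp2, Fz, Cz, Pz, O1, O2
#' the theta, alpha and beta band powers.
#'
#' @return Character vector of length 29.
#' @export
feature_schema <- function() {
  c(paste0("EDA_", c("min", "max", "mean")),
    paste0("RSP_", c("min", "max", "mean")),
    c("ECG_beats", "ECG_ibi"),
    paste0(rep(EEG_SITES, each = 3L), "_", names(FREQ_BANDS)))
}

#' Raw multichannel recording
#'
#' One subject's continuous recording: named channel time series sampled at a
#' common rate (the seven EEG sites plus `EOG`, `EDA`, `RSP`, `ECG`) and an
#' event list giving stimulus times and class labels.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param channels Named list of equal-length numeric vectors.
#' @param events Data.frame with columns `time` (seconds) and `label`.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(sampling_rate, channels, events) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive", call. = FALSE)
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be a named list", call. = FALSE)
  len <- unique(vapply(channels, length, integer(1)))
  if (length(len) != 1L)
    stop("all channels must have the same length", call. = FALSE)
  if (!is.data.frame(events) || !all(c("time", "label") %in% names(events)))
    stop("events must be a data.frame with columns time, label", call. = FALSE)
  dur <- len / sampling_rate
  if (any(events$time < 0 | events$time > dur))
    stop("event times outside the recording", call. = FALSE)
  structure(list(sampling_rate = sampling_rate, channels = channels,
                 events = events),
            class = "raw_recording")
}

#' Cut stimulus-locked epochs from a recording
#'
#' Extracts, for every event, a 3-second window from 1 second before to 2
#' seconds after the stimulus, across all channels. Events without enough
#' pre- or post-stimulus context are skipped with a warning.
#'
#' @param rec A [raw_recording()].
#' @param pre,post Seconds of context before and after the stimulus
#'   (defaults 1 and 2).
#' @return List of epochs, ordered by event time; each epoch is a list with
#'   `channels` (named list of vectors of length `(pre + post) * rate`),
#'   `rate`, `label` and `time`.
#' @export
epoch_signals <- function(rec, pre = 1, post = 2) {
  stopifnot(inherits(rec, "raw_recording"))
  rate <- rec$sampling_rate
  n <- length(rec$channels[[1L]])
  len <- as.integer(round((pre + post) * rate))
  ev <- rec$events[order(rec$events$time), , drop = FALSE]
  epochs <- list()
  for (i in seq_len(nrow(ev))) {
    start <- as.integer(round((ev$time[i] - pre) * rate)) + 1L
    stop_ <- start + len - 1L
    if (start < 1L || stop_ > n) {
      warning(sprintf("event at t=%.3f s too close to a recording edge; skipped",
                      ev$time[i]), call. = FALSE)
      next
    }
    epochs[[length(epochs) + 1L]] <- list(
      channels = lapply(rec$channels, function(ch) ch[start:stop_]),
      rate = rate, label = ev$label[i], time = ev$time[i])
  }
  epochs
}

#' Regression-based EOG artifact removal
#'
#' Removes ocular artifacts from EEG channels by subtracting, per channel,
#' the least-squares projection on the EOG channel: `eeg - b * eog` with
#' `b = cov(eeg, eog) / var(eog)`. The residual is uncorrelated with the EOG.
#' A zero-variance EOG channel leaves the EEG unchanged.
#'
#' @param eeg Named list of EEG channel vectors (or a single vector).
#' @param eog EOG channel vector of the same length.
#' @return Cleaned channels, same shape as `eeg`.
#' @export
remove_eog <- function(eeg, eog) {
  single <- !is.list(eeg)
  if (single) eeg <- list(eeg)
  v <- stats::var(eog)
  if (!is.finite(v) || v == 0) {
    out <- eeg
  } else {
    out <- lapply(eeg, function(ch) {
      if (length(ch) != length(eog))
        stop("EEG and EOG lengths differ", call. = FALSE)
      ch - (stats::cov(ch, eog) / v) * eog
    })
  }
  if (single) out[[1L]] else out
}

# Zero-phase Butterworth bandpass (applied to EEG before spectral features).
bandpass <- function(x, rate, low = 1, high = 20, order = 4L) {
  ny <- rate / 2
  if (high >= ny) stop("bandpass upper edge must be below Nyquist", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Spectral band power of a single channel
#'
#' Mean integrated spectral power in one of the canonical bands theta
#' (3.5-7 Hz), alpha (7.5-13.5 Hz) or beta (13.5-19.5 Hz). The signal is cut
#' into overlapping 1-second windows (50% overlap), each window is linearly
#' detrended, its one-sided periodogram computed, and power is summed over
#' frequency bins inside the band and averaged across windows.
#'
#' @param x Numeric vector, at least one second long.
#' @param band `"theta"`, `"alpha"` or `"beta"`, or a numeric `c(low, high)`
#'   in Hz.
#' @param rate Sampling rate in Hz.
#' @return Non-negative power (unitless; input units squared per Hz,
#'   integrated over the band).
#' @export
band_power <- function(x, band, rate) {
  if (is.character(band)) {
    band <- FREQ_BANDS[[match.arg(band, names(FREQ_BANDS))]]
  }
  if (band[2L] > rate / 2)
    stop("band edge above the Nyquist frequency", call. = FALSE)
  w <- as.integer(round(rate))
  if (length(x) < w) stop("window shorter than 1 s", call. = FALSE)
  hop <- max(1L, w %/% 2L)
  starts <- seq(1L, length(x) - w + 1L, by = hop)
  freqs <- (seq_len(w) - 1L) * rate / w
  sel <- freqs >= band[1L] & freqs <= band[2L] & freqs <= rate / 2
  df <- rate / w
  powers <- vapply(starts, function(s) {
    seg <- x[s:(s + w - 1L)]
    t_ <- seq_along(seg)
    seg <- stats::residuals(stats::lm.fit(cbind(1, t_), seg))
    P <- Mod(stats::fft(seg))^2 / (w * rate)   # two-sided periodogram
    2 * sum(P[sel]) * df                       # one-sided band integral
  }, numeric(1))
  mean(powers)
}

# R-peak detection: light smoothing, block-adaptive threshold at 0.6 x local
# maximum, local-maximum test with a 250 ms refractory period.
detect_r_peaks <- function(x, rate) {
  n <- length(x)
  w <- max(1L, as.integer(round(rate * 0.02)))
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2L))
  sm[is.na(sm)] <- x[is.na(sm)]
  block <- max(1L, as.integer(round(rate / 2)))
  nb <- ceiling(n / block)
  bmax <- vapply(seq_len(nb), function(b) {
    max(sm[((b - 1L) * block + 1L):min(b * block, n)])
  }, numeric(1))
  thr <- vapply(seq_len(n), function(i) {
    b <- (i - 1L) %/% block + 1L
    0.6 * max(bmax[max(1L, b - 1L):min(nb, b + 1L)])
  }, numeric(1))
  left <- c(-Inf, sm[-n]); right <- c(sm[-1L], -Inf)
  cand <- which(sm >= thr & sm >= left & sm > right)
  refract <- as.integer(round(0.25 * rate))
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) == 0L || i - peaks[length(peaks)] >= refract)
      peaks <- c(peaks, i)
  }
  peaks
}

#' Peripheral (EDA, RSP, ECG) features of one epoch
#'
#' EDA and RSP are summarised by their minimum, maximum and mean amplitude in
#' the epoch window. ECG yields the number of detected heartbeats (R peaks)
#' and the mean inter-beat interval in seconds (time between successive R
#' waves). If fewer than two R peaks are detected the IBI is undefined; the
#' epoch length in seconds is emitted as a sentinel, a warning is raised and
#' the result carries attribute `ibi_flagged = TRUE`.
#'
#' @param epoch An epoch from [epoch_signals()] with `EDA`, `RSP` and `ECG`
#'   channels.
#' @return Named numeric vector of length 8.
#' @export
peripheral_features <- function(epoch) {
  ch <- epoch$channels
  need <- c("EDA", "RSP", "ECG")
  if (!all(need %in% names(ch)))
    stop("epoch lacks one of the channels EDA, RSP, ECG", call. = FALSE)
  peaks <- detect_r_peaks(ch$ECG, epoch$rate)
  flagged <- FALSE
  if (length(peaks) >= 2L) {
    ibi <- mean(diff(peaks)) / epoch$rate
  } else {
    ibi <- length(ch$ECG) / epoch$rate
    flagged <- TRUE
    warning("fewer than 2 R peaks detected; IBI set to the epoch length",
            call. = FALSE)
  }
  out <- c(EDA_min = min(ch$EDA), EDA_max = max(ch$EDA), EDA_mean = mean(ch$EDA),
           RSP_min = min(ch$RSP), RSP_max = max(ch$RSP), RSP_mean = mean(ch$RSP),
           ECG_beats = length(peaks), ECG_ibi = ibi)
  if (flagged) attr(out, "ibi_flagged") <- TRUE
  out
}

#' Assemble the 29-feature vector of one epoch
#'
#' Computes the full feature schema (see [feature_schema()]) for one epoch:
#' peripheral features from the raw EDA/RSP/ECG channels, and theta/alpha/beta
#' band powers per EEG site after optional EOG regression and zero-phase
#' 1-20 Hz bandpass filtering.
#'
#' @param epoch An epoch from [epoch_signals()] containing all EEG sites and
#'   the `EOG`, `EDA`, `RSP`, `ECG` channels.
#' @param eog_correct Apply [remove_eog()] to the EEG channels first?
#' @param filter_eeg Apply the 1-20 Hz zero-phase bandpass before the band
#'   powers?
#' @return Named numeric vector of length 29, in schema order.
#' @export
assemble_feature_vector <- function(epoch, eog_correct = TRUE, filter_eeg = TRUE) {
  ch <- epoch$channels
  if (!all(EEG_SITES %in% names(ch)))
    stop("epoch lacks EEG channels: ",
         paste(setdiff(EEG_SITES, names(ch)), collapse = ", "), call. = FALSE)
  periph <- peripheral_features(epoch)
  eeg <- ch[EEG_SITES]
  if (eog_correct) {
    if (!"EOG" %in% names(ch)) stop("epoch lacks EOG channel", call. = FALSE)
    eeg <- remove_eog(eeg, ch$EOG)
  }
  eeg_feats <- unlist(lapply(EEG_SITES, function(site) {
    x <- eeg[[site]]
    if (filter_eeg) x <- bandpass(x, epoch$rate)
    vapply(names(FREQ_BANDS), function(b) band_power(x, b, epoch$rate),
           numeric(1))
  }))
  out <- c(as.numeric(periph), as.numeric(eeg_feats))
  names(out) <- feature_schema()
  out
}

#' Extract a feature dataset from a raw recording
#'
#' Full pipeline: epoch the recording, compute the 29-feature vector per
#' epoch, and return one [feature_dataset()] (unnormalized; apply
#' [minmax_normalize()] before classifier use).
#'
#' @param rec A [raw_recording()].
#' @param subject_id Subject identifier for the resulting dataset.
#' @param n_classes Number of classes (default: maximum event label).
#' @inheritParams assemble_feature_vector
#' @return A [feature_dataset()] with one row per retained epoch.
#' @export
extract_features <- function(rec, subject_id, n_classes = NULL,
                             eog_correct = TRUE, filter_eeg = TRUE) {
  epochs <- epoch_signals(rec)
  if (length(epochs) == 0L) stop("no epochs could be extracted", call. = FALSE)
  X <- t(vapply(epochs, assemble_feature_vector, numeric(29L),
                eog_correct = eog_correct, filter_eeg = filter_eeg))
  y <- vapply(epochs, `[[`, numeric(1), "label")
  feature_dataset(subject_id, X, y, feature_names = feature_schema(),
                  n_classes = n_classes)
}

#' Per-subject min-max normalization to [0, 1]
#'
#' Rescales every feature column of one subject's dataset to `[0, 1]` by
#' `(x - min) / (max - min)` over that subject's epochs. Constant columns map
#' to 0 (a deterministic convention avoiding division by zero). The
#' operation is idempotent.
#'
#' @param ds A [feature_dataset()] with at least 2 epochs.
#' @return A [feature_dataset()] with all columns in `[0, 1]`.
#' @export
minmax_normalize <- function(ds) {
  stopifnot(inherits(ds, "feature_dataset"))
  if (nrow(ds$X) < 2L) stop("normalization needs at least 2 epochs", call. = FALSE)
  X <- apply(ds$X, 2L, function(col) {
    rng <- range(col)
    if (rng[1L] == rng[2L]) rep(0, length(col))
    else (col - rng[1L]) / (rng[2L] - rng[1L])
  })
  feature_dataset(ds$subject_id, X, ds$y, feature_names = ds$feature_names,
                  n_classes = ds$n_classes)
}
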