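#' Re-reference a recording to the mean of reference channels
#'
#' Subtracts the sample-wise arithmetic mean of the reference derivations
#' (by default the midline trio, i.e. (Fz + Cz + Pz)/3) from every channel.
#' Applied before filtering. The operation is idempotent: after the first
#' pass the mean of the reference channels is identically zero.
#'
#' @param rec an `eeg_recording`.
#' @param ref_labels channel labels to average into the reference.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, ref_labels = c("Fz", "Cz", "Pz")) {
  validate_recording(rec)
  missing_ref <- setdiff(ref_labels, rec$labels)
  if (length(missing_ref)) {
    stop("reference channel(s) not present: ",
         paste(missing_ref, collapse = ", "))
  }
  ref <- colMeans(rec$data[ref_labels, , drop = FALSE])
  rec$data <- sweep(rec$data, 2L, ref, `-`)
  rec$provenance <- c(rec$provenance,
                      paste0("rereference:(", paste(ref_labels, collapse = "+"),
                             ")/", length(ref_labels)))
  rec
}

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth filter forward and backward (`signal::filtfilt`) to
#' every channel, so no group delay is introduced and downstream phase
#' estimates are unbiased. The high-pass and low-pass sections are cascaded
#' rather than designed as a single band-pass, which keeps the recursion
#' numerically stable at the very low normalized high-pass corner typical of
#' EEG (0.5 Hz).
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi band edges in Hz; must satisfy `0 < lo < hi < fs/2`.
#' @param order Butterworth order of each section.
#' @return The filtered `eeg_recording`, same length as the input.
#' @export
bandpass_filter <- function(rec, lo = 0.5, hi = 60, order = 4) {
  validate_recording(rec)
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi)) stop("band edges must satisfy 0 < lo < hi")
  if (hi >= nyq) {
    stop("upper band edge (", hi, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  }
  hp <- signal::butter(order, lo / nyq, type = "high")
  lp <- signal::butter(order, hi / nyq, type = "low")
  rec$data <- t(apply(rec$data, 1L, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x))))
  rec$provenance <- c(rec$provenance,
                      sprintf("bandpass:butterworth_order%d_%g-%gHz_zerophase",
                              order, lo, hi))
  rec
}

#' Resample a recording with anti-aliasing
#'
#' Downsamples each channel by zero-phase Butterworth low-pass filtering at
#' 90% of the target Nyquist frequency followed by cubic-spline evaluation
#' at the new sample times. Only downsampling (or the identity) is
#' supported; `onset_s` is expressed in seconds and is unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs target sampling rate in Hz, `<= rec$fs`.
#' @return The resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_fs = 200) {
  validate_recording(rec)
  if (target_fs > rec$fs) {
    stop("upsampling (", rec$fs, " -> ", target_fs, " Hz) is not supported")
  }
  if (target_fs == rec$fs) return(rec)
  n_in <- ncol(rec$data)
  n_out <- floor(n_in * target_fs / rec$fs)
  t_in <- (seq_len(n_in) - 1) / rec$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  lp <- signal::butter(8, 0.9 * (target_fs / 2) / (rec$fs / 2), type = "low")
  rec$data <- t(apply(rec$data, 1L, function(x) {
    spline(x = t_in, y = signal::filtfilt(lp, x), xout = t_out)$y
  }))
  rownames(rec$data) <- rec$labels
  rec$provenance <- c(rec$provenance,
                      sprintf("resample:%g->%gHz_antialias", rec$fs, target_fs))
  rec$fs <- target_fs
  rec
}

#' Cut a recording into non-overlapping fixed-length windows
#'
#' Segments the recording into contiguous windows of `W` samples (5 s at the
#' study's 200 Hz with the default `W = 1000`); a trailing partial window is
#' discarded so every window is statistically comparable. Window times are
#' reported both absolutely (`t0_s`) and relative to seizure onset
#' (`rel_onset_s`), using the window start.
#'
#' @param rec an `eeg_recording`.
#' @param W window length in samples.
#' @return An object of class `window_series`: the windowed data plus
#'   per-window timing and all recording metadata.
#' @export
segment_windows <- function(rec, W = 1000) {
  validate_recording(rec)
  n <- ncol(rec$data)
  if (n < W) {
    stop("recording (", n, " samples) is shorter than one window (", W, ")")
  }
  n_win <- n %/% W
  t0 <- (seq_len(n_win) - 1) * W / rec$fs
  structure(
    list(
      data = rec$data[, seq_len(n_win * W), drop = FALSE],
      labels = rec$labels,
      groups = rec$groups,
      fs = rec$fs,
      W = W,
      n_windows = n_win,
      t0_s = t0,
      rel_onset_s = t0 - rec$onset_s,
      onset_s = rec$onset_s,
      lateralization = rec$lateralization,
      provenance = c(rec$provenance, sprintf("segment:W=%d", W))
    ),
    class = "window_series"
  )
}

#' @export
print.window_series <- function(x, ...) {
  cat("<window_series> ", x$n_windows, " windows x ", length(x$labels),
      " channels, W = ", x$W, " samples (", x$W / x$fs, " s)\n", sep = "")
  invisible(x)
}

#' Extract one window as a channels-by-W matrix
#'
#' @param ws a `window_series`.
#' @param k window index (1-based).
#' @param channels optional channel subset.
#' @return numeric matrix, channels x W.
#' @export
window_data <- function(ws, k, channels = NULL) {
  stopifnot(inherits(ws, "window_series"), k >= 1, k <= ws$n_windows)
  idx <- ((k - 1) * ws$W + 1):(k * ws$W)
  m <- ws$data[, idx, drop = FALSE]
  if (!is.null(channels)) m <- m[channels, , drop = FALSE]
  m
}
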