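#' Baseline-normalised excitability
#'
#' For each channel the per-sample excitability is the absolute first
#' difference divided by the sampling interval, `S_i(k) = |x_i(k+1) -
#' x_i(k)| / dt` (in microvolts per second); each window is summarised by the
#' mean of its per-sample values. A reference scale `sigma_ref` is the
#' standard deviation of the per-window summaries over the first
#' `baseline_windows` windows (which must lie in the preictal stage), and the
#' normalised excitability is `S_norm = S / sigma_ref`. Values above 2.5 mark
#' epileptiform activity (see [count_suprathreshold()]).
#'
#' @param ws a `window_series`.
#' @param baseline_windows number of initial windows defining the baseline.
#' @param dt sampling interval in seconds; defaults to `1 / ws$fs`.
#' @param baseline `"window"` takes the SD of the per-window summaries
#'   (default); `"pooled"` pools all per-sample values of the baseline
#'   windows before taking the SD.
#' @return An `excitability_trace`: list with `S_norm` and `S_raw`
#'   (channels x windows matrices), `sigma_ref`, timing vectors and the
#'   parameters used.
#' @export
excitability <- function(ws, baseline_windows = 12, dt = NULL,
                         baseline = c("window", "pooled")) {
  stopifnot(inherits(ws, "window_series"))
  baseline <- match.arg(baseline)
  if (is.null(dt)) dt <- 1 / ws$fs
  if (ws$n_windows <= baseline_windows) {
    stop("need more than ", baseline_windows, " windows, got ", ws$n_windows)
  }
  n_ch <- length(ws$labels)
  # per-sample |dx|/dt, channels x (n_win * W - per-window last diff dropped)
  S_raw <- matrix(NA_real_, n_ch, ws$n_windows,
                  dimnames = list(ws$labels, NULL))
  pooled <- if (baseline == "pooled") vector("list", baseline_windows)
  for (k in seq_len(ws$n_windows)) {
    m <- window_data(ws, k)
    s <- abs(m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]) / dt
    S_raw[, k] <- rowMeans(s)
    if (baseline == "pooled" && k <= baseline_windows) pooled[[k]] <- s
  }
  sigma_ref <- if (baseline == "window") {
    apply(S_raw[, seq_len(baseline_windows), drop = FALSE], 1L, sd)
  } else {
    apply(do.call(cbind, pooled), 1L, sd)
  }
  degenerate <- ws$labels[!is.finite(sigma_ref) | sigma_ref == 0]
  if (length(degenerate)) {
    stop("degenerate baseline (sigma_ref = 0) for channel(s): ",
         paste(degenerate, collapse = ", "))
  }
  structure(
    list(
      S_norm = S_raw / sigma_ref,
      S_raw = S_raw,
      sigma_ref = sigma_ref,
      baseline_windows = baseline_windows,
      baseline = baseline,
      dt = dt,
      t0_s = ws$t0_s,
      rel_onset_s = ws$rel_onset_s,
      groups = ws$groups
    ),
    class = "excitability_trace"
  )
}

#' Count channels with suprathreshold excitability per window
#'
#' Channels are counted when their normalised excitability strictly exceeds
#' the threshold (`S_norm > thr`); a value exactly at the threshold is not
#' counted. Global event markers typically use "more than 4 channels",
#' mesial-only views "more than 5".
#'
#' @param tr an `excitability_trace`.
#' @param thr threshold on the normalised excitability.
#' @param channels optional channel subset to count within.
#' @return A tibble with `window`, `rel_onset_s` and integer `count`.
#' @export
count_suprathreshold <- function(tr, thr = 2.5, channels = NULL) {
  stopifnot(inherits(tr, "excitability_trace"))
  m <- tr$S_norm
  if (!is.null(channels)) m <- m[channels, , drop = FALSE]
  tibble::tibble(
    window = seq_len(ncol(m)),
    rel_onset_s = tr$rel_onset_s,
    count = as.integer(colSums(m > thr))
  )
}

periodogram_band <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  k <- seq_len(floor(n / 2))       # positive frequencies, DC excluded
  f <- k * fs / n
  keep <- f >= band[1] & f <= band[2]
  list(power = p[k + 1L][keep], freq = f[keep])
}

#' Per-channel spectral entropy
#'
#' For each channel and window the periodogram restricted to the analysis
#' band is normalised to unit sum and its Shannon entropy (natural log,
#' with `0 * log 0 := 0`) is returned. A flat spectrum gives
#' `log(n_freq)`; a single dominant line gives 0, so the measure drops when
#' an ictal rhythm takes over the trace. An all-zero window yields `NA` with
#' a warning.
#'
#' @param ws a `window_series`.
#' @param band analysis band in Hz (matching the acquisition filter).
#' @return A `spectral_entropy_trace`: list with `SE_chan`
#'   (channels x windows, in nats), `n_freq`, `band` and timing vectors.
#' @export
spectral_entropy <- function(ws, band = c(0.5, 60)) {
  stopifnot(inherits(ws, "window_series"))
  if (ws$W < 2) stop("window length must be at least 2 samples")
  n_ch <- length(ws$labels)
  se <- matrix(NA_real_, n_ch, ws$n_windows, dimnames = list(ws$labels, NULL))
  n_freq <- NULL
  for (k in seq_len(ws$n_windows)) {
    m <- window_data(ws, k)
    for (i in seq_len(n_ch)) {
      pg <- periodogram_band(m[i, ], ws$fs, band)
      if (is.null(n_freq)) n_freq <- length(pg$power)
      tot <- sum(pg$power)
      if (tot <= 0) next  # stays NA
      p <- pg$power / tot
      p <- p[p > 0]
      se[i, k] <- -sum(p * log(p))
    }
  }
  if (anyNA(se)) {
    warning("undefined spectrum (all-zero window) for ", sum(is.na(se)),
            " channel-window(s); recorded as NA")
  }
  structure(
    list(SE_chan = se, n_freq = n_freq, band = band,
         t0_s = ws$t0_s, rel_onset_s = ws$rel_onset_s, groups = ws$groups),
    class = "spectral_entropy_trace"
  )
}

#' Average spectral entropy over a channel set
#'
#' Arithmetic mean of the per-channel spectral entropy over the given set,
#' per window. Missing (flagged) entries are excluded with the divisor
#' adjusted; the number excluded is reported per window.
#'
#' @param tr a `spectral_entropy_trace`.
#' @param channels channel labels to average over (non-empty).
#' @return A tibble with `window`, `rel_onset_s`, `value` and `n_missing`.
#' @export
average_se <- function(tr, channels) {
  stopifnot(inherits(tr, "spectral_entropy_trace"))
  if (length(channels) == 0) stop("`channels` must be a non-empty channel set")
  m <- tr$SE_chan[channels, , drop = FALSE]
  tibble::tibble(
    window = seq_len(ncol(m)),
    rel_onset_s = tr$rel_onset_s,
    value = colMeans(m, na.rm = TRUE),
    n_missing = as.integer(colSums(is.na(m)))
  )
}

#' Moving average for display
#'
#' Smooths a per-window trace for plotting (never used in the statistics).
#' Edges use the mean of the available points, so a constant series stays
#' constant.
#'
#' @param x numeric series.
#' @param span number of windows to average over.
#' @param align `"center"` (default) or `"trailing"`.
#' @return numeric series of the same length.
#' @export
moving_average <- function(x, span = 10, align = c("center", "trailing")) {
  align <- match.arg(align)
  stopifnot(span >= 1)
  n <- length(x)
  span <- as.integer(span)
  vapply(seq_len(n), function(i) {
    if (align == "center") {
      lo <- max(1L, i - (span %/% 2L))
      hi <- min(n, i + ((span - 1L) %/% 2L))
    } else {
      lo <- max(1L, i - span + 1L)
      hi <- i
    }
    mean(x[lo:hi])
  }, numeric(1))
}
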