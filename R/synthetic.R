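#' Configuration for the synthetic seizure-recording generator
#'
#' The generator emulates the statistical structure the pipeline assumes in
#' a combined scalp + foramen-ovale montage: broadband weakly/moderately
#' coupled preictal activity, an ictal rise in global coupling, a narrowband
#' dominant rhythm after onset (which lowers spectral entropy), and a
#' lateralized mesial coupling deficit that persists across stages.
#'
#' Each channel is a unit-variance mixture of a private noise source, one
#' anatomical group driver and one global driver (variance shares
#' `base_coupling` and `global_coupling`, so within-group correlation is
#' about `base_coupling + global_coupling` and between-group correlation
#' about `global_coupling`). On the ipsilateral mesial side the group-driver
#' share is multiplied by `ipsi_deficit`. After `onset_s` the global-driver
#' variance share is multiplied by `ictal_gain` and a shared sinusoid at
#' `ictal_freq` Hz, ramping over `ramp_s` seconds to `ictal_amp` times the
#' background RMS, is added to a fraction `ictal_fraction` of the eligible
#' channels. Ipsilateral mesial channels receive the rhythm scaled by
#' `max(0, 2 * ipsi_deficit - 1)`, so a strong coupling deficit
#' (`ipsi_deficit <= 0.5`) keeps the ipsilateral subnetwork out of the
#' dominant ictal rhythm while `ipsi_deficit = 1` treats both sides equally.
#'
#' @param seed RNG seed (integer).
#' @param fs sampling rate in Hz.
#' @param duration_s,onset_s recording length and seizure onset, seconds.
#' @param n_scalp number of scalp channels (split evenly left/right).
#' @param n_foe_per_side mesial contacts per side.
#' @param base_coupling within-group driver variance share in \[0, 1).
#' @param global_coupling global driver variance share.
#' @param ictal_gain multiplicative post-onset increase of the global share
#'   (`>= 1`).
#' @param ictal_freq dominant ictal rhythm in Hz.
#' @param ictal_amp rhythm amplitude relative to background RMS (0 disables).
#' @param ictal_fraction fraction of channels receiving the rhythm.
#' @param ipsi_deficit factor in (0, 1\] scaling ipsilateral mesial coupling.
#' @param lateralization `"left"` or `"right"`.
#' @param noise_model `"pink"` (1/f-shaped, EEG-like) or `"white"`.
#' @param ramp_s rhythm amplitude ramp length in seconds (avoids an onset
#'   discontinuity dominating excitability).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L, fs = 200, duration_s = 300,
                         onset_s = 150, n_scalp = 16, n_foe_per_side = 6,
                         base_coupling = 0.6, global_coupling = 0.05,
                         ictal_gain = 3, ictal_freq = 7, ictal_amp = 2,
                         ictal_fraction = 0.8, ipsi_deficit = 0.5,
                         lateralization = c("left", "right"),
                         noise_model = c("pink", "white"), ramp_s = 10) {
  lateralization <- match.arg(lateralization)
  noise_model <- match.arg(noise_model)
  cfg <- list(seed = as.integer(seed), fs = fs, duration_s = duration_s,
              onset_s = onset_s, n_scalp = n_scalp,
              n_foe_per_side = n_foe_per_side, base_coupling = base_coupling,
              global_coupling = global_coupling, ictal_gain = ictal_gain,
              ictal_freq = ictal_freq, ictal_amp = ictal_amp,
              ictal_fraction = ictal_fraction, ipsi_deficit = ipsi_deficit,
              lateralization = lateralization, noise_model = noise_model,
              ramp_s = ramp_s)
  stopifnot(
    cfg$base_coupling >= 0, cfg$base_coupling <= 1,
    cfg$global_coupling >= 0,
    cfg$base_coupling + cfg$global_coupling * cfg$ictal_gain < 1,
    cfg$ictal_gain >= 1,
    cfg$ipsi_deficit > 0, cfg$ipsi_deficit <= 1,
    cfg$onset_s < cfg$duration_s, cfg$onset_s > 0,
    cfg$ictal_fraction >= 0, cfg$ictal_fraction <= 1,
    cfg$n_scalp %% 2 == 0
  )
  structure(cfg, class = "synth_config")
}

scalp_labels_1020 <- list(
  left = c("Fp1", "F3", "C3", "P3", "O1", "F7", "T3", "T5"),
  right = c("Fp2", "F4", "C4", "P4", "O2", "F8", "T4", "T6")
)

synth_montage <- function(cfg) {
  n_side <- cfg$n_scalp / 2
  sl <- if (n_side <= 8) scalp_labels_1020$left[seq_len(n_side)] else
    paste0("L", seq_len(n_side))
  sr <- if (n_side <= 8) scalp_labels_1020$right[seq_len(n_side)] else
    paste0("R", seq_len(n_side))
  ml <- paste0("LFOE", seq_len(cfg$n_foe_per_side))
  mr <- paste0("RFOE", seq_len(cfg$n_foe_per_side))
  labels <- c(sl, sr, ml, mr)
  groups <- stats::setNames(
    rep(channel_groups, times = c(n_side, n_side,
                                  cfg$n_foe_per_side, cfg$n_foe_per_side)),
    labels)
  list(labels = labels, groups = groups)
}

noise_series <- function(n, model) {
  w <- stats::rnorm(n)
  if (model == "white") return(w)
  # 1/f amplitude shaping in the frequency domain
  W <- fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)            # two-sided frequency index
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(fft(W * shape, inverse = TRUE) / n)
  x / sd(x)
}

#' Generate a synthetic multichannel recording with ground truth
#'
#' Draws a seeded surrogate recording under the mixture model described in
#' [synth_config()] and returns it together with the qualitative orderings
#' the configuration implies, for parameter-recovery tests.
#'
#' @param cfg a `synth_config`.
#' @return list with `recording` (an `eeg_recording`, unit-background-RMS
#'   "microvolt" scale) and `ground_truth` (config echo plus expected
#'   orderings: `coupling_post_gt_pre`, `ipsi_lt_contra`, `se_post_lt_pre`).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  mont <- synth_montage(cfg)
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  ictal <- t >= cfg$onset_s

  drivers <- lapply(channel_groups, function(g)
    noise_series(n, cfg$noise_model))
  names(drivers) <- channel_groups
  global <- noise_series(n, cfg$noise_model)

  ipsi_group <- paste0("mesial_", cfg$lateralization)
  b <- cfg$global_coupling
  b_t <- ifelse(ictal, b * cfg$ictal_gain, b)   # per-sample global share
  w_glob <- sqrt(b_t)

  # shared ictal rhythm, amplitude ramp after onset
  ramp <- pmin(pmax((t - cfg$onset_s) / cfg$ramp_s, 0), 1)
  rhythm <- sin(2 * pi * cfg$ictal_freq * t) * ramp * cfg$ictal_amp
  kappa_ipsi <- max(0, 2 * cfg$ipsi_deficit - 1)

  # deterministic interleaved choice of rhythm-carrying channels
  labels <- mont$labels
  n_rhythm <- round(cfg$ictal_fraction * length(labels))
  rhythm_idx <- unique(round(seq(1, length(labels),
                                 length.out = max(n_rhythm, 0))))
  carries <- seq_along(labels) %in% rhythm_idx

  data <- matrix(NA_real_, length(labels), n,
                 dimnames = list(labels, NULL))
  for (i in seq_along(labels)) {
    g <- mont$groups[labels[i]]
    a_i <- cfg$base_coupling * if (g == ipsi_group) cfg$ipsi_deficit else 1
    w_priv <- sqrt(pmax(1 - a_i - b_t, 0))
    x <- w_priv * noise_series(n, cfg$noise_model) +
      sqrt(a_i) * drivers[[g]] + w_glob * global
    if (carries[i] && cfg$ictal_amp > 0) {
      scale_i <- if (g == ipsi_group) kappa_ipsi else 1
      x <- x + rhythm * scale_i
    }
    data[i, ] <- x
  }

  rec <- new_recording(data, fs = cfg$fs, groups = mont$groups,
                       onset_s = cfg$onset_s,
                       lateralization = cfg$lateralization,
                       provenance = sprintf("synthetic:seed=%d", cfg$seed))
  truth <- structure(
    list(
      config = cfg,
      coupling_post_gt_pre = cfg$ictal_gain > 1 || cfg$ictal_amp > 0,
      ipsi_lt_contra = cfg$ipsi_deficit < 1,
      se_post_lt_pre = cfg$ictal_amp > 0
    ),
    class = "synth_truth"
  )
  list(recording = rec, ground_truth = truth)
}

#' Write a synthetic fixture bundle
#'
#' Writes the recording via [write_recording()] plus, when given, the ground
#' truth as JSON. Output is deterministic: two runs from the same seed give
#' byte-identical files.
#'
#' @param rec an `eeg_recording`.
#' @param dir output directory.
#' @param name file basename.
#' @param ground_truth optional `synth_truth` to serialize alongside.
#' @return Invisibly, named vector of written paths.
#' @export
write_fixture <- function(rec, dir, name = "recording", ground_truth = NULL) {
  paths <- write_recording(rec, dir, name)
  if (!is.null(ground_truth)) {
    gt_path <- file.path(dir, paste0(name, "_truth.json"))
    gt <- ground_truth
    gt$config <- unclass(gt$config)
    jsonlite::write_json(unclass(gt), gt_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, truth = gt_path)
  }
  invisible(paths)
}
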