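#' @importFrom rlang .data
#' @importFrom stats sd fft spline pnorm psignrank var cor p.adjust
#' @importFrom utils read.table write.table head tail
NULL

#' Channel group labels
#'
#' The four anatomical groups a channel may belong to: left/right scalp
#' electrodes (10-20 system) and left/right mesial contacts (foramen ovale
#' electrodes, FOE). These four groups define the anatomical partition used
#' by [modularity_score()].
#'
#' @export
channel_groups <- c("scalp_left", "scalp_right", "mesial_left", "mesial_right")

#' Construct a multichannel recording
#'
#' A recording bundles a channels-by-samples signal matrix (in microvolts)
#' with its sampling rate, the anatomical group of every channel, the
#' seizure-onset time and the clinical lateralization.
#'
#' @param data numeric matrix, channels x samples; rownames are taken as
#'   channel labels when `labels` is `NULL`.
#' @param fs sampling rate in Hz.
#' @param groups named character vector mapping each channel label to one of
#'   [channel_groups].
#' @param onset_s seizure-onset time in seconds from recording start.
#' @param lateralization `"left"` or `"right"`: the clinically diagnosed side
#'   of seizure origin, or `NA` when unknown.
#' @param labels optional character vector of channel labels.
#' @param provenance character vector describing processing already applied.
#'
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, groups, onset_s,
                          lateralization = NA_character_,
                          labels = NULL, provenance = character()) {
  data <- as.matrix(data)
  if (!is.null(labels)) rownames(data) <- labels
  if (is.null(rownames(data))) {
    stop("channel labels are required (rownames of `data` or `labels`)")
  }
  rec <- structure(
    list(
      labels = rownames(data),
      fs = fs,
      data = data,
      groups = groups,
      onset_s = onset_s,
      lateralization = lateralization,
      provenance = provenance
    ),
    class = "eeg_recording"
  )
  validate_recording(rec)
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (anyDuplicated(rec$labels)) {
    dup <- unique(rec$labels[duplicated(rec$labels)])
    stop("duplicated channel label(s): ", paste(dup, collapse = ", "))
  }
  dur <- ncol(rec$data) / rec$fs
  if (!is.na(rec$onset_s) && (rec$onset_s < 0 || rec$onset_s > dur)) {
    stop("`onset_s` (", rec$onset_s, " s) lies outside the recording (",
         signif(dur, 6), " s)")
  }
  unknown_grp <- setdiff(unique(unname(rec$groups)), channel_groups)
  if (length(unknown_grp)) {
    stop("unknown channel group(s): ", paste(unknown_grp, collapse = ", "))
  }
  if (!is.na(rec$lateralization) &&
      !rec$lateralization %in% c("left", "right")) {
    stop("`lateralization` must be \"left\", \"right\" or NA")
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", signif(ncol(x$data) / x$fs, 5), " s)\n",
      sep = "")
  grp <- table(factor(x$groups[x$labels], levels = channel_groups))
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = " "), "\n")
  cat("  onset:", x$onset_s, "s  lateralization:",
      x$lateralization %||% NA, "\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return scalar seconds.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Channels belonging to a scope
#'
#' @param rec an `eeg_recording` (or a `window_series`).
#' @param scope `"global"` (all mapped channels), one of [channel_groups], or
#'   `"mesial_left"` / `"mesial_right"`.
#' @return character vector of channel labels.
#' @export
scope_channels <- function(rec, scope = "global") {
  labs <- if (inherits(rec, "window_series")) rec$labels else rec$labels
  grp <- rec$groups[labs]
  if (scope == "global") return(labs[!is.na(grp)])
  if (!scope %in% channel_groups) stop("unknown scope: ", scope)
  labs[!is.na(grp) & grp == scope]
}

#' Read a multichannel recording from a delimited file
#'
#' The data file holds one header row of channel labels and one row per
#' sample (the ASCII-export layout of clinical EEG software); tab and comma
#' separators are auto-detected. Channel metadata (groups, sampling rate,
#' onset, lateralization) comes from a YAML channel-map file, see
#' [write_recording()] for the layout.
#'
#' @param path path to the delimited data file.
#' @param channel_map path to the YAML channel map / metadata file.
#' @param format only `"delimited"` is supported.
#' @param drop_unmapped if `TRUE`, channels absent from the map are dropped
#'   with a warning instead of raising an error.
#'
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, channel_map, format = "delimited",
                           drop_unmapped = FALSE) {
  format <- match.arg(format, c("delimited", "edf"))
  if (format == "edf") {
    stop("EDF input is not supported; export the recording to a delimited ",
         "text matrix (one header row of labels, one row per sample)")
  }
  if (!file.exists(path)) stop("data file not found: ", path)
  if (!file.exists(channel_map)) stop("channel map not found: ", channel_map)

  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  labels <- colnames(df)
  if (anyDuplicated(labels)) {
    stop("duplicated channel label(s) in header: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }

  meta <- yaml::read_yaml(channel_map)
  for (field in c("fs", "groups")) {
    if (is.null(meta[[field]])) stop("channel map is missing field: ", field)
  }
  groups <- unlist(meta$groups)

  unmapped <- setdiff(labels, names(groups))
  if (length(unmapped)) {
    if (!drop_unmapped) {
      stop("channel(s) without a group in the map: ",
           paste(unmapped, collapse = ", "),
           " (set drop_unmapped = TRUE to discard them)")
    }
    warning("dropping unmapped channel(s): ", paste(unmapped, collapse = ", "))
    df <- df[, setdiff(labels, unmapped), drop = FALSE]
    labels <- colnames(df)
  }

  new_recording(
    data = t(as.matrix(df)),
    fs = meta$fs,
    groups = groups[labels],
    onset_s = meta$onset_s %||% NA_real_,
    lateralization = meta$lateralization %||% NA_character_,
    provenance = paste0("loaded:", basename(path))
  )
}

#' Write a recording as a delimited fixture bundle
#'
#' Writes the signal matrix as a tab-separated file (header row of labels,
#' one row per sample, full double precision so a read/write round trip is
#' exact) plus a YAML channel-map file carrying `fs`, `groups`, `onset_s`
#' and `lateralization`. The bundle is readable by [read_recording()].
#'
#' @param rec an `eeg_recording`.
#' @param dir output directory (created if needed).
#' @param name basename for the two files (`<name>_data.tsv`,
#'   `<name>_map.yaml`).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_recording <- function(rec, dir, name = "recording") {
  validate_recording(rec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data_path <- file.path(dir, paste0(name, "_data.tsv"))
  map_path <- file.path(dir, paste0(name, "_map.yaml"))

  con <- file(data_path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(rec$labels, collapse = "\t"), con)
  # %.17g round-trips IEEE doubles exactly through read.table
  body <- apply(rec$data, 2L, function(col)
    paste(sprintf("%.17g", col), collapse = "\t"))
  writeLines(body, con)

  meta <- list(
    fs = rec$fs,
    onset_s = rec$onset_s,
    lateralization = rec$lateralization,
    groups = as.list(rec$groups[rec$labels])
  )
  yaml::write_yaml(meta, map_path)
  invisible(c(data = data_path, map = map_path))
}
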