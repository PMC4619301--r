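#' Run the full preictal-ictal transition analysis
#'
#' Convenience driver: segments a (pre-cleaned, referenced, filtered)
#' recording into non-overlapping windows, computes the per-window measure
#' traces over the global and mesial scopes and evaluates the nine-part
#' hypothesis battery. Pipe-friendly:
#' `rec |> run_transition_analysis(method = "phase") |> tidy()`.
#'
#' @param rec an `eeg_recording` with onset and channel groups set.
#' @param method `"pearson"` or `"phase"`.
#' @param threshold link threshold.
#' @param W window length in samples.
#' @param span_s epoch length in seconds on each side of onset.
#' @param alpha one-sided significance level.
#' @param measures measures to compute, see [measure_all()].
#' @param ... passed on to [measure_all()].
#' @return An object of class `ictal_analysis`: list with `traces` (tibble),
#'   `hypotheses` (tibble), and `config`.
#' @export
run_transition_analysis <- function(rec, method = c("pearson", "phase"),
                                    threshold = 0.5, W = 1000, span_s = 120,
                                    alpha = 0.05,
                                    measures = c("DoL", "APL", "ACC", "Mod",
                                                 "SE", "excit_count"), ...) {
  method <- match.arg(method)
  ws <- segment_windows(rec, W = W)
  traces <- measure_all(ws, method = method, threshold = threshold,
                        measures = measures, ...)
  hypotheses <- evaluate_hypotheses(traces,
                                    lateralization = rec$lateralization,
                                    alpha = alpha, span_s = span_s)
  structure(
    list(traces = traces, hypotheses = hypotheses,
         config = list(method = method, threshold = threshold, W = W,
                       fs = rec$fs, span_s = span_s, alpha = alpha,
                       lateralization = rec$lateralization,
                       onset_s = rec$onset_s,
                       provenance = rec$provenance)),
    class = "ictal_analysis"
  )
}

#' @export
print.ictal_analysis <- function(x, ...) {
  cat("<ictal_analysis> method =", x$config$method,
      " threshold =", x$config$threshold, "\n")
  n_sup <- sum(x$hypotheses$decision == "supported", na.rm = TRUE)
  cat("  ", nrow(x$hypotheses), " hypothesis tests, ", n_sup,
      " supported at alpha = ", x$config$alpha, "\n", sep = "")
  print(x$hypotheses[, c("id", "stage", "measure", "p_value", "smd",
                         "decision")])
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the hypothesis battery of an analysis
#'
#' @param x an `ictal_analysis`.
#' @param ... unused.
#' @return The hypothesis tibble (one row per test).
#' @method tidy ictal_analysis
#' @export
tidy.ictal_analysis <- function(x, ...) x$hypotheses

#' One-row summary of an analysis
#'
#' @param x an `ictal_analysis`.
#' @param ... unused.
#' @return A one-row tibble: method, threshold, window count, numbers of
#'   tested/supported hypotheses and alpha.
#' @method glance ictal_analysis
#' @export
glance.ictal_analysis <- function(x, ...) {
  tibble::tibble(
    method = x$config$method,
    threshold = x$config$threshold,
    n_windows = max(x$traces$window),
    n_tested = sum(x$hypotheses$status == "tested"),
    n_supported = sum(x$hypotheses$decision == "supported", na.rm = TRUE),
    alpha = x$config$alpha
  )
}
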