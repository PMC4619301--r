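#' Extract paired pre/post-onset epochs from a measure trace
#'
#' Splits a per-window trace into the windows whose start time lies in
#' `[onset - span_s, onset)` (pre) and `[onset, onset + span_s)` (post); a
#' window starting exactly at onset belongs to the post epoch. With the
#' study's 5-s windows and the default 2-minute span each epoch holds 24
#' windows. A truncated epoch (recording starts or ends inside the span) is
#' kept but flagged with a warning; fewer than 5 windows on either side is
#' an error.
#'
#' @param trace a tibble with columns `rel_onset_s` and `value` (one
#'   measure/scope at a time), e.g. a filtered [measure_all()] output.
#' @param span_s epoch length in seconds on each side of onset.
#' @return list with numeric vectors `pre` and `post` (in window order) and
#'   the logical `complete`.
#' @export
extract_epochs <- function(trace, span_s = 120) {
  stopifnot(all(c("rel_onset_s", "value") %in% names(trace)))
  trace <- dplyr::arrange(trace, .data$rel_onset_s)
  pre <- trace$value[trace$rel_onset_s >= -span_s & trace$rel_onset_s < 0]
  post <- trace$value[trace$rel_onset_s >= 0 & trace$rel_onset_s < span_s]
  if (length(pre) < 5 || length(post) < 5) {
    stop("insufficient data: ", length(pre), " pre / ", length(post),
         " post windows (need at least 5 on each side)")
  }
  complete <- length(pre) == length(post)
  if (!complete) {
    warning("unequal epochs (", length(pre), " pre vs ", length(post),
            " post windows): recording does not cover the full span")
  }
  list(pre = pre, post = post, complete = complete)
}

#' Paired one-tailed Wilcoxon signed-rank test
#'
#' Classical conventions: missing pairs and zero differences are dropped,
#' tied absolute differences get average ranks. The p-value uses the exact
#' signed-rank null distribution when `n <= 25` and no ties are present, and
#' the normal approximation with tie correction and continuity correction
#' otherwise. If all differences are zero, `p = 1` with a warning.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param direction `"a_gt_b"` tests the alternative that `a` exceeds `b`;
#'   `"a_lt_b"` the reverse.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `p_value`, `statistic` (V, the positive-rank sum), `n`
#'   (pairs used) and `exact` flag.
#' @export
wilcoxon_one_sided <- function(a, b, direction = c("a_gt_b", "a_lt_b"),
                               exact_max = 25) {
  direction <- match.arg(direction)
  stopifnot(length(a) == length(b))
  ok <- stats::complete.cases(a, b)
  d <- a[ok] - b[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(list(p_value = 1, statistic = NA_real_, n = 0L, exact = FALSE))
  }
  if (n < 5) stop("fewer than 5 non-zero paired differences (n = ", n, ")")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  exact <- !ties && n <= exact_max
  if (exact) {
    p_greater <- 1 - psignrank(V - 1, n)   # P(V* >= V)
    p_less <- psignrank(V, n)              # P(V* <= V)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    sigma <- sqrt(sigma2)
    p_greater <- pnorm((V - 0.5 - mu) / sigma, lower.tail = FALSE)
    p_less <- pnorm((V + 0.5 - mu) / sigma)
  }
  p <- if (direction == "a_gt_b") p_greater else p_less
  list(p_value = min(max(p, 0), 1), statistic = V, n = n, exact = exact)
}

#' Standardized mean difference (SMD)
#'
#' `(mean(a) - mean(b)) / s_pooled` with the usual pooled standard deviation
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`. With `a`
#' the pre-onset (or left-side) values, a positive SMD means the measure
#' decreased after onset (or is higher on the left). Undefined (`NA`, with a
#' warning) when the pooled SD is zero.
#'
#' @param a,b numeric samples (non-empty).
#' @return scalar SMD.
#' @export
smd <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    warning("pooled standard deviation is zero; SMD undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

lag1_acf <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || sd(x) == 0) return(NA_real_)
  suppressWarnings(stats::cor(x[-length(x)], x[-1]))
}

hypothesis_table <- function() {
  tibble::tribble(
    ~id,  ~family,      ~measure, ~hyp_direction, ~description,
    "H1", "transition", "ACC",    "increase", "ACC increases during the seizure",
    "H2", "transition", "APL",    "decrease", "APL decreases during the seizure",
    "H3", "transition", "DoL",    "increase", "DoL increases during the seizure",
    "H4", "transition", "Mod",    "decrease", "Mod decreases during the seizure",
    "H5", "transition", "SE",     "decrease", "SE decreases during the seizure",
    "H6", "imbalance",  "DoL",    "ipsi_lt_contra", "DoL is lower on the ipsilateral side",
    "H7", "imbalance",  "APL",    "ipsi_gt_contra", "APL is higher on the ipsilateral side",
    "H8", "imbalance",  "ACC",    "ipsi_lt_contra", "ACC is lower on the ipsilateral side",
    "H9", "imbalance",  "SE",     "left_gt_right", "SE is higher on the left side than the right"
  )
}

scope_values <- function(traces, scope_, measure_) {
  traces |>
    dplyr::filter(.data$scope == scope_, .data$measure == measure_) |>
    dplyr::arrange(.data$window)
}

#' Evaluate the seizure-transition and mesial-imbalance hypothesis battery
#'
#' Runs the nine one-tailed paired Wilcoxon signed-rank tests on the
#' per-window traces, each with its standardized-mean-difference effect
#' size:
#' \describe{
#'   \item{H1-H5 (transition)}{global ACC / APL / DoL / Mod / SE, two-minute
#'     preictal epoch vs two-minute ictal epoch (window-wise pairs).}
#'   \item{H6-H8 (imbalance)}{mesial DoL / APL / ACC, ipsilateral vs
#'     contralateral side (window-wise pairs within the same stage),
#'     evaluated separately in the preictal and ictal stages. These need a
#'     known lateralization and are reported as skipped without one.}
#'   \item{H9}{mesial SE, left vs right regardless of lateralization, per
#'     stage.}
#' }
#' SMD follows the reporting convention "pre minus post" for transition
#' hypotheses (positive = measure decreased) and "left minus right" for
#' imbalance hypotheses (positive = higher on the left). No multiple-testing
#' correction enters the decisions (a Bonferroni-adjusted column is included
#' for information), and the lag-1 autocorrelation of each epoch is reported
#' as a serial-dependence caveat metric.
#'
#' @param traces a [measure_all()] tibble covering the global and mesial
#'   scopes.
#' @param lateralization `"left"`, `"right"` or `NA`.
#' @param alpha one-sided significance level.
#' @param span_s epoch length in seconds on each side of onset.
#' @return A tibble with one row per hypothesis (and per stage for H6-H9):
#'   `id`, `stage`, `measure`, `description`, `n`, `p_value`, `p_bonferroni`,
#'   `smd`, `acf1_a`, `acf1_b`, `status`, `decision`.
#' @export
evaluate_hypotheses <- function(traces, lateralization = NA_character_,
                                alpha = 0.05, span_s = 120) {
  stopifnot(all(c("scope", "measure", "value", "rel_onset_s") %in%
                  names(traces)))
  hyp <- hypothesis_table()
  rows <- list()

  run_test <- function(a, b, direction) {
    res <- tryCatch(wilcoxon_one_sided(a, b, direction),
                    error = function(e) NULL,
                    warning = function(w) list(p_value = 1, statistic = NA,
                                               n = 0L, exact = FALSE))
    if (is.null(res)) return(NULL)
    res
  }

  for (i in seq_len(nrow(hyp))) {
    h <- hyp[i, ]
    if (h$family == "transition") {
      tr <- scope_values(traces, "global", h$measure)
      if (nrow(tr) == 0) next
      ep <- extract_epochs(tr, span_s = span_s)
      n <- min(length(ep$pre), length(ep$post))
      a <- tail(ep$pre, n); b <- head(ep$post, n)   # window-wise pairs
      direction <- if (h$hyp_direction == "increase") "a_lt_b" else "a_gt_b"
      res <- run_test(a, b, direction)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = h$id, stage = "transition", measure = h$measure,
        description = h$description,
        n = if (is.null(res)) NA_integer_ else res$n,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        smd = smd(a, b),
        acf1_a = lag1_acf(a), acf1_b = lag1_acf(b),
        status = if (is.null(res)) "failed" else "tested"
      )
    } else {
      need_lat <- h$hyp_direction %in% c("ipsi_lt_contra", "ipsi_gt_contra")
      if (need_lat && (is.na(lateralization) ||
                       !lateralization %in% c("left", "right"))) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = h$id, stage = c("preictal", "ictal"), measure = h$measure,
          description = h$description, n = NA_integer_, p_value = NA_real_,
          smd = NA_real_, acf1_a = NA_real_, acf1_b = NA_real_,
          status = "skipped_no_lateralization"
        )
        next
      }
      left <- scope_values(traces, "mesial_left", h$measure)
      right <- scope_values(traces, "mesial_right", h$measure)
      if (nrow(left) == 0 || nrow(right) == 0) next
      for (stage in c("preictal", "ictal")) {
        sel <- if (stage == "preictal") {
          function(t) t$rel_onset_s >= -span_s & t$rel_onset_s < 0
        } else {
          function(t) t$rel_onset_s >= 0 & t$rel_onset_s < span_s
        }
        lv <- left$value[sel(left)]
        rv <- right$value[sel(right)]
        if (h$hyp_direction == "left_gt_right") {
          a <- lv; b <- rv; direction <- "a_gt_b"
        } else {
          ipsi <- if (lateralization == "left") lv else rv
          contra <- if (lateralization == "left") rv else lv
          a <- ipsi; b <- contra
          direction <- if (h$hyp_direction == "ipsi_lt_contra") "a_lt_b"
            else "a_gt_b"
        }
        res <- run_test(a, b, direction)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = h$id, stage = stage, measure = h$measure,
          description = h$description,
          n = if (is.null(res)) NA_integer_ else res$n,
          p_value = if (is.null(res)) NA_real_ else res$p_value,
          smd = smd(lv, rv),   # reporting convention: left minus right
          acf1_a = lag1_acf(a), acf1_b = lag1_acf(b),
          status = if (is.null(res)) "failed" else "tested"
        )
      }
    }
  }

  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- p.adjust(out$p_value, method = "bonferroni")
  out$decision <- ifelse(out$status == "tested" & !is.na(out$p_value) &
                           out$p_value < alpha,
                         "supported", "not_supported")
  out$decision[out$status != "tested"] <- NA_character_
  out <- dplyr::select(out, "id", "stage", "measure", "description", "n",
                       "p_value", "p_bonferroni", "smd", "acf1_a", "acf1_b",
                       "status", "decision")
  attr(out, "alpha") <- alpha
  out
}

#' Link-threshold robustness scan
#'
#' Re-runs graph construction over a grid of link thresholds and reports,
#' for each threshold, the pre-vs-post SMD of the global density of links
#' (positive SMD = DoL decreased after onset) together with the one-sided
#' Wilcoxon p-value for an ictal DoL increase. Connectivity matrices are
#' estimated once per window and re-thresholded, so the scan costs little
#' more than a single run. Where both epochs are constant (e.g. the graph is
#' always complete) the SMD is undefined and flagged.
#'
#' @param ws a `window_series`.
#' @param method `"pearson"` or `"phase"`.
#' @param thresholds threshold grid in \[0, 1).
#' @param span_s epoch length in seconds.
#' @param edge_trim edge trim for [phase_matrix()].
#' @return A tibble with `threshold`, `smd`, `p_value`, `n_pre`, `n_post`
#'   and `defined`.
#' @export
threshold_scan <- function(ws, method = c("pearson", "phase"),
                           thresholds = seq(0.1, 0.8, by = 0.1),
                           span_s = 120, edge_trim = 0.1) {
  stopifnot(inherits(ws, "window_series"))
  method <- match.arg(method)
  stopifnot(all(thresholds >= 0 & thresholds < 1))
  nodes <- scope_channels(ws, "global")
  mats <- lapply(seq_len(ws$n_windows), function(k) {
    win <- window_data(ws, k, channels = nodes)
    if (method == "pearson") pearson_matrix(win)
    else phase_matrix(win, edge_trim = edge_trim)
  })
  purrr::map_dfr(thresholds, function(thr) {
    dol <- vapply(mats, function(M)
      graph_density(threshold_graph(M, threshold = thr)), numeric(1))
    trace <- tibble::tibble(window = seq_along(dol),
                            rel_onset_s = ws$rel_onset_s, value = dol)
    ep <- extract_epochs(trace, span_s = span_s)
    s <- suppressWarnings(smd(ep$pre, ep$post))
    p <- tryCatch(
      suppressWarnings(
        wilcoxon_one_sided(ep$pre, ep$post, "a_lt_b")$p_value),
      error = function(e) NA_real_)
    tibble::tibble(threshold = thr, smd = s, p_value = p,
                   n_pre = length(ep$pre), n_post = length(ep$post),
                   defined = is.finite(s))
  })
}
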