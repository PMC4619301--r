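conn_matrix <- function(M, method, flagged = character()) {
  structure(M, method = method, flagged = flagged, class = "conn_matrix")
}

#' Absolute zero-lag Pearson connectivity matrix
#'
#' The coupling between two channels within a window is the absolute value
#' of their Pearson correlation coefficient at zero lag, giving a symmetric
#' matrix in \[0, 1\] with unit diagonal. A channel that is constant within
#' the window has no defined correlation: its row and column are set to `NA`
#' (it is later excluded from graph construction) and a warning is issued.
#'
#' @param window numeric matrix, channels x W, with channel rownames.
#' @return A `conn_matrix` (symmetric, values in \[0, 1\], diagonal 1) with a
#'   `method` attribute `"pearson"` and the flagged channels in attribute
#'   `"flagged"`.
#' @export
pearson_matrix <- function(window) {
  stopifnot(is.matrix(window), ncol(window) >= 2)
  sds <- apply(window, 1L, sd)
  flagged <- rownames(window)[sds == 0]
  M <- abs(suppressWarnings(cor(t(window))))
  if (length(flagged)) {
    warning("constant channel(s) in window, coupling flagged NA: ",
            paste(flagged, collapse = ", "))
    M[flagged, ] <- NA_real_
    M[, flagged] <- NA_real_
  }
  diag(M) <- 1
  conn_matrix(M, "pearson", flagged)
}

analytic_phase <- function(x) {
  # instantaneous phase via the analytic signal (frequency-domain Hilbert)
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Arg(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Mean phase coherence connectivity matrix
#'
#' Instantaneous phases are extracted per channel from the analytic signal
#' (Hilbert transform); the coupling between channels i and j is the mean
#' phase coherence `R = |mean(exp(1i * (phi_i - phi_j)))|`, bounded in
#' \[0, 1\] with 1 for perfect phase locking at any constant offset. Because
#' the analytic signal is distorted near the window boundaries, a fraction
#' of samples is trimmed from each end before averaging.
#'
#' @param window numeric matrix, channels x W, with channel rownames.
#' @param edge_trim fraction of samples discarded at each window edge.
#' @return A `conn_matrix` with `method = "phase"`; constant channels are
#'   flagged `NA` as in [pearson_matrix()].
#' @export
phase_matrix <- function(window, edge_trim = 0.1) {
  stopifnot(is.matrix(window), ncol(window) >= 2,
            edge_trim >= 0, edge_trim < 0.5)
  W <- ncol(window)
  sds <- apply(window, 1L, sd)
  flagged <- rownames(window)[sds == 0]
  drop_n <- floor(edge_trim * W)
  keep <- (drop_n + 1L):(W - drop_n)
  phi <- t(apply(window, 1L, analytic_phase))[, keep, drop = FALSE]
  E <- exp(1i * phi)
  M <- Mod(E %*% Conj(t(E))) / length(keep)
  M <- (M + t(M)) / 2
  M <- pmin(M, 1)
  dimnames(M) <- list(rownames(window), rownames(window))
  if (length(flagged)) {
    warning("constant channel(s) in window, coupling flagged NA: ",
            paste(flagged, collapse = ", "))
    M[flagged, ] <- NA_real_
    M[, flagged] <- NA_real_
  }
  diag(M) <- 1
  conn_matrix(M, "phase", flagged)
}

#' Threshold a connectivity matrix into a functional graph
#'
#' Keeps an undirected edge between two channels iff their coupling strictly
#' exceeds the threshold (ties at the threshold are dropped, so an edge-count
#' scan over thresholds is monotone). Surviving edges carry the coupling
#' value as weight; channels flagged `NA` in the matrix are excluded from
#' the node set with a warning. An empty graph is valid.
#'
#' @param M a `conn_matrix` (or plain symmetric matrix with dimnames).
#' @param threshold link threshold in \[0, 1).
#' @param nodes optional channel subset to restrict the graph to.
#' @return An `igraph` undirected weighted graph with graph attributes
#'   `threshold` and `method`.
#' @export
threshold_graph <- function(M, threshold = 0.5, nodes = NULL) {
  stopifnot(threshold >= 0, threshold < 1)
  method <- attr(M, "method") %||% "unknown"
  A <- unclass(M)
  attr(A, "method") <- NULL; attr(A, "flagged") <- NULL
  if (!is.null(nodes)) A <- A[nodes, nodes, drop = FALSE]
  # flagged channels have whole rows/columns of missing couplings
  off_na <- apply(A, 1L, function(r) sum(is.na(r)))
  bad <- rownames(A)[off_na >= ncol(A) - 1L & ncol(A) > 1L]
  if (length(bad)) {
    warning("excluding flagged channel(s) from graph: ",
            paste(bad, collapse = ", "))
    keep <- setdiff(rownames(A), bad)
    A <- A[keep, keep, drop = FALSE]
  }
  W <- A * (A > threshold)
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  igraph::set_graph_attr(g, "method", method)
}
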