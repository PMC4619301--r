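# Independent brute-force oracles and small fixture builders shared by the
# suite. Everything here is deliberately naive (enumeration, direct formulas)
# and independent of the package's implementation paths.

# --- random weighted graph as an adjacency matrix --------------------------
random_adjacency <- function(n, p = 0.4, weighted = TRUE) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) {
        w <- if (weighted) stats::runif(1, 0.1, 1) else 1
        A[i, j] <- w
        A[j, i] <- w
      }
    }
  }
  dimnames(A) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  A
}

graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# --- brute-force graph measures --------------------------------------------
oracle_density <- function(A) {
  n <- nrow(A)
  sum(A[upper.tri(A)] > 0) / (n * (n - 1) / 2)
}

oracle_apl <- function(A) {
  # Floyd-Warshall on hop counts, mean over reachable unordered pairs
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  off <- d[upper.tri(d)]
  off <- off[is.finite(off)]
  if (length(off) == 0) NA_real_ else mean(off)
}

oracle_barrat <- function(A, i) {
  # direct triple enumeration of c_i; the defining sum runs over ordered
  # neighbour pairs (j,h), i.e. each triangle contributes (w_ij + w_ih)
  nb <- which(A[i, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  s <- sum(A[i, nb])
  acc <- 0
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      j <- nb[a]; h <- nb[b]
      if (A[j, h] > 0) acc <- acc + (A[i, j] + A[i, h])
    }
  }
  acc / (s * (k - 1))
}

oracle_modularity <- function(A, membership) {
  # Q = sum_c (e_cc - a_c^2) over fractions of edges / edge endpoints
  edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  m <- nrow(edges)
  if (m == 0) return(NA_real_)
  coms <- unique(membership)
  Q <- 0
  for (cc in coms) {
    inside <- sum(membership[edges[, 1]] == cc & membership[edges[, 2]] == cc)
    ends <- sum(membership[edges[, 1]] == cc) +
      sum(membership[edges[, 2]] == cc)
    Q <- Q + inside / m - (ends / (2 * m))^2
  }
  Q
}

# --- exhaustive signed-rank test -------------------------------------------
oracle_wilcoxon <- function(a, b, direction = "a_gt_b") {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  # all 2^n sign assignments of the ranked magnitudes
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- as.vector(signs %*% r)
  if (direction == "a_gt_b") mean(V_all >= V_obs) else mean(V_all <= V_obs)
}

# --- tiny window-series builder --------------------------------------------
# Wraps a channels x samples matrix as a window_series via a recording with
# trivially valid metadata.
make_ws <- function(data, fs = 200, W = 1000, onset_s = NULL,
                    groups = NULL, lateralization = NA_character_) {
  if (is.null(rownames(data))) {
    rownames(data) <- paste0("ch", seq_len(nrow(data)))
  }
  if (is.null(groups)) {
    groups <- stats::setNames(
      rep(ictalnet::channel_groups, length.out = nrow(data)),
      rownames(data))
  }
  if (is.null(onset_s)) onset_s <- ncol(data) / fs / 2
  rec <- new_recording(data, fs = fs, groups = groups, onset_s = onset_s,
                       lateralization = lateralization)
  segment_windows(rec, W = W)
}

# default synthetic fixtures at the study conditions
ictal_fixture <- function(seed) generate_recording(synth_config(seed = seed))
null_fixture <- function(seed) {
  generate_recording(synth_config(seed = seed, ictal_gain = 1,
                                  ictal_amp = 0, ipsi_deficit = 1))
}
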