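#' Density of links (DoL)
#'
#' Ratio of the number of edges present to the number of possible edges
#' `n(n-1)/2`.
#'
#' @param g an `igraph` graph (from [threshold_graph()]).
#' @return scalar in \[0, 1\].
#' @export
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("density is undefined on fewer than 2 nodes")
  igraph::ecount(g) / (n * (n - 1) / 2)
}

#' Average path length (APL)
#'
#' Mean number of steps along unweighted shortest paths, over all reachable
#' node pairs; unreachable pairs are excluded and their fraction is attached
#' as attribute `"unreachable_frac"`. On an edgeless graph the measure is
#' undefined and `NA` is returned. With `mode = "largest_component"` the mean
#' is taken within the largest connected component instead.
#'
#' @param g an `igraph` graph.
#' @param mode `"reachable"` (default) or `"largest_component"`.
#' @return scalar `>= 1` (or `NA`), with attribute `unreachable_frac`.
#' @export
average_path_length <- function(g, mode = c("reachable", "largest_component")) {
  mode <- match.arg(mode)
  n <- igraph::vcount(g)
  if (n < 2) stop("average path length is undefined on fewer than 2 nodes")
  d <- igraph::distances(g, weights = NA)
  off <- d[upper.tri(d)]
  unreach <- mean(is.infinite(off))
  if (mode == "largest_component") {
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    if (length(keep) < 2) return(structure(NA_real_, unreachable_frac = unreach))
    dk <- d[keep, keep]
    off <- dk[upper.tri(dk)]
    off <- off[is.finite(off)]
  } else {
    off <- off[is.finite(off)]
  }
  val <- if (length(off) == 0) NA_real_ else mean(off)
  structure(val, unreachable_frac = unreach)
}

#' Barrat weighted clustering coefficient
#'
#' Per-node weighted clustering
#' `c_i = 1 / (s_i (k_i - 1)) * sum_{j,h} (w_ij + w_ih)/2 * a_ij a_ih a_jh`,
#' where `k_i` is the degree, `s_i` the strength and the sum runs over
#' unordered neighbour pairs that close a triangle. Nodes with fewer than
#' two neighbours get `c_i = 0`. With all weights equal this reduces to the
#' unweighted local clustering coefficient.
#'
#' @param g an `igraph` weighted graph.
#' @param nodes optional node names; defaults to all nodes.
#' @return named numeric vector of `c_i` in \[0, 1\].
#' @export
weighted_clustering <- function(g, nodes = NULL) {
  if (is.null(nodes)) nodes <- igraph::V(g)$name
  if (igraph::ecount(g) == 0) {
    return(stats::setNames(rep(0, length(nodes)), nodes))
  }
  ci <- igraph::transitivity(g, type = "barrat",
                             vids = nodes,
                             weights = igraph::E(g)$weight,
                             isolates = "zero")
  stats::setNames(ci, nodes)
}

#' Average weighted clustering coefficient (ACC)
#'
#' Mean of the Barrat per-node weighted clustering over all nodes; isolated
#' and degree-1 nodes contribute 0.
#'
#' @param g an `igraph` weighted graph.
#' @return scalar in \[0, 1\].
#' @export
average_clustering <- function(g) {
  if (igraph::vcount(g) < 1) stop("ACC is undefined on an empty node set")
  mean(weighted_clustering(g))
}

#' Anatomical four-community partition
#'
#' Builds the "natural" partition of the channel set into its four regional
#' subnetworks (left/right scalp, left/right mesial), used as the reference
#' community structure for [modularity_score()].
#'
#' @param groups named character vector channel -> group.
#' @param nodes node names, in graph order.
#' @return integer membership vector named by node.
#' @export
anatomical_partition <- function(groups, nodes) {
  grp <- groups[nodes]
  if (anyNA(grp)) {
    stop("node(s) without a group: ", paste(nodes[is.na(grp)], collapse = ", "))
  }
  stats::setNames(match(grp, channel_groups), nodes)
}

#' Modularity of a partition on the thresholded graph
#'
#' Newman-Girvan modularity `Q = sum_c (e_cc - a_c^2)` of the given
#' partition on the binary (unweighted) thresholded graph, where `e_cc` is
#' the fraction of edges inside community c and `a_c` the fraction of edge
#' endpoints in c. The headline per-window trace uses the fixed anatomical
#' four-community partition, so Q drops whenever inter-regional links
#' appear. Undefined (`NA`, with a warning) on an edgeless graph.
#'
#' @param g an `igraph` graph.
#' @param partition membership vector named by node (e.g. from
#'   [anatomical_partition()]), covering every node of `g`.
#' @param weighted if `TRUE`, use edge weights in Q (off by default: the
#'   companion measures DoL/APL are binary too).
#' @return scalar Q.
#' @export
modularity_score <- function(g, partition, weighted = FALSE) {
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(partition))) {
    stop("partition does not cover all graph nodes")
  }
  if (igraph::ecount(g) == 0) {
    warning("modularity is undefined on an edgeless graph")
    return(NA_real_)
  }
  memb <- as.integer(factor(partition[nodes]))
  w <- if (weighted) igraph::E(g)$weight else NULL
  igraph::modularity(g, membership = memb, weights = w)
}

#' Detect communities by greedy modularity maximization
#'
#' Runs fast-greedy modularity maximization on the binary thresholded graph
#' and, when a reference partition is supplied, reports the normalized
#' mutual information (NMI) between the detected and reference partitions.
#' An edgeless graph yields the trivial singleton partition, flagged.
#'
#' @param g an `igraph` graph.
#' @param reference optional membership vector named by node.
#' @return list with `membership` (named integer vector), `n_communities`,
#'   `Q` (modularity of the detected partition), `nmi` (or `NA`), and
#'   `degenerate` flag.
#' @export
detect_communities <- function(g, reference = NULL) {
  nodes <- igraph::V(g)$name
  if (igraph::ecount(g) == 0) {
    warning("edgeless graph: returning singleton partition")
    memb <- stats::setNames(seq_along(nodes), nodes)
    return(list(membership = memb, n_communities = length(nodes),
                Q = NA_real_, nmi = NA_real_, degenerate = TRUE))
  }
  cl <- igraph::cluster_fast_greedy(igraph::simplify(g), weights = NULL)
  memb <- stats::setNames(igraph::membership(cl), nodes)
  nmi <- NA_real_
  if (!is.null(reference)) {
    ref <- as.integer(factor(reference[nodes]))
    nmi <- igraph::compare(as.integer(memb), ref, method = "nmi")
  }
  list(membership = memb, n_communities = length(unique(memb)),
       Q = igraph::modularity(g, membership = memb, weights = NULL),
       nmi = nmi, degenerate = FALSE)
}

#' Per-window measure traces over scopes
#'
#' Drives the sliding-window analysis: for every window it estimates the
#' connectivity matrix once (Pearson or mean phase coherence), thresholds it
#' within each scope (global = all mapped channels; mesial_left /
#' mesial_right = the 6 FOE contacts per side) and computes the requested
#' graph measures, alongside the voltage-dependent measures (mean spectral
#' entropy per scope, suprathreshold excitability count). Modularity is
#' computed for the global scope only, against the anatomical four-community
#' partition. Failures of individual measures propagate as `NA` values.
#'
#' @param ws a `window_series`.
#' @param method `"pearson"` or `"phase"`.
#' @param threshold link threshold.
#' @param scopes subset of `c("global", "mesial_left", "mesial_right")`.
#' @param measures subset of `c("DoL", "APL", "ACC", "Mod", "SE",
#'   "excit_count")`.
#' @param band spectral-entropy analysis band in Hz.
#' @param edge_trim edge trim fraction for [phase_matrix()].
#' @param baseline_windows excitability baseline length in windows.
#' @return A tibble (one row per window x scope x measure) with columns
#'   `window`, `t0_s`, `rel_onset_s`, `scope`, `measure`, `value`, `method`,
#'   `threshold`.
#' @export
measure_all <- function(ws, method = c("pearson", "phase"), threshold = 0.5,
                        scopes = c("global", "mesial_left", "mesial_right"),
                        measures = c("DoL", "APL", "ACC", "Mod", "SE",
                                     "excit_count"),
                        band = c(0.5, 60), edge_trim = 0.1,
                        baseline_windows = 12) {
  stopifnot(inherits(ws, "window_series"))
  method <- match.arg(method)
  measures <- match.arg(measures, several.ok = TRUE)
  scope_nodes <- lapply(stats::setNames(scopes, scopes),
                        function(s) scope_channels(ws, s))
  if (any(lengths(scope_nodes) < 2)) {
    stop("scope(s) with fewer than 2 channels: ",
         paste(scopes[lengths(scope_nodes) < 2], collapse = ", "))
  }
  graph_measures <- intersect(measures, c("DoL", "APL", "ACC", "Mod"))

  rows <- vector("list", ws$n_windows)
  for (k in seq_len(ws$n_windows)) {
    if (length(graph_measures) == 0) break
    win <- window_data(ws, k, channels = scope_nodes[["global"]] %||%
                         scope_channels(ws, "global"))
    M <- if (method == "pearson") pearson_matrix(win) else
      phase_matrix(win, edge_trim = edge_trim)
    out <- list()
    for (s in scopes) {
      g <- threshold_graph(M, threshold = threshold, nodes = scope_nodes[[s]])
      vals <- c(
        if ("DoL" %in% measures) c(DoL = graph_density(g)),
        if ("APL" %in% measures)
          c(APL = as.numeric(suppressWarnings(average_path_length(g)))),
        if ("ACC" %in% measures) c(ACC = average_clustering(g)),
        if ("Mod" %in% measures && s == "global")
          c(Mod = suppressWarnings(modularity_score(
            g, anatomical_partition(ws$groups, igraph::V(g)$name))))
      )
      if (length(vals)) {
        out[[s]] <- tibble::tibble(scope = s, measure = names(vals),
                                   value = unname(vals))
      }
    }
    rows[[k]] <- dplyr::bind_rows(out) |>
      dplyr::mutate(window = k, .before = 1)
  }
  res <- dplyr::bind_rows(rows)

  if ("SE" %in% measures) {
    se_tr <- spectral_entropy(ws, band = band)
    se_rows <- purrr::map_dfr(scopes, function(s) {
      average_se(se_tr, scope_nodes[[s]]) |>
        dplyr::transmute(window = .data$window, scope = s, measure = "SE",
                         value = .data$value)
    })
    res <- dplyr::bind_rows(res, se_rows)
  }
  if ("excit_count" %in% measures) {
    ex <- excitability(ws, baseline_windows = baseline_windows)
    ex_rows <- purrr::map_dfr(scopes, function(s) {
      count_suprathreshold(ex, channels = scope_nodes[[s]]) |>
        dplyr::transmute(window = .data$window, scope = s,
                         measure = "excit_count", value = as.numeric(.data$count))
    })
    res <- dplyr::bind_rows(res, ex_rows)
  }

  res |>
    dplyr::mutate(
      t0_s = ws$t0_s[.data$window],
      rel_onset_s = ws$rel_onset_s[.data$window],
      method = method,
      threshold = threshold
    ) |>
    dplyr::select("window", "t0_s", "rel_onset_s", "scope", "measure",
                  "value", "method", "threshold") |>
    dplyr::arrange(.data$scope, .data$measure, .data$window)
}
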