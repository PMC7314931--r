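#' Significance-threshold a window's edge correlations into a network
#'
#' Each edge's windowed correlation r is converted to
#' t = r * sqrt((L - 2) / (1 - r^2)) with df = L - 2; the edge is kept iff
#' its two-tailed p-value is at most `alpha / n_edges` (Bonferroni over the
#' per-window edge family) and r > 0. Kept edges carry weight r, all others
#' 0. Negative correlations are excluded because path-length and efficiency
#' need non-negative weights.
#'
#' @param edge_vector numeric edge vector (row-major upper triangle).
#' @param window_length window length L in TRs (>= 4).
#' @param alpha edgewise family alpha (default 0.05).
#' @param n_edges family size for the Bonferroni correction (defaults to
#'   the number of edges in the vector).
#' @return N x N symmetric weight matrix (zero diagonal) of class
#'   `window_network`.
#' @export
threshold_edges <- function(edge_vector, window_length, alpha = 0.05,
                            n_edges = length(edge_vector)) {
  if (window_length < 4) abort("window_length must be >= 4 to test edges")
  r <- as.double(edge_vector)
  r_c <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  t_stat <- r_c * sqrt((window_length - 2) / (1 - r_c^2))
  p <- 2 * pt(-abs(t_stat), df = window_length - 2)
  keep <- (p <= alpha / n_edges) & (r > 0)
  w <- ifelse(keep, r, 0)
  net <- vec_to_sym(w)
  class(net) <- c("window_network", "matrix", "array")
  net
}

# Critical |r| above which an edge survives threshold_edges.
critical_r <- function(window_length, alpha = 0.05, n_edges) {
  tc <- qt(1 - alpha / n_edges / 2, df = window_length - 2)
  tc / sqrt(window_length - 2 + tc^2)
}

#' Weighted clustering coefficient (geometric-mean triangle form)
#'
#' Weights are first normalized by the maximum weight in the network. Per
#' node i, the weighted triangle count is
#' t_i = 1/2 * sum_jh (w_ij w_ih w_jh)^(1/3) and
#' C_i = 2 t_i / (k_i (k_i - 1)) with k_i the binary degree; nodes with
#' fewer than two neighbors contribute 0. Returns the mean over all nodes.
#' An edgeless network gives 0.
#'
#' @param network N x N symmetric non-negative weight matrix.
#' @return scalar clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient_w <- function(network) {
  w <- as.matrix(unclass(network))
  diag(w) <- 0
  mx <- max(w)
  if (mx == 0) return(0)
  wn <- (w / mx)^(1 / 3)
  tri <- diag(wn %*% wn %*% wn) / 2
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  mean(ci)
}

#' All-pairs shortest path distances with edge length 1/weight
#'
#' Positive weights become lengths 1/w; unreachable pairs are +Inf and the
#' diagonal is 0. Dijkstra per source via igraph.
#'
#' @param network N x N symmetric non-negative weight matrix.
#' @return N x N distance matrix.
#' @export
shortest_distances <- function(network) {
  w <- as.matrix(unclass(network))
  diag(w) <- 0
  n <- nrow(w)
  if (all(w == 0)) {
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    return(d)
  }
  len <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered pairs i != j with finite
#' distance. The fraction of infinite (disconnected) pairs is attached as
#' attribute `inf_fraction`; if every pair is disconnected the value is NA.
#'
#' @param distances matrix from [shortest_distances()].
#' @return scalar (possibly NA) with attribute `inf_fraction`.
#' @export
characteristic_path_length <- function(distances) {
  off <- distances[row(distances) != col(distances)]
  inf_frac <- mean(!is.finite(off))
  lw <- if (all(!is.finite(off))) NA_real_ else mean(off[is.finite(off)])
  attr(lw, "inf_fraction") <- inf_frac
  lw
}

#' Global efficiency
#'
#' Mean over ordered pairs i != j of 1/d_ij, with 1/Inf = 0.
#'
#' @param distances matrix from [shortest_distances()].
#' @return scalar efficiency.
#' @export
global_efficiency <- function(distances) {
  off <- distances[row(distances) != col(distances)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced on its
#' neighbors (keeping original weights); nodes with fewer than two
#' neighbors contribute 0. Returns the mean over all nodes.
#'
#' @param network N x N symmetric non-negative weight matrix.
#' @return scalar local efficiency.
#' @export
local_efficiency <- function(network) {
  w <- as.matrix(unclass(network))
  diag(w) <- 0
  n <- nrow(w)
  el <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(shortest_distances(w[nb, nb, drop = FALSE]))
  }, 0)
  mean(el)
}

#' All four topology metrics for one window network
#'
#' @param network N x N weight matrix (as from [threshold_edges()]).
#' @return one-row tibble: `cw`, `lw`, `eglob`, `eloc`, `inf_pair_fraction`.
#' @export
network_metrics <- function(network) {
  d <- shortest_distances(network)
  lw <- characteristic_path_length(d)
  inf_frac <- attr(lw, "inf_fraction")
  tibble::tibble(
    cw = clustering_coefficient_w(network),
    lw = as.double(lw),
    eglob = global_efficiency(d),
    eloc = local_efficiency(network),
    inf_pair_fraction = inf_frac
  )
}

#' Per-window topology for one subject
#'
#' Thresholds each window's edge vector into a weighted network and
#' computes the four metrics.
#'
#' @param window_corr a `window_corr` matrix.
#' @param alpha edgewise family alpha (default 0.05, Bonferroni over E).
#' @return tibble: `subject`, `group`, `window`, `cw`, `lw`, `eglob`,
#'   `eloc`, `inf_pair_fraction`.
#' @export
window_topology <- function(window_corr, alpha = 0.05) {
  l_tr <- attr(window_corr, "length_tr")
  e <- ncol(window_corr)
  rows <- purrr::map(seq_len(nrow(window_corr)), function(w) {
    net <- threshold_edges(unclass(window_corr)[w, ], l_tr, alpha, e)
    network_metrics(net)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(subject = as.character(attr(window_corr, "subject") %||% NA),
                  group = as.character(attr(window_corr, "group") %||% NA),
                  window = dplyr::row_number(), .before = 1)
}

#' Per-subject, per-state mean topology
#'
#' Arithmetic mean of each metric over a subject's windows within each
#' state. Windows whose characteristic path length is undefined (fully
#' disconnected) are excluded from the `lw` mean; the excluded count is in
#' `n_lw_missing`.
#'
#' @param window_metrics tibble from [window_topology()] (possibly several
#'   subjects bound together).
#' @param labels integer state label per window.
#' @return tibble: `subject`, `group`, `state`, `n_windows`, `cw`, `lw`,
#'   `eglob`, `eloc`, `n_lw_missing`.
#' @export
state_topology <- function(window_metrics, labels) {
  labels <- as.integer(labels)
  window_metrics |>
    dplyr::mutate(state = labels[.data$window]) |>
    dplyr::group_by(.data$subject, .data$group, .data$state) |>
    dplyr::summarise(
      n_windows = dplyr::n(),
      n_lw_missing = sum(is.na(.data$lw)),
      cw = mean(.data$cw),
      lw = if (all(is.na(.data$lw))) NA_real_ else mean(.data$lw, na.rm = TRUE),
      eglob = mean(.data$eglob),
      eloc = mean(.data$eloc),
      .groups = "drop"
    )
}

#' Topology of state-mean networks
#'
#' Alternative aggregation: instead of averaging per-window metrics within
#' state, threshold each subject's state-mean edge vector into one network
#' per state and compute the four metrics on that network. The edgewise
#' threshold uses the same single-window degrees of freedom.
#'
#' @param state_means tibble from [state_mean_dfc()].
#' @param window_length window length L in TRs used for the edge test.
#' @param alpha edgewise family alpha (default 0.05).
#' @return tibble: `subject`, `group`, `state`, `cw`, `lw`, `eglob`,
#'   `eloc`, `inf_pair_fraction`.
#' @export
state_mean_network_topology <- function(state_means, window_length,
                                        alpha = 0.05) {
  en <- unique(state_means$edge)
  state_means |>
    dplyr::group_by(.data$subject, .data$group, .data$state) |>
    dplyr::summarise(
      metrics = list(network_metrics(threshold_edges(
        .data$mean_r[match(en, .data$edge)], window_length, alpha, length(en)
      ))),
      .groups = "drop"
    ) |>
    tidyr::unnest("metrics")
}
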