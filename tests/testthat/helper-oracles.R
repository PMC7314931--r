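# Independent brute-force oracles used to cross-check the package's
# implementations on small fixtures. These are deliberately naive loops,
# kept free of any package internals.

# Weighted clustering coefficient: explicit triple enumeration.
oracle_cw <- function(w) {
  diag(w) <- 0
  mx <- max(w)
  if (mx == 0) return(0)
  wn <- w / mx
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- sum(w[i, ] > 0)
    if (k_i < 2) next
    t_i <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          t_i <- t_i + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
        }
      }
    }
    ci[i] <- t_i / (k_i * (k_i - 1))
  }
  mean(ci)
}

# All-pairs shortest paths on lengths 1/w via Floyd-Warshall.
oracle_distances <- function(w) {
  diag(w) <- 0
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_lw <- function(d) {
  off <- d[row(d) != col(d)]
  if (all(!is.finite(off))) return(NA_real_)
  mean(off[is.finite(off)])
}

oracle_eglob <- function(d) {
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

oracle_eloc <- function(w) {
  diag(w) <- 0
  n <- nrow(w)
  el <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    el[i] <- oracle_eglob(oracle_distances(w[nb, nb, drop = FALSE]))
  }
  mean(el)
}

# Mean silhouette by direct definition (naive loops).
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    same <- setdiff(which(labels == own), i)
    if (!length(same)) { s[i] <- 0; next }
    a_i <- mean(d[i, same])
    b_i <- Inf
    for (cl in setdiff(unique(labels), own)) {
      b_i <- min(b_i, mean(d[i, labels == cl]))
    }
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# All symmetric binary topologies on n nodes (list of adjacency matrices).
all_binary_graphs <- function(n) {
  e <- n * (n - 1) / 2
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lapply(seq_len(2^e) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(e)]
    m <- matrix(0, n, n)
    m[pairs] <- bits
    m + t(m)
  })
}

# Random weighted graph: random binary topology with edge density p and
# Uniform(0.1, 1) weights.
random_weighted_graph <- function(n, p = 0.5) {
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  on <- up[runif(length(up)) < p]
  m[on] <- runif(length(on), 0.1, 1)
  m + t(m)
}

# Small synthetic dataset for fast end-to-end tests.
tiny_dataset <- function(seed = 1, n_a = 4, n_b = 4, n_timepoints = 90,
                         n_nodes = 6, n_states = 2,
                         effects = group_effects(1, 2, 1, 0.4)) {
  simulate_dataset(n_a = n_a, n_b = n_b, n_timepoints = n_timepoints,
                   n_nodes = n_nodes, n_states = n_states,
                   effects = effects, rng_seed = seed, min_state_run = 36)
}
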