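#' @importFrom rlang %||% abort warn inform
#' @importFrom stats cor sd pt qt rnorm runif rexp setNames
#' @importFrom utils head tail
NULL

#' Upper-triangle edge index pairs in row-major order
#'
#' Edges of an N-node undirected graph are stored as a vector ordered
#' row-major over the upper triangle: (1,2), (1,3), ..., (1,N), (2,3), ...
#' This ordering is fixed package-wide so that state centroids and edge
#' vectors are interpretable against a node table.
#'
#' @param n_nodes number of nodes N (>= 2).
#' @return integer matrix with columns `i`, `j` (i < j) and N(N-1)/2 rows.
#' @export
edge_pairs <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  i <- rep(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes))
  cbind(i = i, j = as.integer(j))
}

#' Edge labels "a-b" for a node-name vector
#' @param node_names character vector of node names.
#' @return character vector of length N(N-1)/2.
#' @export
edge_names <- function(node_names) {
  ep <- edge_pairs(length(node_names))
  paste(node_names[ep[, "i"]], node_names[ep[, "j"]], sep = "-")
}

# Extract the upper triangle (row-major) of a symmetric matrix as a vector.
ut_vec <- function(m) {
  ep <- edge_pairs(nrow(m))
  m[ep]
}

# Rebuild a symmetric matrix (zero diagonal) from a row-major edge vector.
vec_to_sym <- function(v, diag_value = 0) {
  e <- length(v)
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(n - round(n)) > 1e-8) {
    abort("edge vector length is not N(N-1)/2 for any integer N")
  }
  n <- as.integer(round(n))
  m <- matrix(diag_value * 0, n, n)
  ep <- edge_pairs(n)
  m[ep] <- v
  m[ep[, c(2, 1)]] <- v
  diag(m) <- diag_value
  m
}

# Number of nodes implied by an edge-vector length.
n_nodes_from_edges <- function(e) {
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(n - round(n)) > 1e-8) abort("not a valid edge count N(N-1)/2")
  as.integer(round(n))
}

#' Deterministic child seed derived from a master seed
#'
#' All randomness in the package flows from one integer master seed through
#' this counter-based scheme, so stages can be re-run independently while
#' remaining reproducible. Values stay below 2^31.
#'
#' @param master integer master seed.
#' @param stream integer stream counter (>= 0).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, stream) {
  m <- as.double(master) %% 2147483647
  s <- as.double(stream) %% 2147483647
  as.integer((m * 48271 + s * 9973 + 12345) %% 2147483647)
}

# Run code with a local RNG seeded at `seed`, restoring global RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Atomic write: write to a temp file in the same directory, then rename.
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) abort(paste0("could not write ", path))
  invisible(path)
}
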