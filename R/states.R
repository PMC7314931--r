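# Squared Euclidean distances between rows of x and rows of centers.
row_dist2 <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

#' Lloyd's k-means with restarts
#'
#' Uniform random row initialization per restart, Lloyd iterations until the
#' assignment is unchanged or the maximum centroid shift drops below 1e-6,
#' empty clusters re-seeded at the row farthest from the empty cluster's
#' previous centroid, and the best of `n_restarts` runs by within-cluster
#' sum of squares. Fully deterministic given `rng_seed`.
#'
#' @param x numeric matrix (rows = samples).
#' @param k number of clusters (<= nrow(x)).
#' @param n_restarts random restarts (default 50).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @param rng_seed integer seed.
#' @return list with `labels`, `centroids` (k x ncol(x)), `inertia`.
#' @export
kmeans_lloyd <- function(x, k, n_restarts = 50, max_iter = 300, rng_seed = 1) {
  x <- as.matrix(unclass(x))
  if (k > nrow(x)) abort("k must not exceed the number of samples")
  stopifnot(k >= 1, n_restarts >= 1)
  best <- NULL
  with_seed(rng_seed, {
    for (rs in seq_len(n_restarts)) {
      centers <- x[sample.int(nrow(x), k), , drop = FALSE]
      labels <- rep(0L, nrow(x))
      for (iter in seq_len(max_iter)) {
        d2 <- row_dist2(x, centers)
        new_labels <- max.col(-d2, ties.method = "first")
        new_centers <- centers
        for (cl in seq_len(k)) {
          members <- which(new_labels == cl)
          if (length(members)) {
            new_centers[cl, ] <- colMeans(x[members, , drop = FALSE])
          } else {
            far <- which.max(d2[, cl])
            new_centers[cl, ] <- x[far, ]
            new_labels[far] <- cl
          }
        }
        shift <- sqrt(max(rowSums((new_centers - centers)^2)))
        converged <- identical(new_labels, labels) || shift < 1e-6
        labels <- new_labels
        centers <- new_centers
        if (converged) break
      }
      inertia <- sum((x - centers[labels, , drop = FALSE])^2)
      if (is.null(best) || inertia < best$inertia) {
        best <- list(labels = labels, centroids = centers, inertia = inertia)
      }
    }
  })
  best
}

#' Mean silhouette width
#'
#' Per sample i, s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean
#' Euclidean distance to the other members of its own cluster and b(i) the
#' smallest mean distance to any other cluster; members of singleton
#' clusters contribute s = 0. Returns the mean over all samples.
#'
#' @param x numeric matrix of samples, or a precomputed distance matrix
#'   when `is_dist = TRUE`.
#' @param labels integer cluster labels.
#' @param is_dist is `x` already a full pairwise distance matrix?
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_mean <- function(x, labels, is_dist = FALSE) {
  labels <- as.integer(labels)
  cl_ids <- sort(unique(labels))
  if (length(cl_ids) < 2) abort("silhouette needs >= 2 clusters")
  d <- if (is_dist) x else as.matrix(stats::dist(as.matrix(unclass(x))))
  n <- nrow(d)
  sizes <- tabulate(labels, max(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[own] == 1) { s[i] <- 0; next }
    a_i <- sum(d[i, labels == own]) / (sizes[own] - 1)
    b_i <- min(vapply(cl_ids[cl_ids != own], function(cl) {
      mean(d[i, labels == cl])
    }, 0))
    s[i] <- if (max(a_i, b_i) > 0) (b_i - a_i) / max(a_i, b_i) else 0
  }
  mean(s)
}

#' Select the number of states from a silhouette curve
#'
#' Argmax of the mean silhouette over the candidate k values; ties go to
#' the smallest k. The full curve is always carried along so the silhouette
#' versus k pattern can be inspected.
#'
#' @param silhouettes tibble/data frame with columns `k` and `silhouette`.
#' @return the selected k (integer).
#' @export
select_k <- function(silhouettes) {
  stopifnot(all(c("k", "silhouette") %in% names(silhouettes)))
  o <- order(silhouettes$k)
  k_sorted <- silhouettes$k[o]
  sil_sorted <- silhouettes$silhouette[o]
  as.integer(k_sorted[which.max(sil_sorted)])  # which.max takes first = smallest k
}

#' Cluster sliding windows into dFC states
#'
#' Runs k-means over each candidate k, scores each solution by mean
#' silhouette (Euclidean distance on the raw correlation rows), selects k by
#' [select_k()], and renumbers the selected states by descending occupancy
#' (ties by first occurrence) so labels are stable across seeds.
#'
#' @param dynmat a `dynamic_matrix` (or plain matrix; rows = windows).
#' @param k_range candidate cluster counts (default 2:12).
#' @param n_restarts k-means restarts per k (default 50).
#' @param max_iter Lloyd cap (default 300).
#' @param rng_seed master integer seed.
#' @param transform `"none"` (default: cluster raw correlations) or
#'   `"fisher_z"` (cluster atanh-transformed rows; |r| clipped at 1 - 1e-7).
#' @return an object of class `dfc_states`: list with `k`, `labels`,
#'   `centroids`, `silhouettes` (tibble k, silhouette), `occupancy`,
#'   `inertia`, `window_starts`, `seed`.
#' @export
cluster_windows <- function(dynmat, k_range = 2:12, n_restarts = 50,
                            max_iter = 300, rng_seed = 1,
                            transform = c("none", "fisher_z")) {
  transform <- match.arg(transform)
  x <- as.matrix(unclass(dynmat))
  if (transform == "fisher_z") {
    x <- atanh(pmin(pmax(x, -1 + 1e-7), 1 - 1e-7))
  }
  dmat <- as.matrix(stats::dist(x))
  fits <- list()
  sil <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fits[[i]] <- kmeans_lloyd(x, k, n_restarts, max_iter,
                              rng_seed = child_seed(rng_seed, k))
    sil[i] <- silhouette_mean(dmat, fits[[i]]$labels, is_dist = TRUE)
  }
  sil_tbl <- tibble::tibble(k = as.integer(k_range), silhouette = sil)
  k_best <- select_k(sil_tbl)
  fit <- fits[[which(k_range == k_best)]]

  occ <- tabulate(fit$labels, k_best)
  remap <- order(-occ, seq_len(k_best))           # descending occupancy
  new_of_old <- match(seq_len(k_best), remap)
  labels <- new_of_old[fit$labels]
  centroids <- fit$centroids[remap, , drop = FALSE]

  structure(
    list(k = k_best, labels = as.integer(labels), centroids = centroids,
         silhouettes = sil_tbl, occupancy = tabulate(labels, k_best),
         inertia = fit$inertia,
         window_starts = attr(dynmat, "window_starts"),
         edge_names = attr(dynmat, "edge_names"),
         subject_order = attr(dynmat, "subject_order"),
         seed = rng_seed),
    class = "dfc_states"
  )
}

#' @export
print.dfc_states <- function(x, ...) {
  cat("<dfc_states> k = ", x$k, " states over ", length(x$labels),
      " windows (mean silhouette ",
      signif(x$silhouettes$silhouette[x$silhouettes$k == x$k], 3), ")\n",
      "occupancy: ", paste(x$occupancy, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-subject, per-state mean dynamic connectivity
#'
#' For every subject, the arithmetic mean of each edge's windowed r over the
#' windows assigned to each state. States a subject never occupies (possible
#' only with per-subject label sets) are simply absent from the output.
#'
#' @param window_corrs list of `window_corr` matrices, one per subject.
#' @param labels integer state label per window (length W).
#' @return tibble with columns `subject`, `group`, `state`, `edge`,
#'   `mean_r`.
#' @export
state_mean_dfc <- function(window_corrs, labels) {
  labels <- as.integer(labels)
  purrr::imap(window_corrs, function(wc, idx) {
    if (nrow(wc) != length(labels)) {
      abort("labels length does not match the window count")
    }
    en <- attr(wc, "edge_names")
    states <- sort(unique(labels))
    purrr::map(states, function(s) {
      rows <- which(labels == s)
      tibble::tibble(
        subject = as.character(attr(wc, "subject") %||% idx),
        group = as.character(attr(wc, "group") %||% NA),
        state = s, edge = en,
        mean_r = colMeans(unclass(wc)[rows, , drop = FALSE])
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Match clustered states to a known latent sequence
#'
#' Maps each clustered state to the latent (planted) state that is modal
#' among the true per-TR labels at its windows' start TRs. Used to evaluate
#' recovery on synthetic data.
#'
#' @param states a `dfc_states` object.
#' @param true_states per-TR latent labels.
#' @param length_tr window length used (for window-level truth, the modal
#'   latent label inside each window is used).
#' @return integer vector: for each clustered state, the matched latent
#'   state.
#' @export
match_states <- function(states, true_states, length_tr = 35) {
  starts <- states$window_starts %||% (seq_along(states$labels) - 1L)
  win_truth <- vapply(starts, function(s0) {
    seg <- true_states[(s0 + 1):min(s0 + length_tr, length(true_states))]
    as.integer(names(which.max(table(seg))))
  }, 1L)
  vapply(seq_len(states$k), function(cl) {
    seg <- win_truth[states$labels == cl]
    if (!length(seg)) return(NA_integer_)
    as.integer(names(which.max(table(seg))))
  }, 1L)
}
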