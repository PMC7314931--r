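test_that("k-means recovers well-separated clouds and is deterministic", {
  mk_clouds <- function(seed) {
    withr::with_seed(seed, {
      rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
            matrix(rnorm(40, 10, 0.5), 20, 2))
    })
  }
  truth <- rep(1:2, each = 20)
  for (seed in 1:20) {
    fit <- kmeans_lloyd(mk_clouds(seed), 2, n_restarts = 5, rng_seed = seed)
    agree <- max(mean(fit$labels == truth), mean(fit$labels == 3 - truth))
    expect_equal(agree, 1)
  }
  x <- mk_clouds(1)
  f1 <- kmeans_lloyd(x, 3, n_restarts = 8, rng_seed = 11)
  f2 <- kmeans_lloyd(x, 3, n_restarts = 8, rng_seed = 11)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$centroids, f2$centroids)
})

test_that("k-means edge cases: identical rows, k bounds, inertia quality", {
  same <- matrix(1, 10, 3)
  fit <- kmeans_lloyd(same, 4, n_restarts = 2, rng_seed = 1)
  expect_equal(fit$inertia, 0)
  x <- withr::with_seed(2, matrix(rnorm(60), 20, 3))
  expect_error(kmeans_lloyd(x, 21, rng_seed = 1), "exceed")
  # matches stats::kmeans objective quality on easy data (independent check)
  ref <- withr::with_seed(3, stats::kmeans(x, 3, nstart = 20))
  fit3 <- kmeans_lloyd(x, 3, n_restarts = 20, rng_seed = 3)
  expect_lt(fit3$inertia, ref$tot.withinss * 1.05)
})

test_that("silhouette matches the hand example and the brute-force oracle", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labels <- c(1, 1, 2, 2)
  # a = 1, b = mean(10, sqrt(101)) = 10.0249; s = (b - a)/b = 0.900246
  b <- mean(c(10, sqrt(101)))
  expect_equal(silhouette_mean(pts, labels), (b - 1) / b, tolerance = 1e-6)
  expect_equal(round(silhouette_mean(pts, labels), 4), 0.9002)

  for (seed in 1:5) {
    x <- withr::with_seed(seed, matrix(rnorm(40 * 3), 40, 3))
    lab <- withr::with_seed(seed + 50, sample(1:4, 40, replace = TRUE))
    expect_equal(silhouette_mean(x, lab), oracle_silhouette(x, lab),
                 tolerance = 1e-10)
    if (requireNamespace("cluster", quietly = TRUE)) {
      ref <- mean(cluster::silhouette(lab, dist(x))[, "sil_width"])
      expect_equal(silhouette_mean(x, lab), ref, tolerance = 1e-10)
    }
  }
})

test_that("silhouette degenerate geometry follows the definition", {
  # coincident clusters: a = b = 0 for every point -> s = 0 by convention
  x <- matrix(0, 4, 2)
  expect_equal(silhouette_mean(x, c(1, 1, 2, 2)), 0)
  # separation growing -> s -> 1
  far <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
               matrix(rnorm(20, 1000, 0.1), 10, 2))
  expect_gt(silhouette_mean(far, rep(1:2, each = 10)), 0.99)
  expect_error(silhouette_mean(x, rep(1, 4)), "2 clusters")
  # singleton clusters contribute 0
  y <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  lab <- c(1, 1, 2)
  s12 <- vapply(1:2, function(i) {
    a <- 0.1
    b <- sqrt(sum((y[i, ] - y[3, ])^2))
    (b - a) / max(a, b)
  }, 0)
  expect_equal(silhouette_mean(y, lab), mean(c(s12, 0)), tolerance = 1e-10)
})

test_that("k selection takes the argmax with ties to smaller k", {
  sil <- tibble::tibble(k = 2:12, silhouette = seq(0.9, by = -0.05, length.out = 11))
  expect_equal(select_k(sil), 2L)
  flat <- tibble::tibble(k = 2:12, silhouette = rep(0.4, 11))
  expect_equal(select_k(flat), 2L)
  bump <- tibble::tibble(k = 2:12, silhouette = c(0.2, 0.3, 0.6, 0.6, 0.5,
                                                  0.4, 0.3, 0.2, 0.2, 0.2, 0.2))
  expect_equal(select_k(bump), 4L)
})

test_that("state renumbering is by descending occupancy", {
  x <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(30, 8, 0.1), 15, 2))
  st <- cluster_windows(x, k_range = 2:3, n_restarts = 10, rng_seed = 4)
  expect_equal(st$occupancy, sort(st$occupancy, decreasing = TRUE))
  expect_equal(sum(st$occupancy), 20)
  expect_true(all(st$labels %in% seq_len(st$k)))
})

test_that("per-state mean dFC averages the right windows", {
  ds <- tiny_dataset(seed = 9, n_a = 2, n_b = 2, n_timepoints = 80)
  wcs <- lapply(ds$subjects, window_correlations, length_tr = 20)
  w <- nrow(wcs[[1]])
  labels <- rep(c(1L, 2L), length.out = w)
  sm <- state_mean_dfc(wcs, labels)
  # direct check for subject 1, state 2, first edge
  expect_equal(sm$mean_r[sm$subject == "sub01" & sm$state == 2 &
                           sm$edge == attr(wcs[[1]], "edge_names")[1]],
               mean(unclass(wcs[[1]])[labels == 2, 1]))
  # all windows in one state: mean over everything
  sm1 <- state_mean_dfc(wcs[1], rep(1L, w))
  expect_equal(sm1$mean_r, colMeans(unclass(wcs[[1]])), ignore_attr = TRUE)
  # groups carried through
  expect_setequal(unique(sm$group), c("A", "B"))
})

test_that("planted state means are recovered within tolerance", {
  ds <- simulate_dataset(n_a = 5, n_b = 5, rng_seed = 17,
                         effects = group_effects(1, 2, 1, 0))
  wcs <- lapply(ds$subjects, window_correlations)
  dm <- build_dynamic_matrix(wcs)
  st <- cluster_windows(dm, k_range = 2:6, n_restarts = 20, rng_seed = 18)
  expect_equal(st$k, 4)
  mp <- match_states(st, ds$true_states)
  sm <- state_mean_dfc(wcs, st$labels)
  atten <- 1 / (1 + 0.5^2)
  ep <- edge_pairs(17)
  for (cl in seq_len(st$k)) {
    planted <- ds$model_b$correlations[[mp[cl]]][ep] * atten
    got <- sm |>
      dplyr::filter(.data$state == cl) |>
      dplyr::group_by(.data$edge) |>
      dplyr::summarise(m = mean(.data$mean_r)) |>
      dplyr::arrange(match(.data$edge, attr(wcs[[1]], "edge_names")))
    # pooled over subjects; transition-window mixing keeps this loose
    expect_lt(mean(abs(got$m - planted)), 0.08)
  }
})

test_that("state labelling matches the planted sequence", {
  ds <- simulate_dataset(rng_seed = 23)
  wcs <- lapply(ds$subjects, window_correlations)
  st <- cluster_windows(build_dynamic_matrix(wcs), k_range = 2:6,
                        n_restarts = 20, rng_seed = 24)
  expect_equal(st$k, 4)
  mp <- match_states(st, ds$true_states)
  expect_setequal(mp, 1:4)
  # windows fully inside a latent segment must carry the matched label
  runs <- rle(ds$true_states)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  correct <- 0; total <- 0
  for (seg in seq_along(runs$values)) {
    pure <- which(st$window_starts + 1 >= starts[seg] &
                    st$window_starts + 35 <= ends[seg])
    total <- total + length(pure)
    correct <- correct + sum(mp[st$labels[pure]] == runs$values[seg])
  }
  expect_gt(correct / total, 0.9)
})

test_that("fisher-z transformed clustering is available and consistent", {
  ds <- tiny_dataset(seed = 61, n_a = 3, n_b = 3, n_timepoints = 80,
                     n_nodes = 5, n_states = 2)
  wcs <- lapply(ds$subjects, window_correlations, length_tr = 20)
  dm <- build_dynamic_matrix(wcs)
  st_r <- cluster_windows(dm, k_range = 2:3, n_restarts = 10, rng_seed = 3)
  st_z <- cluster_windows(dm, k_range = 2:3, n_restarts = 10, rng_seed = 3,
                          transform = "fisher_z")
  expect_true(all(is.finite(st_z$centroids)))
  # the monotone transform preserves the planted two-cluster split here
  expect_equal(st_z$k, st_r$k)
  agree <- max(mean(st_z$labels == st_r$labels),
               mean(st_z$labels != st_r$labels))
  expect_gt(agree, 0.9)
})
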