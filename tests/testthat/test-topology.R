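unit_path3 <- vec_to_sym(c(1, 0, 1))         # a-b-c unit chain
unit_triangle <- vec_to_sym(c(1, 1, 1))

test_that("edge thresholding keeps exactly the significant positive edges", {
  l_tr <- 35
  e <- 136
  rc <- dynfc:::critical_r(l_tr, 0.05, e)
  v <- rep(0, e)
  v[1] <- rc + 1e-4        # just above critical
  v[2] <- rc - 1e-4        # just below
  v[3] <- -0.9             # strongly negative: excluded
  net <- threshold_edges(v, l_tr, 0.05, e)
  expect_equal(net[1, 2], rc + 1e-4)   # edge 1 = (1,2)
  expect_equal(net[1, 3], 0)
  expect_equal(net[1, 4], 0)
  expect_equal(sum(net != 0), 2)       # one edge, symmetric
  expect_equal(net, t(net))
  expect_equal(diag(net), rep(0, 17))
  # r = 0 edges are always removed; saturated r = 1 survives
  all1 <- threshold_edges(rep(1, 3), 10, 0.05, 3)
  expect_true(all(all1[upper.tri(all1)] == 1))
})

test_that("metric hand values on canonical small graphs", {
  expect_equal(clustering_coefficient_w(unit_triangle), 1)
  expect_equal(clustering_coefficient_w(unit_path3), 0)
  d3 <- shortest_distances(unit_path3)
  expect_equal(d3[1, 3], 2)
  expect_equal(as.double(characteristic_path_length(d3)), 4 / 3)
  expect_equal(global_efficiency(d3), 5 / 6)
  expect_equal(local_efficiency(unit_path3), 0)
  expect_equal(local_efficiency(unit_triangle), 1)
  dtri <- shortest_distances(unit_triangle)
  expect_equal(as.double(characteristic_path_length(dtri)), 1)
  expect_equal(global_efficiency(dtri), 1)
  # a 0.5-weight edge has length 2
  half <- vec_to_sym(c(0.5, 0, 0))
  expect_equal(shortest_distances(half)[1, 2], 2)
})

test_that("disconnected graphs follow the finite-pair conventions", {
  two_edges <- vec_to_sym(c(1, 0, 0, 0, 0, 1))   # 4 nodes: 1-2, 3-4
  d <- shortest_distances(two_edges)
  lw <- characteristic_path_length(d)
  expect_equal(as.double(lw), 1)                 # 4 finite ordered pairs, all 1
  expect_equal(attr(lw, "inf_fraction"), 2 / 3)
  empty <- matrix(0, 4, 4)
  expect_equal(global_efficiency(shortest_distances(empty)), 0)
  expect_equal(clustering_coefficient_w(empty), 0)
  expect_true(is.na(characteristic_path_length(shortest_distances(empty))))
})

test_that("all four metrics equal brute-force oracles on random graphs", {
  withr::with_seed(77, {
    for (rep in 1:60) {
      n <- sample(6:7, 1)
      w <- random_weighted_graph(n, p = runif(1, 0.2, 0.9))
      expect_equal(clustering_coefficient_w(w), oracle_cw(w), tolerance = 1e-12)
      d <- shortest_distances(w)
      od <- oracle_distances(w)
      expect_equal(d, od, tolerance = 1e-12)
      expect_equal(as.double(characteristic_path_length(d)), oracle_lw(od),
                   tolerance = 1e-12)
      expect_equal(global_efficiency(d), oracle_eglob(od), tolerance = 1e-12)
      expect_equal(local_efficiency(w), oracle_eloc(w), tolerance = 1e-12)
    }
  })
})

test_that("metric invariants hold on random fixtures", {
  withr::with_seed(123, {
    for (rep in 1:20) {
      w <- random_weighted_graph(6, 0.6)
      d <- shortest_distances(w)
      lw <- characteristic_path_length(d)
      eg <- global_efficiency(d)
      # mean of inverses >= inverse of mean over the same finite pairs
      off <- d[row(d) != col(d)]
      fin <- off[is.finite(off)]
      if (length(fin)) {
        expect_gte(mean(1 / fin) + 1e-12, 1 / mean(fin))
      }
      # scaling weights by c > 0: cw invariant, eglob scales by c
      c_scale <- runif(1, 0.2, 3)
      expect_equal(clustering_coefficient_w(c_scale * w),
                   clustering_coefficient_w(w), tolerance = 1e-10)
      expect_equal(global_efficiency(shortest_distances(c_scale * w)),
                   c_scale * eg, tolerance = 1e-10)
      # adding an edge never decreases eglob nor increases a distance
      zero_edges <- which(w == 0 & upper.tri(w), arr.ind = TRUE)
      if (nrow(zero_edges)) {
        w2 <- w
        pick <- zero_edges[1, ]
        w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- 0.5
        d2 <- shortest_distances(w2)
        expect_true(all(d2 <= d + 1e-12))
        expect_gte(global_efficiency(d2) + 1e-12, eg)
      }
    }
  })
})

test_that("per-window and per-state topology aggregate correctly", {
  ds <- tiny_dataset(seed = 12, n_a = 2, n_b = 2, n_timepoints = 80)
  wcs <- lapply(ds$subjects, window_correlations, length_tr = 20)
  wm <- dplyr::bind_rows(lapply(wcs, window_topology, alpha = 0.05))
  expect_setequal(names(wm), c("subject", "group", "window", "cw", "lw",
                               "eglob", "eloc", "inf_pair_fraction"))
  w <- nrow(wcs[[1]])
  labels <- rep(1L, w)
  st <- state_topology(wm, labels)
  one_sub <- wm[wm$subject == "sub01", ]
  expect_equal(st$cw[st$subject == "sub01"], mean(one_sub$cw))
  expect_equal(st$eglob[st$subject == "sub01"], mean(one_sub$eglob))
  # identical windows -> state mean equals the window value
  wc1 <- wcs[[1]]
  net <- threshold_edges(unclass(wc1)[1, ], 20, 0.05, ncol(wc1))
  m1 <- network_metrics(net)
  rep_metrics <- dplyr::bind_rows(m1, m1, m1) |>
    dplyr::mutate(subject = "s", group = "A", window = 1:3, .before = 1)
  stm <- state_topology(rep_metrics, c(1L, 1L, 1L))
  expect_equal(stm$cw, m1$cw)
  expect_equal(stm$lw, m1$lw)
})

test_that("denser connectivity states show higher global efficiency", {
  # two states, one strongly and one weakly coupled; the denser state's
  # thresholded networks should be more efficient on average
  strong <- make_state_correlations(8, 1, base_strength = 0.85, rng_seed = 5)
  weak <- make_state_correlations(8, 1, base_strength = 0.2, rng_seed = 6)
  model <- state_model(list(strong$correlations[[1]], weak$correlations[[1]]),
                       matrix(0.5, 2, 2), 40)
  hits <- 0
  for (seed in 1:10) {
    states <- rep(c(1L, 2L), each = 60)
    sub <- simulate_subject(model, states, noise_sd = 0.3, rng_seed = seed)
    wc <- window_correlations(sub, length_tr = 30, step_tr = 10)
    wm <- window_topology(wc, alpha = 0.05)
    win_states <- states[attr(wc, "window_starts") + 1]
    stt <- state_topology(dplyr::mutate(wm, subject = "s", group = "A"),
                          win_states)
    if (stt$eglob[stt$state == 1] > stt$eglob[stt$state == 2]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("state-mean network topology mirrors per-window metrics when static", {
  # constant series in time: every window identical, so metrics of the
  # state-mean network equal the per-window metrics
  m <- make_state_correlations(6, 1, base_strength = 0.7, rng_seed = 9)
  sub <- simulate_subject(m, rep(1L, 80), noise_sd = 0.2, rng_seed = 10)
  wc <- window_correlations(sub, length_tr = 20)
  labels <- rep(1L, nrow(wc))
  sm <- state_mean_dfc(list(wc), labels)
  smt <- state_mean_network_topology(sm, window_length = 20, alpha = 0.2)
  expect_setequal(names(smt), c("subject", "group", "state", "cw", "lw",
                                "eglob", "eloc", "inf_pair_fraction"))
  # cross-check one cell against a directly built network
  v <- sm$mean_r[match(attr(wc, "edge_names"), sm$edge)]
  direct <- network_metrics(threshold_edges(v, 20, 0.2, length(v)))
  expect_equal(smt$cw, direct$cw)
  expect_equal(smt$eglob, direct$eglob)
})
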