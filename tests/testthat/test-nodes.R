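grid3 <- function(shape = c(20, 20, 20), origin = c(-30, -30, -30)) {
  rbind(cbind(diag(3, 3), origin), c(0, 0, 0, 1))
}

test_that("sphere_voxels enumerates lattice points within the radius", {
  aff <- grid3()
  shape <- c(20, 20, 20)
  # 3 mm radius on a 3 mm grid centered on a voxel center: center + 6 face
  # neighbors = 7 voxels
  v7 <- sphere_voxels(c(0, 0, 0), 3, aff, shape)
  expect_equal(nrow(v7), 7)
  # tiny radius: only the center voxel
  v1 <- sphere_voxels(c(0, 0, 0), 0.1, aff, shape)
  expect_equal(nrow(v1), 1)
  # center outside the grid errors
  expect_error(sphere_voxels(c(500, 0, 0), 3, aff, shape), "outside")
  # radius 4.5 mm: center + 6 face + 12 edge neighbors = 19
  expect_equal(nrow(sphere_voxels(c(0, 0, 0), 4.5, aff, shape)), 19)
})

test_that("fisher z transform matches the closed form and inverts", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_message(z1 <- fisher_z(c(0, 1)), "clipped")
  expect_true(is.finite(z1[2]))
})

test_that("one-sample t map matches hand computation and edge cases", {
  aff <- grid3(c(2, 2, 2))
  mk <- function(vals) {
    dynfc:::new_stat_map(array(vals, c(2, 2, 2)), "z", aff)
  }
  # two subjects {1, 3}: mean 2, sd sqrt(2), t = 2 / (sqrt(2)/sqrt(2)) = 2
  tm <- onesample_t_map(list(mk(1), mk(3)))
  expect_equal(tm$values[1, 1, 1], 2)
  expect_equal(tm$df, 1)
  # identical zero maps -> t = 0
  expect_equal(max(abs(onesample_t_map(list(mk(0), mk(0), mk(0)))$values)), 0)
  # sd = 0, mean != 0 -> +Inf with sign of the mean
  expect_equal(onesample_t_map(list(mk(2), mk(2)))$values[1, 1, 1], Inf)
  expect_equal(onesample_t_map(list(mk(-2), mk(-2)))$values[1, 1, 1], -Inf)
})

test_that("FWE thresholding is Bonferroni over in-mask voxels and monotone", {
  aff <- grid3(c(4, 4, 4))
  vals <- withr::with_seed(9, array(rnorm(64, sd = 3), c(4, 4, 4)))
  tm <- dynfc:::new_stat_map(vals, "t", aff, df = 20)
  mask <- array(0.95, c(4, 4, 4))
  keep <- fwe_voxel_threshold(tm, 0.05, mask)
  expect_equal(attr(keep, "n_mask"), 64)
  p <- 2 * pt(-abs(vals), 20)
  expect_equal(as.vector(keep), as.vector(p <= 0.05 / 64))
  # monotone: smaller alpha never adds voxels
  keep_small <- fwe_voxel_threshold(tm, 0.01, mask)
  expect_true(all(which(keep_small) %in% which(keep)))
  # infinite t always kept
  tm$values[1, 1, 1] <- Inf
  expect_true(fwe_voxel_threshold(tm, 0.01, mask)[1, 1, 1])
  expect_error(fwe_voxel_threshold(tm, 0.01, array(0.1, c(4, 4, 4))), "empty")
})

test_that("cluster extraction respects size floor and connectivity", {
  aff <- grid3(c(12, 12, 12))
  shape <- c(12, 12, 12)
  bin <- array(FALSE, shape)
  bin[2:5, 2:5, 2:4] <- TRUE                 # 4*4*3 = 48-voxel blob
  tvals <- array(0, shape)
  tvals[bin] <- seq_len(sum(bin))
  tm <- dynfc:::new_stat_map(tvals, "t", aff, df = 20)
  expect_equal(nrow(extract_clusters(bin, tm, min_size = 50)), 0)
  cl <- extract_clusters(bin, tm, min_size = 48)
  expect_equal(cl$size, 48)
  # peak = voxel holding the max t
  expect_equal(tm$values[cl$voxels[[1]][which.max(tm$values[cl$voxels[[1]]])]],
               cl$peak_t)

  # two blobs touching only at a corner: 6-connectivity separates them,
  # 26-connectivity joins them
  bin2 <- array(FALSE, shape)
  bin2[2:3, 2:3, 2:3] <- TRUE
  bin2[4:5, 4:5, 4:5] <- TRUE
  tm2 <- dynfc:::new_stat_map(array(1, shape), "t", aff, df = 20)
  expect_equal(nrow(extract_clusters(bin2, tm2, 1, connectivity = 6)), 2)
  expect_equal(nrow(extract_clusters(bin2, tm2, 1, connectivity = 26)), 1)
})

test_that("cluster tables are disjoint and bounded by supra-threshold count", {
  aff <- grid3(c(10, 10, 10))
  bin <- withr::with_seed(12, array(runif(1000) < 0.2, c(10, 10, 10)))
  tm <- dynfc:::new_stat_map(withr::with_seed(13, array(rnorm(1000), c(10, 10, 10))),
                             "t", aff, df = 10)
  cl <- extract_clusters(bin, tm, min_size = 2, connectivity = 6)
  vox <- unlist(cl$voxels)
  expect_equal(anyDuplicated(vox), 0)
  expect_lte(length(vox), sum(bin))
  expect_equal(cl$size, lengths(cl$voxels))
})

test_that("phantom node identification recovers planted clusters", {
  nodes <- tibble::tibble(node = c("left_blob", "right_blob"),
                          x = c(-12, 12), y = c(6, -9), z = c(0, 9))
  ph <- simulate_volume_phantom(nodes, grid_shape = c(16, 16, 12),
                                seed_specs = list(seed_spec("seedA", c(0, 0, 0), 3)),
                                rng_seed = 5, n_timepoints = 80,
                                cluster_voxels = 60, coupling = 1.2,
                                origin_mni = c(-24, -24, -18))
  vols <- lapply(1:10, function(s) {
    p <- simulate_volume_phantom(nodes, grid_shape = c(16, 16, 12),
                                 seed_specs = list(seed_spec("seedA", c(0, 0, 0), 3)),
                                 rng_seed = 100 + s, n_timepoints = 80,
                                 cluster_voxels = 60, coupling = 1.2,
                                 origin_mni = c(-24, -24, -18))
    list(data = p$data, affine = p$affine)
  })
  res <- identify_network_nodes(vols, ph$gm_mask,
                                seeds = list(seed_spec("seedA", c(0, 0, 0), 3)),
                                alpha = 0.01, min_cluster = 50)
  expect_gte(nrow(res$node_table), 1)
  # every planted center within 6 mm of some recovered node
  for (r in seq_len(nrow(nodes))) {
    d <- sqrt((res$node_table$x - nodes$x[r])^2 +
                (res$node_table$y - nodes$y[r])^2 +
                (res$node_table$z - nodes$z[r])^2)
    expect_lte(min(d), 6)
  }
  # no negative-tail clusters in a positive-coupling phantom
  expect_equal(sum(vapply(res$negative_clusters, nrow, 0L)), 0)
})

test_that("null phantom produces no supra-threshold clusters", {
  nodes <- tibble::tibble(node = "blob", x = 0, y = 0, z = 0)
  vols <- lapply(1:5, function(s) {
    p <- simulate_volume_phantom(nodes, grid_shape = c(10, 10, 10),
                                 seed_specs = list(seed_spec("s", c(-9, 0, 0), 3)),
                                 rng_seed = 200 + s, n_timepoints = 60,
                                 cluster_voxels = 20, coupling = 0,
                                 origin_mni = c(-15, -15, -15))
    list(data = p$data, affine = p$affine)
  })
  mask <- array(0.95, c(10, 10, 10))
  z_maps <- lapply(vols, function(v) {
    fisher_z(seed_fc_map(v, seed_spec("s", c(-9, 0, 0), 3)))
  })
  tm <- onesample_t_map(z_maps)
  keep <- fwe_voxel_threshold(tm, 0.01, mask)
  # seed sphere voxels correlate with themselves; exclude them
  sphere <- attr(sphere_voxels(c(-9, 0, 0), 3, vols[[1]]$affine, c(10, 10, 10)),
                 "linear")
  keep[sphere] <- FALSE
  expect_equal(sum(keep), 0)
})

test_that("seed map correlation matches the closed-form attenuation", {
  # cluster voxel = coupling * seed + noise; seed mean itself is seed + noise
  # averaged over 7 sphere voxels: r ~= c / sqrt((c^2 + s2) * (1 + s2/7))
  nodes <- tibble::tibble(node = "blob", x = 9, y = 0, z = 0)
  coupling <- 0.8
  rs <- vapply(1:4, function(s) {
    p <- simulate_volume_phantom(nodes, grid_shape = c(12, 12, 12),
                                 seed_specs = list(seed_spec("s", c(-9, 0, 0), 3)),
                                 rng_seed = 300 + s, n_timepoints = 170,
                                 cluster_voxels = 30, coupling = coupling,
                                 noise_sd = 1, origin_mni = c(-18, -18, -18))
    rmap <- seed_fc_map(list(data = p$data, affine = p$affine),
                        seed_spec("s", c(-9, 0, 0), 3))
    mean(rmap$values[p$clusters$voxels[[1]]])
  }, 0)
  expected <- coupling / sqrt((coupling^2 + 1) * (1 + 1 / 7))
  expect_lt(abs(mean(rs) - expected), 0.1)
})

test_that("node tables merge across seeds and flag duplicate peaks", {
  cl <- tibble::tibble(cluster = 1:2, size = c(60L, 55L), peak_t = c(9, 7),
                       peak_x = c(0, 6), peak_y = c(0, 6), peak_z = c(0, 6),
                       voxels = list(1:60, 61:115))
  expect_warning(nt <- build_node_table(list(A = cl, B = cl[2, ])), "duplicate")
  expect_equal(nrow(nt), 3)
  expect_equal(sum(nt$seed == "A"), 2)
  expect_error(build_node_table(list(A = cl[0, ])), "no clusters")
})
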