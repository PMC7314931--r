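#' Seed sphere specification
#'
#' @param name seed label.
#' @param center_mni numeric length-3 MNI coordinate (mm).
#' @param radius_mm sphere radius in mm (default 3).
#' @return a list of class `seed_spec`.
#' @export
seed_spec <- function(name, center_mni, radius_mm = 3) {
  stopifnot(length(center_mni) == 3, radius_mm > 0)
  structure(list(name = name, center_mni = as.double(center_mni),
                 radius_mm = radius_mm), class = "seed_spec")
}

#' Canonical language-network seeds
#'
#' Broca's area (left pars triangularis, MNI -53, 20, 15) and Wernicke's
#' area (left supramarginal gyrus, MNI -51, -51, 30), each a 3-mm-radius
#' sphere.
#'
#' @return list of two [seed_spec] objects.
#' @export
default_seed_specs <- function() {
  list(seed_spec("Broca", c(-53, 20, 15), 3),
       seed_spec("Wernicke", c(-51, -51, 30), 3))
}

# MNI mm -> 0-based voxel indices (columns of a 3 x m matrix).
mni_to_ijk <- function(xyz, affine) {
  xyz <- matrix(xyz, ncol = 3)
  inv <- solve(affine)
  t(inv %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

# 0-based voxel indices -> MNI mm.
ijk_to_mni <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Voxels inside a sphere
#'
#' All voxels whose center lies within (inclusive) `radius_mm` of the MNI
#' center. On a 3-mm grid, a 3-mm-radius sphere centered on a voxel center
#' contains 7 voxels (the center and its 6 face neighbors).
#'
#' @param center_mni sphere center, MNI mm.
#' @param radius_mm radius in mm.
#' @param affine 4 x 4 voxel-to-MNI affine (0-based voxel indices).
#' @param grid_shape integer length-3 grid dimensions.
#' @return integer matrix of 0-based voxel indices (columns i, j, k) with a
#'   `linear` attribute giving 1-based linear indices into the grid.
#' @export
sphere_voxels <- function(center_mni, radius_mm, affine, grid_shape) {
  cen_ijk <- drop(mni_to_ijk(center_mni, affine))
  if (any(cen_ijk < -0.5) || any(cen_ijk > grid_shape - 0.5)) {
    abort(paste0("sphere center (", paste(center_mni, collapse = ", "),
                 ") maps outside the grid"))
  }
  vox_mm <- sqrt(colSums((affine[1:3, 1:3])^2))
  halo <- ceiling(radius_mm / vox_mm)
  lo <- pmax(floor(cen_ijk) - halo, 0)
  hi <- pmin(ceiling(cen_ijk) + halo, grid_shape - 1)
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  mni <- ijk_to_mni(cand, affine)
  d <- sqrt(colSums((t(mni) - as.double(center_mni))^2))
  keep <- d <= radius_mm + 1e-9
  if (!any(keep)) abort("sphere contains no voxel centers")
  vox <- cand[keep, , drop = FALSE]
  lin <- vox[, 1] + grid_shape[1] * (vox[, 2] + grid_shape[2] * vox[, 3]) + 1L
  attr(vox, "linear") <- as.integer(lin)
  vox
}

# Accept a volume_phantom or a list(data=4D array, affine=4x4).
volume_parts <- function(volume) {
  if (inherits(volume, "volume_phantom")) {
    list(data = volume$data, affine = volume$affine)
  } else if (is.list(volume) && !is.null(volume$data)) {
    list(data = volume$data, affine = volume$affine)
  } else {
    abort("volume must be a volume_phantom or list(data, affine)")
  }
}

new_stat_map <- function(values, kind, affine, df = NA_real_) {
  structure(list(values = values, kind = kind, df = df, affine = affine),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> kind '", x$kind, "', grid ",
      paste(dim(x$values), collapse = "x"),
      if (!is.na(x$df)) paste0(", df ", x$df), "\n", sep = "")
  invisible(x)
}

#' Seed-to-voxel correlation map
#'
#' Pearson correlation between the mean series over the seed sphere and
#' every voxel's series. Voxels with zero variance get r = 0 (the count is
#' reported via a message).
#'
#' @param volume a `volume_phantom` or list(data = 4D array, affine).
#' @param seed a [seed_spec].
#' @return a `stat_map` with kind `"r"`.
#' @export
seed_fc_map <- function(volume, seed) {
  vp <- volume_parts(volume)
  d <- dim(vp$data)
  if (length(d) != 4 || d[4] < 3) abort("volume must be 4D with >= 3 volumes")
  grid_shape <- d[1:3]
  vox <- sphere_voxels(seed$center_mni, seed$radius_mm, vp$affine, grid_shape)
  mat <- matrix(vp$data, prod(grid_shape), d[4])
  seed_series <- colMeans(mat[attr(vox, "linear"), , drop = FALSE])
  if (sd(seed_series) == 0) abort("seed sphere mean series has zero variance")
  vox_sd <- sqrt(rowSums((mat - rowMeans(mat))^2))
  r <- as.vector(cor(t(mat), seed_series))
  zero_var <- vox_sd == 0
  if (any(zero_var)) {
    inform(paste0(sum(zero_var), " zero-variance voxel(s) set to r = 0"))
    r[zero_var] <- 0
  }
  new_stat_map(array(r, grid_shape), "r", vp$affine)
}

#' Fisher r-to-z transform of a correlation map
#'
#' z = atanh(r) elementwise; |r| = 1 is clipped to 1 - 1e-7 first (with a
#' message) so the map stays finite.
#'
#' @param map_r a `stat_map` of kind `"r"`, or a numeric array/vector.
#' @return a `stat_map` of kind `"z"` (or numeric like the input).
#' @export
fisher_z <- function(map_r) {
  vals <- if (inherits(map_r, "stat_map")) map_r$values else map_r
  clip <- abs(vals) >= 1
  if (any(clip, na.rm = TRUE)) {
    inform(paste0(sum(clip, na.rm = TRUE), " |r| = 1 value(s) clipped before atanh"))
    vals[clip] <- sign(vals[clip]) * (1 - 1e-7)
  }
  z <- atanh(vals)
  if (inherits(map_r, "stat_map")) {
    if (map_r$kind != "r") abort("fisher_z expects a map of kind 'r'")
    new_stat_map(z, "z", map_r$affine)
  } else {
    z
  }
}

#' Group-level one-sample t map
#'
#' Per voxel, t = mean / (sd / sqrt(n)) across subjects with the sample
#' (n-1) standard deviation; df = n - 1. Voxels with sd = 0 give t = 0 when
#' the mean is 0 and +/-Inf otherwise (treated as supra-threshold
#' downstream).
#'
#' @param z_maps list of `stat_map` objects (kind `"z"`) sharing one grid.
#' @return a `stat_map` of kind `"t"`.
#' @export
onesample_t_map <- function(z_maps) {
  stopifnot(length(z_maps) >= 2)
  dims <- lapply(z_maps, function(m) dim(m$values))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    abort("z maps do not share a common grid")
  }
  n <- length(z_maps)
  stack <- vapply(z_maps, function(m) as.vector(m$values),
                  numeric(length(z_maps[[1]]$values)))
  mu <- rowMeans(stack)
  s <- apply(stack, 1, sd)
  t_vals <- ifelse(s > 0, mu / (s / sqrt(n)),
                   ifelse(mu == 0, 0, sign(mu) * Inf))
  new_stat_map(array(t_vals, dim(z_maps[[1]]$values)), "t",
               z_maps[[1]]$affine, df = n - 1)
}

#' Voxelwise family-wise-error threshold (Bonferroni)
#'
#' Keeps a voxel iff it lies in the mask (gray-matter probability above
#' `gm_prob`) and its two-tailed t p-value is at most `alpha` divided by the
#' number of in-mask voxels. Bonferroni is conservative relative to
#' random-field FWE but dependency-free; the choice is recorded in the
#' output attributes.
#'
#' @param t_map a `stat_map` of kind `"t"` with df set.
#' @param alpha family-wise alpha (default 0.01).
#' @param mask 3D array: gray-matter probability map (or logical mask).
#' @param gm_prob inclusion threshold on the probability map (default 0.9;
#'   strictly greater than).
#' @return logical 3D array with attributes `n_mask`, `alpha`, `method`,
#'   `t_critical`.
#' @export
fwe_voxel_threshold <- function(t_map, alpha = 0.01, mask, gm_prob = 0.9) {
  stopifnot(inherits(t_map, "stat_map"), t_map$kind == "t")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  in_mask <- if (is.logical(mask)) mask else mask > gm_prob
  n_mask <- sum(in_mask)
  if (n_mask == 0) abort("mask is empty at the requested probability threshold")
  p <- 2 * pt(-abs(t_map$values), df = t_map$df)  # Inf t -> p = 0, kept
  keep <- in_mask & (p <= alpha / n_mask)
  attr(keep, "n_mask") <- n_mask
  attr(keep, "alpha") <- alpha
  attr(keep, "method") <- "bonferroni"
  attr(keep, "t_critical") <- qt(1 - alpha / n_mask / 2, df = t_map$df)
  keep
}

# Neighbor offsets for 6/18/26 connectivity.
connectivity_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  deg <- rowSums(abs(offs) > 0)
  switch(as.character(connectivity),
         "6" = offs[deg == 1, , drop = FALSE],
         "18" = offs[deg <= 2, , drop = FALSE],
         "26" = offs,
         abort("connectivity must be 6, 18 or 26"))
}

# Label connected components of a logical 3D array (flood fill).
label_components <- function(binary, connectivity = 26) {
  dims <- dim(binary)
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, dims)
  lin_all <- which(binary)
  if (length(lin_all) == 0) return(labels)
  sub_all <- arrayInd(lin_all, dims)
  current <- 0L
  for (start in lin_all) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      sub <- arrayInd(v, dims)
      nb <- t(t(offs) + as.integer(sub))
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      nb_lin <- nb[, 1] + dims[1] * ((nb[, 2] - 1) + dims[2] * (nb[, 3] - 1))
      new <- nb_lin[binary[nb_lin] & labels[nb_lin] == 0L]
      if (length(new)) {
        labels[new] <- current
        queue <- c(queue, new)
      }
    }
  }
  labels
}

#' Extract supra-threshold clusters
#'
#' Connected components of a thresholded map, annotated with their size and
#' the peak (maximum-t) voxel in MNI coordinates. Peak ties are broken by
#' the smallest linear voxel index.
#'
#' @param binary_map logical 3D array of supra-threshold voxels.
#' @param t_map the `stat_map` of kind `"t"` the threshold came from.
#' @param min_size minimum voxel count to keep a cluster (default 50).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return tibble with columns `cluster`, `size`, `peak_t`, `peak_x/y/z`
#'   (MNI mm) and a `voxels` list-column of linear indices; zero rows when
#'   nothing survives.
#' @export
extract_clusters <- function(binary_map, t_map, min_size = 50,
                             connectivity = 26) {
  stopifnot(min_size >= 1)
  labels <- label_components(binary_map, connectivity)
  n_comp <- max(labels)
  if (n_comp == 0) return(empty_cluster_table())
  rows <- list()
  for (cmp in seq_len(n_comp)) {
    lin <- which(labels == cmp)
    if (length(lin) < min_size) next
    tv <- t_map$values[lin]
    best <- lin[order(-tv, lin)[1]]
    peak <- ijk_to_mni(arrayInd(best, dim(binary_map)) - 1L, t_map$affine)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cluster = length(rows) + 1L, size = length(lin),
      peak_t = t_map$values[best],
      peak_x = peak[1], peak_y = peak[2], peak_z = peak[3],
      voxels = list(lin)
    )
  }
  if (!length(rows)) return(empty_cluster_table())
  dplyr::bind_rows(rows)
}

empty_cluster_table <- function() {
  tibble::tibble(cluster = integer(), size = integer(), peak_t = double(),
                 peak_x = double(), peak_y = double(), peak_z = double(),
                 voxels = list())
}

#' Build a node table from clusters found per seed
#'
#' One node per cluster, centered at the cluster's peak voxel, 3-mm radius,
#' labeled by the seed the cluster was found from. Duplicate peak
#' coordinates across seeds are kept with suffixed names and a warning.
#'
#' @param clusters_by_seed named list: seed name -> cluster tibble from
#'   [extract_clusters()].
#' @param radius_mm node sphere radius (default 3).
#' @return tibble with columns `node`, `seed`, `x`, `y`, `z`, `radius_mm`,
#'   `peak_t`, `cluster_size`.
#' @export
build_node_table <- function(clusters_by_seed, radius_mm = 3) {
  if (!length(clusters_by_seed) ||
      all(vapply(clusters_by_seed, nrow, 0L) == 0)) {
    abort("no clusters to build a node table from")
  }
  tabs <- purrr::imap(clusters_by_seed, function(cl, seed_name) {
    if (nrow(cl) == 0) return(NULL)
    tibble::tibble(
      node = paste0(seed_name, "_", seq_len(nrow(cl))),
      seed = seed_name,
      x = cl$peak_x, y = cl$peak_y, z = cl$peak_z,
      radius_mm = radius_mm, peak_t = cl$peak_t, cluster_size = cl$size
    )
  })
  out <- dplyr::bind_rows(tabs)
  key <- paste(out$x, out$y, out$z)
  if (anyDuplicated(key)) {
    warn("duplicate peak coordinates across seeds; keeping both")
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    out$node[dup] <- paste0(out$node[dup], "_dup")
  }
  out
}

#' Identify network nodes from subject volumes
#'
#' Full seed-based node identification: per subject and seed a seed-to-voxel
#' correlation map, Fisher z, a group one-sample t map, Bonferroni FWE
#' voxel thresholding inside the gray-matter mask, cluster extraction and a
#' merged node table. Negative-tail clusters (voxels significantly below
#' zero) are searched too and returned separately.
#'
#' @param volumes list of subject volumes (each `volume_phantom`-like).
#' @param gm_mask 3D gray-matter probability array.
#' @param seeds list of [seed_spec] (default [default_seed_specs()]).
#' @param alpha voxel FWE alpha (default 0.01).
#' @param min_cluster minimum cluster size in voxels (default 50).
#' @param connectivity component connectivity (default 26).
#' @param gm_prob gray-matter probability threshold (default 0.9).
#' @return list with `node_table`, `negative_clusters`, `t_maps` (per seed),
#'   `clusters` (per seed).
#' @export
identify_network_nodes <- function(volumes, gm_mask,
                                   seeds = default_seed_specs(),
                                   alpha = 0.01, min_cluster = 50,
                                   connectivity = 26, gm_prob = 0.9) {
  t_maps <- list(); clusters <- list(); neg_clusters <- list()
  for (sp in seeds) {
    z_maps <- lapply(volumes, function(v) fisher_z(seed_fc_map(v, sp)))
    t_map <- onesample_t_map(z_maps)
    keep <- fwe_voxel_threshold(t_map, alpha, gm_mask, gm_prob)
    pos <- keep & (t_map$values > 0)
    neg <- keep & (t_map$values < 0)
    t_maps[[sp$name]] <- t_map
    clusters[[sp$name]] <- extract_clusters(pos, t_map, min_cluster, connectivity)
    neg_map <- t_map
    neg_map$values <- -neg_map$values
    neg_clusters[[sp$name]] <- extract_clusters(neg, neg_map, min_cluster,
                                                connectivity)
  }
  list(node_table = build_node_table(clusters),
       negative_clusters = neg_clusters,
       t_maps = t_maps, clusters = clusters)
}

#' Write / read a 3D or 4D volume as NIfTI
#'
#' @param data numeric array (3D or 4D).
#' @param affine 4 x 4 voxel-to-MNI affine (0-based voxel indices).
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path` (write); list(data, affine) (read).
#' @export
write_volume_nifti <- function(data, affine, path) {
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}
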