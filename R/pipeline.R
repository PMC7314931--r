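#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline with its conventional
#' default: 35-TR windows at step 1 (TR = 3 s), 10 discarded volumes,
#' k = 2..12 candidate states with 50 k-means restarts, voxel FWE alpha
#' 0.01 with 50-voxel minimum clusters inside a > 0.9 gray-matter mask,
#' edgewise alpha 0.05, group alpha 0.05 with 5000 permutations, and the
#' Broca (-53, 20, 15) / Wernicke (-51, -51, 30) 3-mm seed spheres.
#'
#' @param window_length_tr,window_step_tr sliding-window geometry.
#' @param tr_seconds sampling interval.
#' @param discard_volumes initial volumes to drop.
#' @param k_range candidate state counts.
#' @param kmeans_restarts restarts per k.
#' @param node_alpha,min_cluster_voxels,gm_prob_threshold node stage.
#' @param edge_alpha per-window edgewise family alpha.
#' @param group_alpha group-test alpha.
#' @param n_perm permutation count.
#' @param master_seed master integer seed.
#' @param cluster_transform `"none"` or `"fisher_z"`: whether windows are
#'   clustered on raw correlations or atanh-transformed ones.
#' @param seeds list of [seed_spec].
#' @return list of class `analysis_config` with a `hash` attribute.
#' @export
analysis_config <- function(window_length_tr = 35, window_step_tr = 1,
                            tr_seconds = 3, discard_volumes = 10,
                            k_range = 2:12, kmeans_restarts = 50,
                            node_alpha = 0.01, min_cluster_voxels = 50,
                            gm_prob_threshold = 0.9, edge_alpha = 0.05,
                            group_alpha = 0.05, n_perm = 5000,
                            master_seed = 1, cluster_transform = "none",
                            seeds = default_seed_specs()) {
  cfg <- list(
    window_length_tr = window_length_tr, window_step_tr = window_step_tr,
    tr_seconds = tr_seconds, discard_volumes = discard_volumes,
    k_range = k_range, kmeans_restarts = kmeans_restarts,
    node_alpha = node_alpha, min_cluster_voxels = min_cluster_voxels,
    gm_prob_threshold = gm_prob_threshold, edge_alpha = edge_alpha,
    group_alpha = group_alpha, n_perm = n_perm, master_seed = master_seed,
    cluster_transform = cluster_transform, seeds = seeds
  )
  attr(cfg, "hash") <- rlang::hash(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config> hash ", attr(x, "hash"), "\n", sep = "")
  flat <- x[setdiff(names(x), "seeds")]
  for (nm in names(flat)) {
    cat("  ", nm, ": ", paste(flat[[nm]], collapse = " "), "\n", sep = "")
  }
  cat("  seeds: ", paste(vapply(x$seeds, function(s) s$name, ""),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Run the full dFC pipeline
#'
#' Orchestrates the stages: (optional) node identification from volumes,
#' sliding-window correlations, dynamic-matrix assembly, state clustering,
#' per-state mean dFC and topology, and permutation group inference. Input
#' is either a synthetic `dfc_dataset`, a list of [subject_series] (node
#' stage skipped), or a list of subject volumes plus a gray-matter mask.
#'
#' @param input a `dfc_dataset`, a list of [subject_series], or
#'   `list(volumes = ..., gm_mask = ...)`.
#' @param config an [analysis_config].
#' @param preprocess apply [preprocess_series()] conditioning to every
#'   series (default FALSE: synthetic series are already stationary
#'   zero-mean draws).
#' @param topology compute the per-window topology stage (default TRUE;
#'   the slowest stage).
#' @return list of class `dfc_results`: `config`, `node_table`, `states`,
#'   `state_means`, `dfc_tests`, `state_topo`, `topology_tests`,
#'   `window_corrs`, `true_states` (when known).
#' @export
run_pipeline <- function(input, config = analysis_config(),
                         preprocess = FALSE, topology = TRUE) {
  seed <- config$master_seed
  node_table <- NULL
  true_states <- NULL

  if (inherits(input, "dfc_dataset")) {
    series_list <- input$subjects
    true_states <- input$true_states
  } else if (is.list(input) && !is.null(input$volumes)) {
    if (is.null(input$gm_mask)) abort("node stage requires input$gm_mask")
    nodes <- identify_network_nodes(
      input$volumes, input$gm_mask, seeds = config$seeds,
      alpha = config$node_alpha, min_cluster = config$min_cluster_voxels,
      gm_prob = config$gm_prob_threshold
    )
    node_table <- nodes$node_table
    grp <- input$groups %||% rep(NA, length(input$volumes))
    series_list <- purrr::imap(input$volumes, function(v, i) {
      extract_node_series(v, node_table, tr_seconds = config$tr_seconds,
                          subject_id = sprintf("sub%02d", i), group = grp[[i]])
    })
  } else if (is.list(input) && all(vapply(input, inherits, TRUE, "subject_series"))) {
    series_list <- input
    inform("node-identification stage skipped: node series supplied directly")
  } else {
    abort("input must be a dfc_dataset, a list of subject_series, or list(volumes, gm_mask)")
  }

  if (preprocess) {
    series_list <- lapply(series_list, preprocess_series,
                          n_discard = config$discard_volumes)
  }

  wcs <- lapply(series_list, window_correlations,
                length_tr = config$window_length_tr,
                step_tr = config$window_step_tr)
  dynmat <- build_dynamic_matrix(wcs)
  states <- cluster_windows(dynmat, k_range = config$k_range,
                            n_restarts = config$kmeans_restarts,
                            rng_seed = child_seed(seed, 1),
                            transform = config$cluster_transform %||% "none")
  state_means <- state_mean_dfc(wcs, states$labels)
  dfc_tests <- compare_states(state_means, n_perm = config$n_perm,
                              rng_seed = child_seed(seed, 2))

  state_topo <- NULL; topology_tests <- NULL
  if (topology) {
    wm <- dplyr::bind_rows(lapply(wcs, window_topology,
                                  alpha = config$edge_alpha))
    state_topo <- state_topology(wm, states$labels)
    topology_tests <- compare_topology(state_topo, n_perm = config$n_perm,
                                       rng_seed = child_seed(seed, 3))
  }

  structure(
    list(config = config, node_table = node_table, states = states,
         state_means = state_means, dfc_tests = dfc_tests,
         state_topo = state_topo, topology_tests = topology_tests,
         window_corrs = wcs, true_states = true_states),
    class = "dfc_results"
  )
}

#' @export
print.dfc_results <- function(x, ...) {
  cat("<dfc_results> ", length(x$window_corrs), " subjects, k = ",
      x$states$k, " states\n", sep = "")
  n_sig <- sum(x$dfc_tests$p_fwe < x$config$group_alpha)
  cat("  ", n_sig, " edge-state comparison(s) significant at FWE p < ",
      x$config$group_alpha, "\n", sep = "")
  invisible(x)
}

#' Extract node-sphere mean series from a subject volume
#'
#' Averages each node's 3-mm sphere voxels into one series per node,
#' producing the [subject_series] the windowing stage consumes.
#'
#' @param volume a `volume_phantom` or list(data, affine).
#' @param node_table tibble with `node`, `x`, `y`, `z` (and optional
#'   `radius_mm`).
#' @param tr_seconds,subject_id,group series metadata.
#' @return a [subject_series].
#' @export
extract_node_series <- function(volume, node_table, tr_seconds = 3,
                                subject_id = "sub01", group = NA) {
  vp <- volume_parts(volume)
  d <- dim(vp$data)
  mat <- matrix(vp$data, prod(d[1:3]), d[4])
  radius <- if ("radius_mm" %in% names(node_table)) {
    node_table$radius_mm
  } else {
    rep(3, nrow(node_table))
  }
  series <- vapply(seq_len(nrow(node_table)), function(r) {
    vox <- sphere_voxels(c(node_table$x[r], node_table$y[r], node_table$z[r]),
                         radius[r], vp$affine, d[1:3])
    colMeans(mat[attr(vox, "linear"), , drop = FALSE])
  }, numeric(d[4]))
  colnames(series) <- node_table$node
  subject_series(series, tr_seconds = tr_seconds, subject_id = subject_id,
                 group = group)
}

#' Write a results bundle to disk
#'
#' Writes the stage outputs as TSV (labels, silhouettes, state means,
#' topology, test tables) plus a provenance JSON carrying the resolved
#' config, its hash and the master seed. All writes are atomic
#' (write-then-rename), and every TSV carries the config hash as a header
#' comment.
#'
#' @param results a `dfc_results` bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- attr(results$config, "hash")
  write_tsv_hashed <- function(df, file) {
    atomic_write(function(tmp) {
      con <- file(tmp, "w")
      on.exit(close(con))
      writeLines(paste0("# config_hash=", hash), con)
      utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(dir, file))
  }
  write_tsv_hashed(tibble::tibble(window = seq_along(results$states$labels),
                                  start = results$states$window_starts %||%
                                    (seq_along(results$states$labels) - 1L),
                                  state = results$states$labels),
                   "state_labels.tsv")
  write_tsv_hashed(results$states$silhouettes, "silhouettes.tsv")
  write_tsv_hashed(results$state_means, "state_mean_dfc.tsv")
  write_tsv_hashed(results$dfc_tests, "dfc_tests.tsv")
  if (!is.null(results$state_topo)) {
    write_tsv_hashed(results$state_topo, "state_topology.tsv")
    write_tsv_hashed(results$topology_tests, "topology_tests.tsv")
  }
  if (!is.null(results$node_table)) {
    write_tsv_hashed(results$node_table, "node_table.tsv")
  }
  cfg <- results$config
  prov <- list(config = cfg[setdiff(names(cfg), "seeds")],
               seeds = lapply(cfg$seeds, unclass),
               config_hash = hash,
               package_version = as.character(utils::packageVersion("dynfc")),
               selected_k = results$states$k)
  atomic_write(function(tmp) {
    jsonlite::write_json(prov, tmp, auto_unbox = TRUE, digits = NA)
  }, file.path(dir, "provenance.json"))
  invisible(dir)
}
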