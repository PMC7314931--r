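#' Latent connectivity-state model
#'
#' A `state_model` holds K symmetric positive-definite correlation matrices
#' (one per latent connectivity state), a row-stochastic K x K transition
#' matrix for the hidden Markov state sequence, and the implied mean dwell
#' time in TR units. It is the generative structure behind the recurring
#' dFC states that sliding-window clustering is meant to recover.
#'
#' @param correlations list of K correlation matrices (unit diagonal, SPD).
#' @param transition K x K row-stochastic matrix.
#' @param mean_dwell expected consecutive TRs spent in a state (>= 1).
#' @param node_names optional node labels (length N).
#' @return an object of class `state_model`.
#' @export
state_model <- function(correlations, transition, mean_dwell, node_names = NULL) {
  stopifnot(is.list(correlations), length(correlations) >= 1)
  k <- length(correlations)
  n <- nrow(correlations[[1]])
  node_names <- node_names %||% paste0("node", sprintf("%02d", seq_len(n)))
  m <- structure(
    list(
      n_states = k, n_nodes = n, correlations = correlations,
      transition = transition, mean_dwell = mean_dwell,
      node_names = node_names
    ),
    class = "state_model"
  )
  validate_state_model(m)
  m
}

#' @export
print.state_model <- function(x, ...) {
  cat("<state_model> ", x$n_states, " states, ", x$n_nodes, " nodes, mean dwell ",
      x$mean_dwell, " TRs\n", sep = "")
  invisible(x)
}

validate_state_model <- function(m) {
  for (s in seq_len(m$n_states)) {
    cm <- m$correlations[[s]]
    if (!isTRUE(all.equal(cm, t(cm), tolerance = 1e-10))) {
      abort(paste0("state ", s, ": correlation matrix not symmetric"))
    }
    if (max(abs(diag(cm) - 1)) > 1e-8) {
      abort(paste0("state ", s, ": diagonal not 1"))
    }
    off <- cm[upper.tri(cm)]
    if (length(off) && max(abs(off)) >= 1) {
      abort(paste0("state ", s, ": off-diagonal outside (-1, 1)"))
    }
    ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      abort(paste0("state ", s, ": correlation matrix not positive definite"))
    }
  }
  tr <- m$transition
  if (nrow(tr) != m$n_states || ncol(tr) != m$n_states) {
    abort("transition matrix dimension does not match n_states")
  }
  if (max(abs(rowSums(tr) - 1)) > 1e-10 || any(tr < 0)) {
    abort("transition matrix rows must be non-negative and sum to 1")
  }
  if (m$mean_dwell < 1) abort("mean_dwell must be >= 1")
  invisible(m)
}

# Random orthogonal matrix via QR of a Gaussian matrix, sign-fixed.
random_orthogonal <- function(n) {
  qrd <- qr(matrix(rnorm(n * n), n, n))
  q <- qr.Q(qrd)
  q %*% diag(sign(diag(qr.R(qrd))), n)
}

# One random SPD correlation matrix: orthogonal mixing of a random spiked
# spectrum (trace N before rescaling), eigenvalues floored at 0.05, then
# rescaled to unit diagonal.
random_state_correlation <- function(n_nodes, base_strength) {
  if (base_strength == 0) return(diag(n_nodes))
  g <- rexp(n_nodes)
  spec <- (1 - base_strength) + base_strength * n_nodes * g / sum(g)
  spec <- pmax(spec, 0.05)
  q <- random_orthogonal(n_nodes)
  m <- q %*% (spec * t(q))
  cm <- stats::cov2cor(m)
  ev <- eigen(cm, symmetric = TRUE)
  if (min(ev$values) < 0.05) {
    v <- pmax(ev$values, 0.05)
    cm <- stats::cov2cor(ev$vectors %*% (v * t(ev$vectors)))
  }
  (cm + t(cm)) / 2
}

#' Generate a latent state model with distinct SPD correlation matrices
#'
#' Each state's correlation matrix is built by orthogonally mixing a random
#' spiked eigen-spectrum and rescaling to unit diagonal; `base_strength` in
#' `[0, 1)` moves the spectrum from flat (identity correlation at 0) to
#' strongly spiked (large off-diagonal correlations near 1). The transition
#' matrix has self-transition probability `1 - 1/mean_dwell` with the
#' remaining mass spread uniformly over the other states, giving geometric
#' dwell times with the requested mean.
#'
#' @param n_nodes number of network nodes N (>= 2).
#' @param n_states number of latent states K (>= 1).
#' @param base_strength coupling strength in `[0, 1)`; default 0.85 yields
#'   off-diagonal correlations of roughly the magnitude seen in language-
#'   network dFC tables (|r| ~ 0.2-0.6).
#' @param mean_dwell expected dwell per state in TRs (default 50).
#' @param rng_seed integer seed.
#' @param node_names optional node labels.
#' @return a [state_model].
#' @export
make_state_correlations <- function(n_nodes, n_states, base_strength = 0.85,
                                    mean_dwell = 50, rng_seed = 1,
                                    node_names = NULL) {
  stopifnot(n_nodes >= 2, n_states >= 1,
            base_strength >= 0, base_strength < 1)
  correlations <- with_seed(rng_seed, {
    lapply(seq_len(n_states), function(s) {
      for (attempt in 1:20) {
        cm <- random_state_correlation(n_nodes, base_strength)
        ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) > 0) return(cm)
      }
      abort(paste0("state ", s, ": failed to construct an SPD correlation matrix"))
    })
  })
  if (n_states > 1 && base_strength > 0) {  # zero coupling: all states identity
    for (a in seq_len(n_states - 1)) {
      for (b in (a + 1):n_states) {
        if (norm(correlations[[a]] - correlations[[b]], "F") <= 0) {
          abort("generated states are not pairwise distinct")
        }
      }
    }
  }
  p_stay <- 1 - 1 / mean_dwell
  tr <- if (n_states == 1) {
    matrix(1, 1, 1)
  } else {
    t0 <- matrix((1 - p_stay) / (n_states - 1), n_states, n_states)
    diag(t0) <- p_stay
    t0
  }
  state_model(correlations, tr, mean_dwell, node_names = node_names)
}

#' Planted group effects on state-specific edges
#'
#' @param node_i,node_j node indices (or names resolved later) of each edge.
#' @param state state index the effect lives in.
#' @param delta additive difference in correlation (r units) given to group
#'   A relative to group B on that edge in that state.
#' @return a tibble with class `group_effects`.
#' @export
group_effects <- function(node_i, node_j, state, delta) {
  stopifnot(length(node_i) == length(node_j),
            length(node_i) == length(state),
            length(node_i) == length(delta))
  if (any(node_i == node_j)) abort("group effects require node_i != node_j")
  out <- tibble::tibble(node_i = as.integer(node_i), node_j = as.integer(node_j),
                        state = as.integer(state), delta = as.double(delta))
  class(out) <- c("group_effects", class(out))
  out
}

#' Default planted group effects
#'
#' Three edges, one in each of three different states, with additive
#' correlation differences of about 0.25-0.35 r units, the magnitude of the
#' group differences reported for early- vs late-bilingual language
#' networks. With the 17-node default node ordering these correspond to
#' IFGtriang.L-MTG.R (state 1), MTG.L-IFGoperc.R (state 2) and
#' TPOsup.R-MTG.L (state 3).
#'
#' @return a `group_effects` tibble.
#' @export
default_group_effects <- function() {
  group_effects(node_i = c(1L, 4L, 2L),
                node_j = c(5L, 14L, 4L),
                state = c(1L, 2L, 3L),
                delta = c(0.30, 0.30, 0.30))
}

#' Apply planted group effects to a state model
#'
#' Group "A" receives `+delta` on each listed edge in the listed state;
#' group "B" gets the model unchanged. If a perturbation destroys positive
#' definiteness the delta is halved (up to 10 times) before giving up.
#'
#' @param model a [state_model].
#' @param effects a [group_effects] tibble.
#' @param group `"A"` or `"B"`.
#' @return a [state_model] (perturbed for group A).
#' @export
apply_group_effects <- function(model, effects, group = c("A", "B")) {
  group <- match.arg(group)
  if (group == "B" || nrow(effects) == 0) return(model)
  if (any(effects$state < 1 | effects$state > model$n_states)) {
    abort("effect state index outside 1..K")
  }
  if (any(effects$node_i > model$n_nodes | effects$node_j > model$n_nodes)) {
    abort("effect node index outside 1..N")
  }
  cors <- model$correlations
  for (r in seq_len(nrow(effects))) {
    s <- effects$state[r]
    i <- effects$node_i[r]; j <- effects$node_j[r]
    delta <- effects$delta[r]
    for (attempt in 0:10) {
      d <- delta / 2^attempt
      cand <- cors[[s]]
      cand[i, j] <- cand[i, j] + d
      cand[j, i] <- cand[i, j]
      if (abs(cand[i, j]) < 1 &&
          min(eigen(cand, symmetric = TRUE, only.values = TRUE)$values) > 0) {
        if (attempt > 0) {
          warn(paste0("delta on edge (", i, ",", j, ") state ", s,
                      " shrunk to ", signif(d, 3), " to keep SPD"))
        }
        cors[[s]] <- cand
        d <- NULL
        break
      }
      if (attempt == 10) {
        abort(paste0("edge (", i, ",", j, ") state ", s,
                     ": perturbation destroys positive definiteness"))
      }
    }
  }
  state_model(cors, model$transition, model$mean_dwell, model$node_names)
}

#' Sample a Markov latent-state sequence
#'
#' @param n_timepoints sequence length T in TRs (>= 1).
#' @param transition K x K row-stochastic matrix.
#' @param rng_seed integer seed; identical seeds give identical sequences.
#' @param init optional initial distribution (default uniform).
#' @return integer vector of state labels in 1..K, length T.
#' @export
simulate_state_sequence <- function(n_timepoints, transition, rng_seed,
                                    init = NULL) {
  stopifnot(n_timepoints >= 1)
  k <- nrow(transition)
  init <- init %||% rep(1 / k, k)
  with_seed(rng_seed, {
    s <- integer(n_timepoints)
    s[1] <- sample.int(k, 1, prob = init)
    if (n_timepoints > 1) {
      for (t in 2:n_timepoints) {
        s[t] <- sample.int(k, 1, prob = transition[s[t - 1], ])
      }
    }
    s
  })
}

#' Balanced latent-state schedule
#'
#' Constructs a state sequence that visits every state exactly once, in
#' random order, with segment lengths of at least `min_run` TRs and the
#' remaining TRs allocated multinomially. This is the default schedule of
#' [simulate_dataset()]: it guarantees the planted states are all present
#' with enough contiguous occupancy to contain pure sliding windows, which
#' an unconditioned Markov chain with mean dwell comparable to T/K
#' frequently fails to do.
#'
#' @param n_timepoints sequence length T.
#' @param n_states number of states K.
#' @param min_run minimum segment length in TRs (default 36, one more than
#'   the default 35-TR window).
#' @param rng_seed integer seed.
#' @return integer state sequence of length T.
#' @export
simulate_state_schedule <- function(n_timepoints, n_states, min_run = 36,
                                    rng_seed = 1) {
  if (min_run * n_states > n_timepoints) {
    abort(paste0("cannot fit ", n_states, " segments of >= ", min_run,
                 " TRs into ", n_timepoints, " TRs"))
  }
  with_seed(rng_seed, {
    ord <- sample.int(n_states)
    extra <- n_timepoints - min_run * n_states
    add <- if (extra > 0) {
      as.vector(stats::rmultinom(1, extra, rep(1 / n_states, n_states)))
    } else {
      rep(0L, n_states)
    }
    rep(ord, times = min_run + add)
  })
}

# Longest run length per state for a label sequence (0 for absent states).
state_run_lengths <- function(states, k) {
  r <- rle(states)
  vapply(seq_len(k), function(s) {
    runs <- r$lengths[r$values == s]
    if (length(runs)) max(runs) else 0L
  }, integer(1))
}

#' Simulate one subject's node time series under a state model
#'
#' At each TR the node vector is drawn from a zero-mean multivariate normal
#' with the active state's correlation matrix, plus independent Gaussian
#' noise with standard deviation `noise_sd`. Under additive noise the
#' observable correlation on an edge with planted correlation r is
#' attenuated to r / (1 + noise_sd^2).
#'
#' @param model a [state_model].
#' @param true_states integer state labels, one per TR.
#' @param noise_sd independent noise SD (>= 0), default 0.5.
#' @param rng_seed integer seed.
#' @param tr_seconds sampling interval (default 3).
#' @param subject_id,group labels stored on the output.
#' @return a [subject_series].
#' @export
simulate_subject <- function(model, true_states, noise_sd = 0.5, rng_seed = 1,
                             tr_seconds = 3, subject_id = "sub01", group = NA) {
  stopifnot(noise_sd >= 0)
  n <- model$n_nodes
  t_len <- length(true_states)
  chols <- lapply(model$correlations, chol)
  vals <- with_seed(rng_seed, {
    out <- matrix(0, t_len, n)
    for (s in unique(true_states)) {
      idx <- which(true_states == s)
      z <- matrix(rnorm(length(idx) * n), length(idx), n)
      out[idx, ] <- z %*% chols[[s]]
    }
    if (noise_sd > 0) out <- out + matrix(rnorm(t_len * n, sd = noise_sd), t_len, n)
    out
  })
  colnames(vals) <- model$node_names
  subject_series(vals, tr_seconds = tr_seconds, subject_id = subject_id,
                 group = group)
}

#' Simulate a complete multi-subject dataset with planted structure
#'
#' Generates a latent state model, a single latent state sequence shared by
#' all subjects (matching a clustering layout that assigns one state label
#' per window index across subjects), and per-subject node series. Group A
#' subjects receive the planted edge effects; group B subjects do not. By
#' default the latent sequence is a balanced schedule
#' ([simulate_state_schedule()]) so every planted state is present with
#' enough contiguous occupancy to be recoverable; `schedule = "markov"`
#' instead samples the model's Markov chain and resamples (via child seeds)
#' until every state has a run of at least `min_state_run` TRs.
#'
#' @param n_a,n_b group sizes (defaults 10 and 11).
#' @param n_timepoints series length T in TRs (default 170).
#' @param n_nodes number of nodes (default 17; node names then come from the
#'   packaged language-network node table).
#' @param n_states number of latent states (default 4).
#' @param mean_dwell mean state dwell in TRs (default 50).
#' @param base_strength coupling strength (default 0.85).
#' @param noise_sd independent noise SD (default 0.5).
#' @param effects a [group_effects] tibble (default [default_group_effects()]).
#' @param rng_seed master integer seed.
#' @param schedule `"balanced"` (default) or `"markov"`.
#' @param min_state_run minimum segment (balanced) or longest-run (markov)
#'   length per state, in TRs (default 36).
#' @param tr_seconds sampling interval (default 3).
#' @return an object of class `dfc_dataset`: list with `subjects` (list of
#'   [subject_series]), `groups`, `true_states`, `model_a`, `model_b`,
#'   `effects`, `seed`.
#' @export
simulate_dataset <- function(n_a = 10, n_b = 11, n_timepoints = 170,
                             n_nodes = 17, n_states = 4, mean_dwell = 50,
                             base_strength = 0.85, noise_sd = 0.5,
                             effects = default_group_effects(), rng_seed = 1,
                             schedule = c("balanced", "markov"),
                             min_state_run = 36, tr_seconds = 3) {
  schedule <- match.arg(schedule)
  node_names <- if (n_nodes == 17) language_node_table()$node else NULL
  model_b <- make_state_correlations(n_nodes, n_states, base_strength,
                                     mean_dwell,
                                     rng_seed = child_seed(rng_seed, 1),
                                     node_names = node_names)
  model_a <- apply_group_effects(model_b, effects, "A")

  if (schedule == "balanced") {
    true_states <- simulate_state_schedule(n_timepoints, n_states,
                                           min_run = min_state_run,
                                           rng_seed = child_seed(rng_seed, 100))
  } else {
    true_states <- NULL
    for (attempt in seq_len(10000)) {
      cand <- simulate_state_sequence(n_timepoints, model_b$transition,
                                      rng_seed = child_seed(rng_seed, 100 + attempt))
      if (n_states == 1 ||
          min(state_run_lengths(cand, n_states)) >= min(min_state_run, n_timepoints)) {
        true_states <- cand
        break
      }
    }
    if (is.null(true_states)) {
      abort("could not sample a state sequence visiting every state long enough; lower min_state_run")
    }
  }

  groups <- c(rep("A", n_a), rep("B", n_b))
  ids <- sprintf("sub%02d", seq_along(groups))
  subjects <- lapply(seq_along(groups), function(s) {
    simulate_subject(if (groups[s] == "A") model_a else model_b,
                     true_states, noise_sd = noise_sd,
                     rng_seed = child_seed(rng_seed, 200 + s),
                     tr_seconds = tr_seconds, subject_id = ids[s],
                     group = groups[s])
  })
  structure(
    list(subjects = subjects, groups = groups, true_states = true_states,
         model_a = model_a, model_b = model_b, effects = effects,
         seed = rng_seed),
    class = "dfc_dataset"
  )
}

#' @export
print.dfc_dataset <- function(x, ...) {
  cat("<dfc_dataset> ", length(x$subjects), " subjects (",
      sum(x$groups == "A"), " A / ", sum(x$groups == "B"), " B), ",
      length(x$true_states), " TRs, ", x$model_b$n_nodes, " nodes, ",
      x$model_b$n_states, " latent states, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a 4D volume phantom with planted seed-coupled clusters
#'
#' Builds a small MNI-like 3-mm grid holding a latent signal for each seed
#' sphere and planted clusters of voxels whose series equal
#' `coupling * (seed sphere mean signal) + noise`; background voxels carry
#' independent noise. The gray-matter probability mask is 0.95 everywhere so
#' planted clusters always lie in the >= 0.9 region.
#'
#' @param node_table tibble with columns `node`, `x`, `y`, `z` giving the
#'   planted cluster centers (MNI mm).
#' @param grid_shape integer length-3 voxel grid dimensions.
#' @param seed_specs list of seed specs as from [seed_spec()]; the first is
#'   used as the latent signal source for all planted clusters unless the
#'   node table has a `seed` column naming one.
#' @param rng_seed integer seed.
#' @param n_timepoints volumes to simulate (default 170).
#' @param cluster_voxels voxels per planted cluster (default 60).
#' @param coupling coupling coefficient of cluster voxels to the seed mean
#'   signal (default 0.8); 0 plants nothing.
#' @param noise_sd voxel noise SD (default 1).
#' @param origin_mni MNI coordinate of voxel (0,0,0); default places the
#'   grid symmetrically around the node coordinates.
#' @return an object of class `volume_phantom`: list with 4D `data`,
#'   `affine`, `gm_mask`, `clusters`, `seed_specs`.
#' @export
simulate_volume_phantom <- function(node_table, grid_shape = c(40L, 48L, 38L),
                                    seed_specs = default_seed_specs(),
                                    rng_seed = 1, n_timepoints = 170,
                                    cluster_voxels = 60, coupling = 0.8,
                                    noise_sd = 1, origin_mni = c(-60, -90, -48)) {
  voxel_mm <- 3
  affine <- rbind(cbind(diag(voxel_mm, 3), origin_mni), c(0, 0, 0, 1))
  centers <- as.matrix(node_table[, c("x", "y", "z")])
  ijk <- t((t(centers) - origin_mni) / voxel_mm)
  inside <- apply(ijk, 1, function(v) all(v >= 0) && all(v <= grid_shape - 1))
  if (!all(inside)) {
    bad <- paste(apply(centers[!inside, , drop = FALSE], 1, paste, collapse = ","),
                 collapse = "; ")
    abort(paste0("node coordinates outside phantom grid: ", bad))
  }
  for (sp in seed_specs) {
    sijk <- (sp$center_mni - origin_mni) / voxel_mm
    if (any(sijk < 0) || any(sijk > grid_shape - 1)) {
      abort(paste0("seed ", sp$name, " outside phantom grid"))
    }
  }

  nv <- prod(grid_shape)
  grid_idx <- arrayInd(seq_len(nv), grid_shape) - 1L
  grid_mni <- t(t(grid_idx * voxel_mm) + origin_mni)

  with_seed(rng_seed, {
    data <- array(rnorm(nv * n_timepoints, sd = noise_sd),
                  dim = c(grid_shape, n_timepoints))
    seed_signals <- lapply(seed_specs, function(sp) rnorm(n_timepoints))
    names(seed_signals) <- vapply(seed_specs, function(sp) sp$name, "")

    seed_names <- names(seed_signals)
    assigned <- if ("seed" %in% names(node_table)) {
      match(node_table$seed, seed_names)
    } else {
      rep(1L, nrow(node_table))
    }
    assigned[is.na(assigned)] <- 1L

    add_signal <- function(vox_lin, signal, coef) {
      for (v in vox_lin) {
        sub <- arrayInd(v, grid_shape)
        data[sub[1], sub[2], sub[3], ] <<-
          data[sub[1], sub[2], sub[3], ] + coef * signal
      }
    }

    # seed spheres carry their own latent signal at unit coupling
    for (s in seq_along(seed_specs)) {
      sp <- seed_specs[[s]]
      vox <- sphere_voxels(sp$center_mni, sp$radius_mm, affine, grid_shape)
      add_signal(attr(vox, "linear"), seed_signals[[s]], 1)
    }

    clusters <- vector("list", nrow(node_table))
    for (r in seq_len(nrow(node_table))) {
      d2 <- colSums((t(grid_mni) - as.double(centers[r, ]))^2)
      vox_lin <- order(d2)[seq_len(cluster_voxels)]
      if (coupling != 0) {
        add_signal(vox_lin, seed_signals[[assigned[r]]], coupling)
      }
      clusters[[r]] <- tibble::tibble(
        node = node_table$node[r], x = centers[r, 1], y = centers[r, 2],
        z = centers[r, 3], n_voxels = cluster_voxels, coupling = coupling,
        seed = seed_names[assigned[r]], voxels = list(vox_lin)
      )
    }
    gm_mask <- array(0.95, dim = grid_shape)
    structure(
      list(data = data, affine = affine, voxel_size = voxel_mm,
           gm_mask = gm_mask, clusters = dplyr::bind_rows(clusters),
           seed_specs = seed_specs, seed = rng_seed),
      class = "volume_phantom"
    )
  })
}

#' @export
print.volume_phantom <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume_phantom> grid ", paste(d[1:3], collapse = "x"), ", ", d[4],
      " volumes, ", nrow(x$clusters), " planted clusters\n", sep = "")
  invisible(x)
}
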