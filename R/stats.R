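#' Cohen's d from summary statistics (pooled SD)
#'
#' d = (mean_a - mean_b) / s_p with
#' s_p = sqrt(((n_a - 1) sd_a^2 + (n_b - 1) sd_b^2) / (n_a + n_b - 2)).
#'
#' @param mean_a,sd_a,n_a group A summary.
#' @param mean_b,sd_b,n_b group B summary.
#' @return Cohen's d (vectorized over its arguments).
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(all(n_a >= 2), all(n_b >= 2), all(sd_a >= 0), all(sd_b >= 0))
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (any(sp == 0)) abort("pooled standard deviation is zero")
  (mean_a - mean_b) / sp
}

#' Cohen's d from raw samples
#' @param a,b numeric vectors.
#' @return Cohen's d.
#' @export
cohens_d_samples <- function(a, b) {
  cohens_d(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
}

# n_perm random group-A index sets (columns), sizes preserved.
permutation_indices <- function(n_total, n_a, n_perm, rng_seed) {
  with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(p) sample.int(n_total, n_a), integer(n_a))
  })
}

#' Two-tailed permutation test for a group mean difference
#'
#' The statistic is |mean(A) - mean(B)|; group labels are randomly
#' re-assigned (group sizes preserved) `n_perm` times and
#' p = (1 + #\{permuted statistic >= observed\}) / (1 + n_perm), so p is
#' never 0 and the test is two-tailed through the absolute difference.
#' When the number of distinct group-A assignments `choose(n, n_a)` does not
#' exceed `n_perm` the test enumerates them all instead and returns the
#' exact permutation p. Degenerate all-equal data give p = 1.
#'
#' @param values_a,values_b numeric per-subject values (>= 2 each).
#' @param n_perm permutation count (default 5000).
#' @param rng_seed integer seed; identical seeds give identical p.
#' @return list: `p`, `observed` (signed mean difference), `n_perm`,
#'   `exact` (TRUE when fully enumerated).
#' @export
permutation_test <- function(values_a, values_b, n_perm = 5000, rng_seed = 1) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2, n_perm >= 1)
  pool <- c(values_a, values_b)
  n_a <- length(values_a); n <- length(pool)
  observed <- mean(values_a) - mean(values_b)
  tot <- sum(pool)
  # the null is a function of the pooled values only: splits are drawn from
  # the sorted pool at the smaller group size, so swapping the group labels
  # leaves the permutation distribution (and hence p) unchanged
  m <- min(n_a, n - n_a)
  spool <- sort(pool)
  exact <- choose(n, m) <= n_perm
  idx <- if (exact) {
    utils::combn(n, m)
  } else {
    permutation_indices(n, m, n_perm, rng_seed)
  }
  sum_s <- colSums(matrix(spool[idx], nrow = m))
  perm_stat <- abs(sum_s / m - (tot - sum_s) / (n - m))
  hits <- sum(perm_stat >= abs(observed) - 1e-12)
  p <- if (exact) {
    hits / ncol(idx)  # the observed assignment is one of the enumerated ones
  } else {
    (1 + hits) / (1 + n_perm)
  }
  list(p = p, observed = observed, n_perm = n_perm, exact = exact)
}

#' Max-statistic permutation FWE across a family of comparisons
#'
#' Single-step family-wise error control: each permutation re-labels the
#' subjects once for the whole family; each member's permuted |mean
#' difference| is standardized by its own permutation SD, and the maximum
#' standardized statistic across members forms the null distribution.
#' Adjusted p-values use the same (1 + count)/(1 + n_perm) convention, so
#' adjusted p >= unadjusted p up to that convention.
#'
#' @param mat_a n_a x m matrix (group A subjects x family members).
#' @param mat_b n_b x m matrix.
#' @param n_perm permutation count (default 5000).
#' @param rng_seed integer seed.
#' @return tibble: `member`, `observed` (signed difference), `p_perm`
#'   (member-wise), `p_fwe` (max-statistic adjusted).
#' @export
fwe_max_stat <- function(mat_a, mat_b, n_perm = 5000, rng_seed = 1) {
  mat_a <- as.matrix(mat_a); mat_b <- as.matrix(mat_b)
  stopifnot(ncol(mat_a) == ncol(mat_b), nrow(mat_a) >= 2, nrow(mat_b) >= 2)
  m <- ncol(mat_a)
  pool <- rbind(mat_a, mat_b)
  n <- nrow(pool); n_a <- nrow(mat_a)
  observed <- colMeans(mat_a) - colMeans(mat_b)

  # canonical null: split the subject rows (sorted lexicographically so the
  # result does not depend on which group was called A) at the smaller size
  n_s <- min(n_a, n - n_a)
  pool <- pool[do.call(order, as.data.frame(pool)), , drop = FALSE]
  idx <- permutation_indices(n, n_s, n_perm, rng_seed)
  in_s <- matrix(0, n, n_perm)
  in_s[cbind(as.vector(idx), rep(seq_len(n_perm), each = n_s))] <- 1
  tot <- colSums(pool)
  sum_s <- t(pool) %*% in_s                     # m x n_perm
  perm_diff <- sum_s / n_s - (tot - sum_s) / (n - n_s)
  perm_abs <- abs(perm_diff)

  # member-wise p
  obs_abs <- abs(observed)
  p_perm <- (1 + rowSums(perm_abs >= obs_abs - 1e-12)) / (1 + n_perm)

  # standardize by permutation SD, then take the family max
  perm_sd <- apply(perm_diff, 1, sd)
  perm_sd[perm_sd == 0] <- 1
  null_max <- apply(perm_abs / perm_sd, 2, max)
  obs_std <- obs_abs / perm_sd
  p_fwe <- (1 + vapply(obs_std, function(o) sum(null_max >= o - 1e-12), 0)) /
    (1 + n_perm)

  tibble::tibble(
    member = colnames(mat_a) %||% paste0("m", seq_len(m)),
    observed = observed, p_perm = p_perm, p_fwe = pmax(p_fwe, p_perm)
  )
}

# Shared engine: per family, permutation tests with max-stat FWE + Cohen's d.
compare_family <- function(df, family_col, member_col, value_col,
                           n_perm, rng_seed) {
  fam_ids <- unique(df[[family_col]])
  out <- purrr::imap(setNames(fam_ids, fam_ids), function(fam, fam_chr) {
    sub <- df[df[[family_col]] == fam, ]
    wide <- tidyr::pivot_wider(
      sub[, c("subject", "group", member_col, value_col)],
      names_from = dplyr::all_of(member_col),
      values_from = dplyr::all_of(value_col)
    )
    complete <- stats::complete.cases(wide[, -(1:2)])
    if (any(!complete)) {
      enough <- function(w) {
        sum(w$group == "A") >= 2 && sum(w$group == "B") >= 2
      }
      if (enough(wide[complete, ])) {
        inform(paste0(sum(!complete), " subject(s) dropped from family '",
                      fam_chr, "' (missing values)"))
        wide <- wide[complete, ]
      } else {
        # dropping subjects would exhaust a group: drop the undefined
        # members (e.g. states whose path length is undefined) instead
        bad <- vapply(wide[, -(1:2), drop = FALSE],
                      function(col) anyNA(col), TRUE)
        inform(paste0("member(s) ", paste(names(bad)[bad], collapse = ", "),
                      " dropped from family '", fam_chr,
                      "' (undefined for too many subjects)"))
        wide <- wide[, c(TRUE, TRUE, !bad)]
        if (ncol(wide) <= 2) return(NULL)
      }
    }
    mat <- as.matrix(wide[, -(1:2)])
    a <- mat[wide$group == "A", , drop = FALSE]
    b <- mat[wide$group == "B", , drop = FALSE]
    res <- fwe_max_stat(a, b, n_perm = n_perm,
                        rng_seed = child_seed(rng_seed, match(fam, fam_ids)))
    res$mean_a <- colMeans(a); res$sd_a <- apply(a, 2, sd)
    res$mean_b <- colMeans(b); res$sd_b <- apply(b, 2, sd)
    res$n_a <- nrow(a); res$n_b <- nrow(b)
    # degenerate members (both groups constant) get d = NA rather than erroring
    sp <- sqrt(((res$n_a - 1) * res$sd_a^2 + (res$n_b - 1) * res$sd_b^2) /
                 (res$n_a + res$n_b - 2))
    res$d <- ifelse(sp > 0, (res$mean_a - res$mean_b) / sp, NA_real_)
    res[[family_col]] <- fam
    res
  })
  dplyr::bind_rows(out) |>
    dplyr::select(dplyr::all_of(family_col), "member", "mean_a", "sd_a",
                  "mean_b", "sd_b", "observed", "d", "p_perm", "p_fwe",
                  "n_a", "n_b")
}

#' Group comparison of per-state mean dFC
#'
#' For every state, permutation tests over the family of edges within that
#' state (member-wise p and max-statistic FWE-adjusted p) plus Cohen's d
#' from the pooled SD. Subjects missing a state are dropped from that
#' state's family with a message.
#'
#' @param state_means tibble from [state_mean_dfc()].
#' @param n_perm permutations (default 5000).
#' @param rng_seed integer seed.
#' @return tibble of class `dfc_test`: `state`, `member` (edge), group
#'   means/SDs, `observed` difference, `d`, `p_perm`, `p_fwe`, `n_a`,
#'   `n_b`.
#' @export
compare_states <- function(state_means, n_perm = 5000, rng_seed = 1) {
  out <- compare_family(state_means, "state", "edge", "mean_r",
                        n_perm, rng_seed)
  class(out) <- c("dfc_test", class(out))
  out
}

#' Group comparison of per-state topology metrics
#'
#' For each metric (cw, lw, eglob, eloc), the family is the set of states;
#' member-wise and max-statistic FWE-adjusted permutation p-values plus
#' Cohen's d.
#'
#' @param state_topo tibble from [state_topology()].
#' @param n_perm permutations (default 5000).
#' @param rng_seed integer seed.
#' @return tibble of class `dfc_test`: `metric`, `member` (state), group
#'   summaries, `observed`, `d`, `p_perm`, `p_fwe`.
#' @export
compare_topology <- function(state_topo, n_perm = 5000, rng_seed = 1) {
  long <- tidyr::pivot_longer(state_topo,
                              cols = c("cw", "lw", "eglob", "eloc"),
                              names_to = "metric", values_to = "value") |>
    dplyr::mutate(member_state = paste0("state", .data$state))
  out <- compare_family(long, "metric", "member_state", "value",
                        n_perm, rng_seed)
  class(out) <- c("dfc_test", class(out))
  out
}
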