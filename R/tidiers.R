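#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a dFC state assignment
#'
#' One row per window: its start TR and assigned state.
#'
#' @param x a `dfc_states` object.
#' @param ... unused.
#' @return tibble with `window`, `start`, `state`.
#' @method tidy dfc_states
#' @export
tidy.dfc_states <- function(x, ...) {
  starts <- x$window_starts %||% (seq_along(x$labels) - 1L)
  tibble::tibble(
    window = seq_along(x$labels),
    start = as.integer(starts),
    state = x$labels
  )
}

#' One-line summary of a dFC state assignment
#'
#' @param x a `dfc_states` object.
#' @param ... unused.
#' @return one-row tibble: `k`, `silhouette`, `inertia`, `n_windows`,
#'   `min_occupancy`, `max_occupancy`.
#' @method glance dfc_states
#' @export
glance.dfc_states <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    silhouette = x$silhouettes$silhouette[match(x$k, x$silhouettes$k)],
    inertia = x$inertia,
    n_windows = length(x$labels),
    min_occupancy = min(x$occupancy),
    max_occupancy = max(x$occupancy)
  )
}

#' Tidy a group-comparison table
#'
#' `dfc_test` tables are already tidy; this returns them as a plain tibble.
#'
#' @param x a `dfc_test` table.
#' @param ... unused.
#' @return tibble.
#' @method tidy dfc_test
#' @export
tidy.dfc_test <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-line summary of a group-comparison table
#'
#' @param x a `dfc_test` table.
#' @param alpha significance threshold (default 0.05).
#' @param ... unused.
#' @return one-row tibble: `n_tests`, `n_sig_perm`, `n_sig_fwe`, `max_abs_d`.
#' @method glance dfc_test
#' @export
glance.dfc_test <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_sig_perm = sum(x$p_perm < alpha),
    n_sig_fwe = sum(x$p_fwe < alpha),
    max_abs_d = if (nrow(x)) max(abs(x$d)) else NA_real_
  )
}
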