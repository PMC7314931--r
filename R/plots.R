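#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_tile geom_col
#'   geom_errorbar facet_wrap labs scale_fill_gradient2 theme_minimal
#'   position_dodge
#' @importFrom rlang .data
NULL

#' Silhouette-versus-k curve for a state assignment
#'
#' @param object a `dfc_states` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot dfc_states
#' @export
autoplot.dfc_states <- function(object, ...) {
  ggplot(object$silhouettes, aes(x = .data$k, y = .data$silhouette)) +
    geom_line() +
    geom_point(aes(colour = .data$k == object$k), show.legend = FALSE) +
    labs(x = "number of states k", y = "mean silhouette",
         title = paste0("Silhouette curve (selected k = ", object$k, ")")) +
    theme_minimal()
}

#' State-sequence plot: assigned state over window start
#'
#' @param states a `dfc_states` object.
#' @return a ggplot.
#' @export
plot_state_sequence <- function(states) {
  df <- tidy(states)
  ggplot(df, aes(x = .data$start, y = .data$state)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "window start (TR)", y = "dFC state") +
    theme_minimal()
}

#' Centroid connectivity heatmaps, one facet per state
#'
#' Averages the subject blocks of each centroid into one edge vector per
#' state and displays it as an N x N correlation heatmap.
#'
#' @param states a `dfc_states` object.
#' @return a ggplot.
#' @export
plot_state_centroids <- function(states) {
  en <- states$edge_names
  if (is.null(en)) abort("states object carries no edge names")
  n_sub <- length(states$subject_order %||% 1)
  e <- length(en)
  dfs <- purrr::map(seq_len(states$k), function(s) {
    cen <- matrix(states$centroids[s, ], nrow = e)
    v <- rowMeans(cen)
    m <- vec_to_sym(v, diag_value = 1)
    nn <- n_nodes_from_edges(e)
    ep <- edge_pairs(nn)
    tibble::tibble(state = paste0("state ", s),
                   node_i = c(ep[, 1], ep[, 2], seq_len(nn)),
                   node_j = c(ep[, 2], ep[, 1], seq_len(nn)),
                   r = c(v, v, rep(1, nn)))
  })
  ggplot(dplyr::bind_rows(dfs),
         aes(x = .data$node_i, y = .data$node_j, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    facet_wrap(~state) +
    labs(x = "node", y = "node", fill = "r") +
    theme_minimal()
}

#' Group-comparison effect plot
#'
#' Group means with SD error bars for the significant members of a
#' `dfc_test` table.
#'
#' @param object a `dfc_test` table.
#' @param alpha FWE threshold used to pick members to show (default 0.05);
#'   set to 1 to show everything.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot dfc_test
#' @export
autoplot.dfc_test <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(unclass(object)) |>
    dplyr::filter(.data$p_fwe < alpha)
  if (nrow(df) == 0) df <- tibble::as_tibble(unclass(object))
  fam <- setdiff(names(df), c("member", "mean_a", "sd_a", "mean_b", "sd_b",
                              "observed", "d", "p_perm", "p_fwe",
                              "n_a", "n_b"))[1]
  long <- df |>
    dplyr::mutate(label = paste(.data[[fam]], .data$member)) |>
    tidyr::pivot_longer(cols = c("mean_a", "mean_b"),
                        names_to = "grp", values_to = "mean") |>
    dplyr::mutate(sd = ifelse(.data$grp == "mean_a", .data$sd_a, .data$sd_b),
                  grp = ifelse(.data$grp == "mean_a", "A", "B"))
  ggplot(long, aes(x = .data$label, y = .data$mean, fill = .data$grp)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd),
                  position = position_dodge(width = 0.8), width = 0.25) +
    labs(x = NULL, y = "group mean", fill = "group") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
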