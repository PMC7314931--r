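#' Sliding-window start/end indices
#'
#' Windows of `length_tr` TRs advanced by `step_tr`, reported as 0-based
#' half-open `[start, end)` TR intervals. The count is
#' `floor((T - length) / step) + 1`; 170 TRs with a 35-TR window at step 1
#' give 136 windows.
#'
#' @param n_timepoints total TRs T.
#' @param length_tr window length in TRs (default 35, i.e. 105 s at TR 3 s).
#' @param step_tr step in TRs (default 1).
#' @return tibble with columns `window`, `start`, `end` (0-based half-open).
#' @export
window_indices <- function(n_timepoints, length_tr = 35, step_tr = 1) {
  if (!(step_tr >= 1 && step_tr <= length_tr)) {
    abort("need 1 <= step_tr <= length_tr")
  }
  if (length_tr > n_timepoints) {
    abort(paste0("window length ", length_tr, " exceeds series length ",
                 n_timepoints))
  }
  n_win <- floor((n_timepoints - length_tr) / step_tr) + 1
  start <- (seq_len(n_win) - 1L) * step_tr
  tibble::tibble(window = seq_len(n_win), start = as.integer(start),
                 end = as.integer(start + length_tr))
}

#' Windowed edge correlations for one subject
#'
#' For each sliding window, the Pearson correlation between every node pair
#' over that window's subseries (window-local means and SDs; rectangular
#' window, no taper). A node with zero variance inside a window has its
#' edges set to 0 for that window, with the affected count reported via a
#' message.
#'
#' @param series a [subject_series] (or T x N matrix).
#' @param length_tr window length in TRs (default 35; must be >= 3).
#' @param step_tr step in TRs (default 1).
#' @return a W x E matrix of class `window_corr` (E = N(N-1)/2 edges in
#'   row-major upper-triangle order) with attributes `edge_names`,
#'   `node_names`, `window_starts`, `length_tr`, `subject`, `group`.
#' @export
window_correlations <- function(series, length_tr = 35, step_tr = 1) {
  v <- series_values(series)
  if (length_tr < 3) abort("window length must be >= 3")
  wins <- window_indices(nrow(v), length_tr, step_tr)
  n <- ncol(v)
  ep <- edge_pairs(n)
  out <- matrix(NA_real_, nrow(wins), nrow(ep))
  n_zero <- 0L
  for (w in seq_len(nrow(wins))) {
    sub <- v[(wins$start[w] + 1):wins$end[w], , drop = FALSE]
    cv <- stats::cov(sub)
    sds <- sqrt(diag(cv))
    zero <- sds == 0
    if (any(zero)) {
      n_zero <- n_zero + sum(zero)
      sds[zero] <- 1
    }
    cm <- cv / tcrossprod(sds)
    if (any(zero)) {
      cm[zero, ] <- 0
      cm[, zero] <- 0
    }
    out[w, ] <- cm[ep]
  }
  if (n_zero > 0) {
    inform(paste0(n_zero, " zero-variance node-window(s); their edges set to 0"))
  }
  nn <- colnames(v) %||% paste0("node", sprintf("%02d", seq_len(n)))
  structure(out,
            class = c("window_corr", "matrix", "array"),
            edge_names = edge_names(nn), node_names = nn,
            window_starts = wins$start, length_tr = length_tr,
            subject = if (inherits(series, "subject_series")) series$subject_id else NA,
            group = if (inherits(series, "subject_series")) series$group else NA)
}

#' Long-format view of windowed correlations
#' @param x a `window_corr` matrix.
#' @param ... unused.
#' @return tibble with `subject`, `group`, `window`, `edge`, `r`.
#' @method as_tibble window_corr
#' @export
as_tibble.window_corr <- function(x, ...) {
  tibble::tibble(
    subject = attr(x, "subject"), group = attr(x, "group"),
    window = rep(seq_len(nrow(x)), times = ncol(x)),
    edge = rep(attr(x, "edge_names"), each = nrow(x)),
    r = as.vector(unclass(x))
  )
}

#' Assemble the group dynamic connectivity matrix
#'
#' Row w concatenates the window-w edge vectors of all subjects
#' (subject-major column blocks), producing a W x (S * E) matrix whose rows
#' are the samples clustered into dFC states: with 21 subjects, 17 nodes
#' and 136 windows this is 136 x 2856 (21 x (N^2 - N)/2 columns).
#'
#' @param window_corrs list of `window_corr` matrices, one per subject, all
#'   with identical window and edge structure.
#' @return a W x (S*E) matrix of class `dynamic_matrix` with attributes
#'   `subject_order`, `edge_names`, `node_names`, `window_starts`,
#'   `length_tr`, `groups`.
#' @export
build_dynamic_matrix <- function(window_corrs) {
  stopifnot(length(window_corrs) >= 1)
  w0 <- nrow(window_corrs[[1]]); e0 <- ncol(window_corrs[[1]])
  ids <- purrr::imap_chr(window_corrs, function(wc, i) {
    as.character(attr(wc, "subject") %||% i)
  })
  for (s in seq_along(window_corrs)) {
    if (nrow(window_corrs[[s]]) != w0 || ncol(window_corrs[[s]]) != e0) {
      abort(paste0("subject ", ids[s], " has a ragged window/edge layout"))
    }
  }
  out <- do.call(cbind, lapply(window_corrs, unclass))
  structure(out,
            class = c("dynamic_matrix", "matrix", "array"),
            subject_order = ids,
            groups = vapply(window_corrs, function(wc) {
              as.character(attr(wc, "group") %||% NA)
            }, ""),
            edge_names = attr(window_corrs[[1]], "edge_names"),
            node_names = attr(window_corrs[[1]], "node_names"),
            window_starts = attr(window_corrs[[1]], "window_starts"),
            length_tr = attr(window_corrs[[1]], "length_tr"))
}

#' @export
print.dynamic_matrix <- function(x, ...) {
  cat("<dynamic_matrix> ", nrow(x), " windows x ", ncol(x), " columns (",
      length(attr(x, "subject_order")), " subjects x ",
      length(attr(x, "edge_names")), " edges)\n", sep = "")
  invisible(x)
}

#' Persist / load a dynamic matrix (TSV + JSON sidecar)
#'
#' @param dynmat a `dynamic_matrix`.
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return base path (write); `dynamic_matrix` (read).
#' @export
write_dynamic_matrix <- function(dynmat, path) {
  atomic_write(function(tmp) {
    utils::write.table(unclass(dynmat), tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }, paste0(path, ".tsv"))
  meta <- list(subject_order = attr(dynmat, "subject_order"),
               groups = attr(dynmat, "groups"),
               edge_names = attr(dynmat, "edge_names"),
               node_names = attr(dynmat, "node_names"),
               window_starts = attr(dynmat, "window_starts"),
               length_tr = attr(dynmat, "length_tr"))
  atomic_write(function(tmp) {
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA)
  }, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_dynamic_matrix
#' @export
read_dynamic_matrix <- function(path) {
  m <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t",
                                   header = FALSE))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(m, class = c("dynamic_matrix", "matrix", "array"),
            subject_order = meta$subject_order, groups = meta$groups,
            edge_names = meta$edge_names, node_names = meta$node_names,
            window_starts = meta$window_starts, length_tr = meta$length_tr)
}
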