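#' A subject's node-by-time signal matrix
#'
#' @param values T x N numeric matrix (rows = TRs, columns = nodes).
#' @param tr_seconds sampling interval in seconds (default 3).
#' @param node_names node labels; default taken from column names.
#' @param subject_id subject label.
#' @param group group label (e.g. "A"/"B"), or NA.
#' @return an object of class `subject_series`.
#' @export
subject_series <- function(values, tr_seconds = 3, node_names = NULL,
                           subject_id = "sub01", group = NA) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2) {
    abort("subject_series needs T >= 2 rows and N >= 2 columns")
  }
  if (!all(is.finite(values))) abort("subject_series values must be finite")
  node_names <- node_names %||% colnames(values) %||%
    paste0("node", sprintf("%02d", seq_len(ncol(values))))
  if (anyDuplicated(node_names)) abort("node names must be unique")
  colnames(values) <- node_names
  structure(
    list(values = values, tr_seconds = tr_seconds, node_names = node_names,
         subject_id = subject_id, group = group),
    class = "subject_series"
  )
}

#' @export
print.subject_series <- function(x, ...) {
  cat("<subject_series> ", x$subject_id, ": ", nrow(x$values), " TRs x ",
      ncol(x$values), " nodes, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' @export
dim.subject_series <- function(x) dim(x$values)

#' Long-format view of a subject series
#' @param x a [subject_series].
#' @param ... unused.
#' @return tibble with columns `subject`, `group`, `tr`, `node`, `value`.
#' @method as_tibble subject_series
#' @export
as_tibble.subject_series <- function(x, ...) {
  tibble::tibble(
    subject = x$subject_id, group = x$group,
    tr = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    node = rep(x$node_names, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

series_values <- function(series) {
  if (inherits(series, "subject_series")) series$values else as.matrix(series)
}

replace_values <- function(series, values) {
  if (inherits(series, "subject_series")) {
    series$values <- values
    colnames(series$values) <- series$node_names
    series
  } else {
    values
  }
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` TRs (default 10, the usual allowance for the
#' MR signal to reach steady state; 180 acquired volumes become 170).
#'
#' @param series a [subject_series] (or plain matrix).
#' @param n_discard number of initial rows to drop (must be < T).
#' @return same class as input with the first rows removed.
#' @export
discard_initial <- function(series, n_discard = 10) {
  v <- series_values(series)
  if (n_discard >= nrow(v)) {
    abort(paste0("n_discard (", n_discard, ") must be smaller than T (", nrow(v), ")"))
  }
  if (n_discard == 0) return(series)
  replace_values(series, v[-seq_len(n_discard), , drop = FALSE])
}

#' Remove a least-squares linear trend from every node
#'
#' @param series a [subject_series] (or plain matrix) with T >= 3.
#' @return detrended series; residuals are orthogonal to the constant and
#'   linear terms.
#' @export
linear_detrend <- function(series) {
  v <- series_values(series)
  if (nrow(v) < 3) abort("linear_detrend needs T >= 3")
  t_idx <- seq_len(nrow(v))
  x <- cbind(1, t_idx)
  replace_values(series, v - x %*% qr.coef(qr(x), v))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (`signal::filtfilt`), so no temporal shift is introduced. The default
#' 0.01-0.08 Hz band is the conventional resting-state BOLD range; at
#' TR = 3 s the Nyquist frequency is 1/6 Hz.
#'
#' @param series a [subject_series] (or matrix; then `tr_seconds` is used).
#' @param low_hz,high_hz band edges in Hz (defaults 0.01, 0.08).
#' @param tr_seconds sampling interval, read from the series if present.
#' @param order Butterworth order per pass (default 2; the effective
#'   attenuation is doubled by the forward-backward application).
#' @return filtered series.
#' @export
bandpass_filter <- function(series, low_hz = 0.01, high_hz = 0.08,
                            tr_seconds = NULL, order = 2) {
  v <- series_values(series)
  tr <- tr_seconds %||%
    (if (inherits(series, "subject_series")) series$tr_seconds else 3)
  nyquist <- 1 / (2 * tr)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyquist)) {
    abort(paste0("band [", low_hz, ", ", high_hz,
                 "] Hz infeasible: Nyquist is ", signif(nyquist, 4),
                 " Hz at TR = ", tr, " s"))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  out <- apply(v, 2, function(col) signal::filtfilt(bf, col))
  replace_values(series, out)
}

#' Regress out nuisance covariates
#'
#' Ordinary-least-squares residuals of each node series after projecting out
#' the confound columns plus an intercept. Rank-deficient confound sets have
#' their linearly dependent columns dropped with a warning. With no
#' confounds this reduces to mean-centering.
#'
#' @param series a [subject_series] (or matrix).
#' @param confounds T x C numeric matrix/data frame (C < T), or NULL/empty.
#' @return residual series.
#' @export
regress_nuisance <- function(series, confounds = NULL) {
  v <- series_values(series)
  if (is.null(confounds) || NCOL(confounds) == 0 || length(confounds) == 0) {
    x <- matrix(1, nrow(v), 1)
  } else {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nrow(v)) abort("confounds must have T rows")
    if (ncol(confounds) >= nrow(v)) abort("need C < T confound columns")
    x <- cbind(1, confounds)
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      keep <- qx$pivot[seq_len(qx$rank)]
      warn(paste0("dropped ", ncol(x) - qx$rank,
                  " linearly dependent confound column(s)"))
      x <- x[, sort(keep), drop = FALSE]
    }
  }
  qx <- qr(x)
  replace_values(series, v - x %*% qr.coef(qx, v))
}

#' Standard conditioning pipeline for one subject
#'
#' Discard initial volumes, remove linear trends, band-pass filter, regress
#' nuisance covariates — in that order. Any step can be switched off.
#' Global-signal regression is deliberately not offered.
#'
#' @param series a [subject_series].
#' @param n_discard initial volumes to drop (default 10; 0 disables).
#' @param detrend apply [linear_detrend()] (default TRUE).
#' @param low_hz,high_hz band-pass edges; NULL disables filtering.
#' @param confounds optional confound matrix (already trimmed to the
#'   retained TRs), NULL skips nuisance regression entirely.
#' @return conditioned [subject_series].
#' @export
preprocess_series <- function(series, n_discard = 10, detrend = TRUE,
                              low_hz = 0.01, high_hz = 0.08,
                              confounds = NULL) {
  out <- discard_initial(series, n_discard)
  if (detrend) out <- linear_detrend(out)
  if (!is.null(low_hz) && !is.null(high_hz)) {
    out <- bandpass_filter(out, low_hz, high_hz)
  }
  if (!is.null(confounds)) out <- regress_nuisance(out, confounds)
  out
}

#' Write / read a subject series as TSV
#'
#' Columns are node names, rows are TRs; written atomically.
#'
#' @param series a [subject_series].
#' @param path file path.
#' @return `path` (write) or a [subject_series] (read).
#' @export
write_series_tsv <- function(series, path) {
  v <- series_values(series)
  atomic_write(function(tmp) {
    utils::write.table(as.data.frame(v), tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, path)
}

#' @rdname write_series_tsv
#' @param tr_seconds,subject_id,group metadata for the reconstructed series.
#' @export
read_series_tsv <- function(path, tr_seconds = 3, subject_id = NULL,
                            group = NA) {
  v <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  subject_series(v, tr_seconds = tr_seconds,
                 subject_id = subject_id %||% basename(path), group = group)
}
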