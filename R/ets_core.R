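# Edge time series construction: z-scoring, co-fluctuation series, the
# edge-by-edge similarity (eFC) matrix, and the per-frame RSS trace.

#' Construct a parcellated ROI time-series object
#'
#' Wraps an ROI x T matrix of parcellated BOLD values together with the
#' repetition time and region labels, validating shape and variance.
#'
#' @param data Numeric matrix, regions in rows, frames (time points) in
#'   columns.
#' @param subject_id Subject identifier (scalar, coerced to character).
#' @param roi_labels Character vector of region labels; defaults to the
#'   matrix rownames or `roi_1 ... roi_N`.
#' @param tr_seconds Repetition time in seconds (one frame).
#' @return An object of class `roi_time_series` with elements `data`,
#'   `subject_id`, `roi_labels`, `tr_seconds`.
#' @examples
#' x <- roi_time_series(matrix(rnorm(40), 4, 10), subject_id = "s1")
#' dim(x$data)
#' @export
roi_time_series <- function(data, subject_id = "subject",
                            roi_labels = NULL, tr_seconds = 3.0) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_edgedyn("'data' must be a numeric matrix (ROI x T)")
  if (anyNA(data)) stop_edgedyn("'data' contains missing values")
  if (nrow(data) < 2L) stop_edgedyn("need at least 2 ROIs, got %d", nrow(data))
  if (ncol(data) < 3L) stop_edgedyn("need at least 3 frames, got %d", ncol(data))
  roi_labels <- roi_labels %||% rownames(data) %||%
    paste0("roi_", seq_len(nrow(data)))
  if (length(roi_labels) != nrow(data))
    stop_edgedyn("roi_labels length %d != ROI count %d",
                 length(roi_labels), nrow(data))
  if (anyDuplicated(roi_labels))
    stop_edgedyn("duplicate ROI labels: %s",
                 paste(unique(roi_labels[duplicated(roi_labels)]), collapse = ", "))
  v <- apply(data, 1L, stats::var)
  if (any(v == 0))
    stop_edgedyn("ROI(s) with zero variance: %s",
                 paste(roi_labels[v == 0], collapse = ", "))
  rownames(data) <- roi_labels
  structure(list(data = data, subject_id = as.character(subject_id)[1L],
                 roi_labels = as.character(roi_labels),
                 tr_seconds = check_positive(tr_seconds, "tr_seconds")),
            class = "roi_time_series")
}

#' @export
print.roi_time_series <- function(x, ...) {
  cat(sprintf("<roi_time_series> subject '%s': %d ROIs x %d frames, TR %.3g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Z-score each ROI time series
#'
#' Standardizes every region's series to mean 0 and unit sample standard
#' deviation (denominator T-1). With this convention the time average of an
#' edge co-fluctuation series times T/(T-1) is exactly the Pearson
#' correlation of the two raw series.
#'
#' @param series A [roi_time_series()] object or a numeric ROI x T matrix.
#' @return Object of class `zscored_series`: list with `data` (ROI x T),
#'   `roi_labels`, `tr_seconds`, `dof_convention = "sample (T-1)"`.
#' @examples
#' zscore_series(roi_time_series(matrix(rnorm(30), 3, 10)))
#' @export
zscore_series <- function(series) {
  if (is.matrix(series)) series <- roi_time_series(series)
  if (!inherits(series, "roi_time_series"))
    stop_edgedyn("'series' must be a roi_time_series or numeric matrix")
  x <- series$data
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  if (any(sdv == 0))
    stop_edgedyn("ROI(s) with zero variance: %s",
                 paste(series$roi_labels[sdv == 0], collapse = ", "))
  z <- (x - mu) / sdv
  structure(list(data = z, roi_labels = series$roi_labels,
                 subject_id = series$subject_id,
                 tr_seconds = series$tr_seconds,
                 dof_convention = "sample (T-1)"),
            class = "zscored_series")
}

#' Canonical edge index for N regions
#'
#' All unordered region pairs (i, j) with i < j in lexicographic order:
#' (1,2), (1,3), ..., (1,N), (2,3), ... This ordering is used for every
#' edge-indexed object in the package.
#'
#' @param n_roi Number of regions.
#' @return Integer matrix with E = N(N-1)/2 rows and columns `i`, `j`
#'   (1-based).
#' @examples
#' edge_index(4)
#' @export
edge_index <- function(n_roi) {
  n_roi <- check_count(n_roi, "n_roi", min = 2L)
  i <- rep.int(seq_len(n_roi - 1L), (n_roi - 1L):1L)
  j <- sequence((n_roi - 1L):1L, from = 2:n_roi)
  cbind(i = i, j = j)
}

#' Compute the edge time series (co-fluctuation series)
#'
#' For every region pair (i, j), the elementwise product
#' e_ij(t) = z_i(t) * z_j(t) of the z-scored series. A positive value means
#' the two regions deflect in the same direction at frame t, a negative
#' value in opposite directions; the time average times T/(T-1) is the
#' Pearson correlation r_ij.
#'
#' @param z A `zscored_series` (from [zscore_series()]) or a
#'   [roi_time_series()] / matrix, which is z-scored first.
#' @return Object of class `edge_time_series`: list with `data` (E x T),
#'   `edge_index` (E x 2, 1-based), `roi_labels`, `n_roi`, `tr_seconds`.
#' @examples
#' ets <- compute_ets(matrix(rnorm(40), 4, 10))
#' nrow(ets$data)  # 6 edges
#' @export
compute_ets <- function(z) {
  if (!inherits(z, "zscored_series")) z <- zscore_series(z)
  idx <- edge_index(nrow(z$data))
  e <- z$data[idx[, 1L], , drop = FALSE] * z$data[idx[, 2L], , drop = FALSE]
  rownames(e) <- paste(z$roi_labels[idx[, 1L]], z$roi_labels[idx[, 2L]],
                       sep = "--")
  structure(list(data = e, edge_index = idx, roi_labels = z$roi_labels,
                 n_roi = nrow(z$data), subject_id = z$subject_id,
                 tr_seconds = z$tr_seconds),
            class = "edge_time_series")
}

#' @export
print.edge_time_series <- function(x, ...) {
  cat(sprintf("<edge_time_series> %d edges (%d ROIs) x %d frames\n",
              nrow(x$data), x$n_roi, ncol(x$data)))
  invisible(x)
}

#' Edge-by-edge co-fluctuation (eFC) matrix
#'
#' Similarity among co-fluctuation series: entry (u, v) is the inner product
#' over time of edge series u and v, optionally normalized by the product of
#' their norms so that all entries lie in \[-1, 1\] with unit diagonal
#' (cosine normalization).
#'
#' The full matrix has E^2 entries with E = N(N-1)/2 and grows quickly;
#' computation refuses more than `max_edges` edges unless overridden.
#'
#' @param ets An `edge_time_series`.
#' @param normalize Normalize to \[-1, 1\]? Default `TRUE`.
#' @param max_edges Guard on the number of edges (default 25000).
#' @return Object of class `efc_matrix`: list with `data` (E x E symmetric)
#'   and `normalized` flag.
#' @examples
#' efc <- compute_efc(compute_ets(matrix(rnorm(50), 5, 10)))
#' range(diag(efc$data))
#' @export
compute_efc <- function(ets, normalize = TRUE, max_edges = 25000L) {
  stopifnot(inherits(ets, "edge_time_series"))
  e <- ets$data
  if (ncol(e) < 2L) stop_edgedyn("need at least 2 frames for the eFC matrix")
  if (nrow(e) > max_edges)
    stop_edgedyn(paste0("eFC matrix would have %d x %d entries; raise",
                        " 'max_edges' to override"), nrow(e), nrow(e))
  g <- tcrossprod(e)
  if (normalize) {
    nrm <- sqrt(diag(g))
    zero <- nrm == 0
    if (any(zero)) {
      warning(sprintf("%d edge series identically zero; eFC rows/cols set to 0",
                      sum(zero)), call. = FALSE)
      nrm[zero] <- 1
    }
    g <- g / outer(nrm, nrm)
    if (any(zero)) { g[zero, ] <- 0; g[, zero] <- 0 }
    diag(g)[!zero] <- 1
  }
  structure(list(data = g, normalized = isTRUE(normalize)),
            class = "efc_matrix")
}

#' Root-sum-square (RSS) co-fluctuation trace
#'
#' Global instantaneous co-fluctuation magnitude: at each frame t, the square
#' root of the sum over all edges of e_ij(t)^2. Invariant under region
#' relabeling.
#'
#' @param ets An `edge_time_series`.
#' @return Object of class `rss_trace`: list with `values` (length T,
#'   non-negative) and `tr_seconds`.
#' @examples
#' rss <- compute_rss(compute_ets(matrix(rnorm(60), 4, 15)))
#' length(rss$values)
#' @export
compute_rss <- function(ets) {
  stopifnot(inherits(ets, "edge_time_series"))
  structure(list(values = sqrt(colSums(ets$data^2)),
                 subject_id = ets$subject_id, tr_seconds = ets$tr_seconds),
            class = "rss_trace")
}
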