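# High-/low-amplitude frame networks: frame splitting by RSS rank, state
# FC estimation, and proportional thresholding over a sparsity grid.

#' Default proportional-sparsity grid
#'
#' `{0.05, 0.10, ..., 0.50}`, ten thresholds in steps of 0.05.
#' @return Numeric vector of length 10.
#' @export
default_sparsity_grid <- function() seq(0.05, 0.50, by = 0.05)

#' Split frames into high- and low-amplitude sets by RSS rank
#'
#' Frames are ranked by RSS from high to low; the top `fraction` (default
#' 10%, k = ceiling(fraction * T) frames) form the high-amplitude set and
#' the remainder the low-amplitude set. Ties at the cutoff resolve to the
#' earlier frame.
#'
#' @param rss An `rss_trace` or numeric vector.
#' @param fraction Fraction of frames in the high-amplitude set, in (0, 1).
#' @return List of two `frame_mask` objects, `high` and `low`, each with
#'   `state`, logical `keep` (length T) and `fraction`.
#' @examples
#' m <- split_frames(c(1, 9, 2, 8, 3, 7, 4, 6, 5, 0), fraction = 0.2)
#' which(m$high$keep)
#' @export
split_frames <- function(rss, fraction = 0.10) {
  v <- if (inherits(rss, "rss_trace")) rss$values else as.numeric(rss)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop_edgedyn("'fraction' must be in (0, 1)")
  n <- length(v)
  k <- as.integer(ceiling(fraction * n))
  if (n < 1 / fraction)
    stop_edgedyn("trace too short: %d frames for fraction %.3g", n, fraction)
  ord <- order(-v, seq_len(n))   # descending RSS, earlier frame wins ties
  keep_high <- logical(n)
  keep_high[ord[seq_len(k)]] <- TRUE
  list(high = structure(list(state = "high", keep = keep_high,
                             fraction = fraction), class = "frame_mask"),
       low = structure(list(state = "low", keep = !keep_high,
                            fraction = 1 - fraction), class = "frame_mask"))
}

#' State-specific functional connectivity matrix
#'
#' Builds an N x N FC matrix from the frames retained by a mask, either as
#' the mean co-fluctuation over retained frames (default; the time-mean of
#' the edge time series restricted to the mask) or as the Pearson
#' correlation of the raw ROI series restricted to those frames.
#'
#' @param ets An `edge_time_series`.
#' @param mask A `frame_mask` from [split_frames()], or a logical vector of
#'   length T.
#' @param method `"mean_cofluctuation"` (default) or `"frame_pearson"`.
#' @param raw Raw [roi_time_series()]; required for `"frame_pearson"`.
#' @return Object of class `frame_fc`: list with `state`, `fc` (N x N
#'   symmetric, zero diagonal), `method`, `n_frames`, `roi_labels`,
#'   `edge_values` (length-E vector in canonical edge order).
#' @export
build_state_fc <- function(ets, mask,
                           method = c("mean_cofluctuation", "frame_pearson"),
                           raw = NULL) {
  stopifnot(inherits(ets, "edge_time_series"))
  method <- match.arg(method)
  state <- "custom"
  if (inherits(mask, "frame_mask")) { state <- mask$state; mask <- mask$keep }
  mask <- as.logical(mask)
  if (length(mask) != ncol(ets$data))
    stop_edgedyn("mask length %d != frame count %d", length(mask), ncol(ets$data))
  m <- sum(mask)
  need <- if (method == "frame_pearson") 3L else 2L
  if (m < need)
    stop_edgedyn("only %d retained frames; need >= %d for method '%s'",
                 m, need, method)
  n <- ets$n_roi
  if (method == "mean_cofluctuation") {
    w <- unname(rowMeans(ets$data[, mask, drop = FALSE]))
  } else {
    if (is.null(raw))
      stop_edgedyn("'raw' roi_time_series required for method 'frame_pearson'")
    cm <- stats::cor(t(raw$data[, mask, drop = FALSE]))
    idx <- ets$edge_index
    w <- cm[cbind(idx[, 1L], idx[, 2L])]
  }
  fc <- matrix(0, n, n, dimnames = list(ets$roi_labels, ets$roi_labels))
  idx <- ets$edge_index
  fc[cbind(idx[, 1L], idx[, 2L])] <- w
  fc[cbind(idx[, 2L], idx[, 1L])] <- w
  structure(list(state = state, fc = fc, method = method, n_frames = m,
                 roi_labels = ets$roi_labels, edge_values = w,
                 edge_index = idx),
            class = "frame_fc")
}

#' Proportional thresholding over a sparsity grid
#'
#' For each sparsity S, keeps the `round(S * E)` largest off-diagonal values
#' (signed, descending; exact .5 rounds away from zero; ties broken by
#' canonical edge order) and binarizes. Graphs are nested across the grid.
#'
#' @param fc A `frame_fc` object or symmetric numeric matrix.
#' @param sparsity_grid Sparsities in (0, 1); default
#'   [default_sparsity_grid()].
#' @param rank_by `"signed"` (default: most positive first) or
#'   `"absolute"`.
#' @return Object of class `graph_set`: list with `graphs` (named list of
#'   N x N binary adjacency matrices, one per S), `sparsity_grid`,
#'   `edge_index`, `rank_order` (edge ranking used).
#' @export
threshold_proportional <- function(fc, sparsity_grid = default_sparsity_grid(),
                                   rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  if (inherits(fc, "frame_fc")) {
    w <- fc$edge_values; idx <- fc$edge_index; labels <- fc$roi_labels
    n <- length(labels)
  } else {
    if (!is.matrix(fc) || nrow(fc) != ncol(fc))
      stop_edgedyn("'fc' must be a square matrix or frame_fc")
    n <- nrow(fc)
    idx <- edge_index(n)
    w <- fc[cbind(idx[, 1L], idx[, 2L])]
    labels <- rownames(fc) %||% paste0("roi_", seq_len(n))
  }
  if (any(sparsity_grid <= 0 | sparsity_grid >= 1))
    stop_edgedyn("sparsity values must lie in (0, 1)")
  e_total <- length(w)
  key <- if (rank_by == "absolute") -abs(w) else -w
  ord <- order(key, seq_len(e_total))  # ties by canonical edge order
  graphs <- vector("list", length(sparsity_grid))
  names(graphs) <- formatC(sparsity_grid, format = "f", digits = 2)
  for (s in seq_along(sparsity_grid)) {
    k <- as.integer(round_half_away(sparsity_grid[s] * e_total))
    adj <- matrix(0L, n, n, dimnames = list(labels, labels))
    if (k > 0L) {
      sel <- ord[seq_len(min(k, e_total))]
      adj[cbind(idx[sel, 1L], idx[sel, 2L])] <- 1L
      adj[cbind(idx[sel, 2L], idx[sel, 1L])] <- 1L
    }
    graphs[[s]] <- adj
  }
  structure(list(graphs = graphs, sparsity_grid = as.numeric(sparsity_grid),
                 edge_index = idx, rank_order = ord, rank_by = rank_by),
            class = "graph_set")
}
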