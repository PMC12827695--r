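# Binary graph metrics: global (Cp, Lp, Eglob, Eloc, and gamma/lambda/sigma
# against degree-preserving rewired nulls) and nodal (Ne, Dc, Bc), plus AUC
# aggregation over the sparsity grid.

as_adjacency <- function(adj) {
  if (inherits(adj, "frame_fc")) stop_edgedyn("pass a binary adjacency, not frame_fc")
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop_edgedyn("'adj' must be a square matrix")
  a <- (adj != 0) * 1L
  diag(a) <- 0L
  if (!isTRUE(all.equal(a, t(a), check.attributes = FALSE)))
    stop_edgedyn("'adj' must be symmetric")
  storage.mode(a) <- "integer"
  a
}

graph_from_adj <- function(a)
  igraph::graph_from_adjacency_matrix(a, mode = "undirected", diag = FALSE)

# mean inverse shortest-path length over distinct pairs (1/Inf = 0)
eglob_from_dist <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global metrics of a binary undirected graph
#'
#' Clustering coefficient Cp (mean over nodes of 2 * triangles / k(k-1),
#' zero for degree < 2), characteristic path length Lp (mean shortest-path
#' length over reachable distinct pairs; the fraction of unreachable pairs
#' is reported), global efficiency Eglob (mean of inverse distances, with
#' 1/Inf = 0) and local efficiency Eloc (mean over nodes of the global
#' efficiency of the neighbor-induced subgraph, zero for degree < 2).
#'
#' @param adj Square binary adjacency matrix (symmetric, zero diagonal).
#' @return Named list: `Cp`, `Lp`, `Eglob`, `Eloc`, `frac_unreachable`.
#' @examples
#' global_metrics(1 - diag(4))  # K4: all metrics 1
#' @export
global_metrics <- function(adj) {
  a <- as_adjacency(adj)
  n <- nrow(a)
  k <- rowSums(a)
  if (sum(a) == 0) {
    warning("empty graph: all global metrics 0", call. = FALSE)
    return(list(Cp = 0, Lp = 0, Eglob = 0, Eloc = 0, frac_unreachable = 1))
  }
  tri <- diag(a %*% a %*% a) / 2
  cp_i <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  d <- igraph::distances(graph_from_adj(a))
  off <- row(d) != col(d)
  reach <- off & is.finite(d)
  lp <- if (any(reach)) mean(d[reach]) else 0
  eloc_i <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1L)
    if (length(nb) < 2L) return(0)
    sub <- a[nb, nb, drop = FALSE]
    if (sum(sub) == 0) return(0)
    eglob_from_dist(igraph::distances(graph_from_adj(sub)))
  }, numeric(1))
  list(Cp = mean(cp_i), Lp = lp, Eglob = eglob_from_dist(d),
       Eloc = mean(eloc_i),
       frac_unreachable = sum(off & is.infinite(d)) / sum(off))
}

#' Nodal metrics of a binary undirected graph
#'
#' Degree centrality Dc, unnormalized shortest-path betweenness centrality
#' Bc (each unordered pair counted once, fractional credit across
#' equal-length shortest paths), and nodal efficiency
#' Ne(i) = mean over j != i of 1/d(i, j).
#'
#' @param adj Square binary adjacency matrix.
#' @return data.frame with columns `roi`, `Dc`, `Bc`, `Ne`.
#' @examples
#' a <- matrix(0, 4, 4); a[cbind(1:3, 2:4)] <- 1; a <- a + t(a)
#' nodal_metrics(a)  # path graph: Bc = 0, 2, 2, 0
#' @export
nodal_metrics <- function(adj) {
  a <- as_adjacency(adj)
  n <- nrow(a)
  labels <- rownames(a) %||% paste0("roi_", seq_len(n))
  g <- graph_from_adj(a)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  data.frame(roi = labels,
             Dc = rowSums(a),
             Bc = as.numeric(igraph::betweenness(g, directed = FALSE,
                                                 normalized = FALSE)),
             Ne = rowSums(inv) / (n - 1),
             stringsAsFactors = FALSE)
}

# One degree-preserving randomization by Maslov-Sneppen double-edge swaps.
# `n_swaps` accepted swaps are attempted, giving up after 100 * n_swaps
# tries (sparse or degenerate graphs may admit few swaps).
rewire_degree_preserving <- function(adj, n_swaps) {
  a <- as_adjacency(adj)
  idx <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  e <- nrow(idx)
  if (e < 2L) return(a)
  accepted <- 0L
  attempts <- 0L
  max_attempts <- 100L * n_swaps
  while (accepted < n_swaps && attempts < max_attempts) {
    attempts <- attempts + 1L
    pick <- sample.int(e, 2L)
    p <- idx[pick[1L], ]; q <- idx[pick[2L], ]
    if (stats::runif(1) < 0.5) { x1 <- p[1L]; y1 <- q[2L]; x2 <- q[1L]; y2 <- p[2L] }
    else                       { x1 <- p[1L]; y1 <- q[1L]; x2 <- p[2L]; y2 <- q[2L] }
    if (x1 == y1 || x2 == y2) next
    if (a[x1, y1] == 1L || a[x2, y2] == 1L) next
    a[p[1L], p[2L]] <- 0L; a[p[2L], p[1L]] <- 0L
    a[q[1L], q[2L]] <- 0L; a[q[2L], q[1L]] <- 0L
    a[x1, y1] <- 1L; a[y1, x1] <- 1L
    a[x2, y2] <- 1L; a[y2, x2] <- 1L
    idx[pick[1L], ] <- c(min(x1, y1), max(x1, y1))
    idx[pick[2L], ] <- c(min(x2, y2), max(x2, y2))
    accepted <- accepted + 1L
  }
  if (accepted == 0L)
    warning("no degree-preserving swap possible; null equals original",
            call. = FALSE)
  a
}

#' Small-world indices against degree-preserving rewired nulls
#'
#' gamma = Cp / mean(Cp of nulls), lambda = Lp / mean(Lp of nulls),
#' sigma = gamma / lambda. Nulls are Maslov-Sneppen double-edge-swap
#' randomizations preserving the degree sequence exactly
#' (`rewires_per_edge * E` accepted swaps each, rejecting self-loops and
#' multi-edges).
#'
#' @param adj Square binary adjacency matrix with at least 2 edges.
#' @param n_nulls Number of null graphs (default 100).
#' @param rewires_per_edge Accepted swaps per edge per null (default 10).
#' @param seed Optional RNG seed (restores caller RNG state).
#' @return Named list: `gamma`, `lambda`, `sigma`, `null_cp_mean`,
#'   `null_lp_mean`, `n_nulls`.
#' @export
null_normalize <- function(adj, n_nulls = 100L, rewires_per_edge = 10L,
                           seed = NULL) {
  a <- as_adjacency(adj)
  e <- sum(a) / 2
  if (e < 2) stop_edgedyn("null normalization needs at least 2 edges")
  n_nulls <- check_count(n_nulls, "n_nulls")
  obs <- global_metrics(a)
  n_swaps <- as.integer(rewires_per_edge * e)
  nulls <- with_seed(seed, lapply(seq_len(n_nulls), function(r) {
    gm <- global_metrics(rewire_degree_preserving(a, n_swaps))
    c(gm$Cp, gm$Lp)
  }))
  nulls <- do.call(rbind, nulls)
  ncp <- mean(nulls[, 1L]); nlp <- mean(nulls[, 2L])
  # a degenerate 0/0 (e.g. triangle-free graph whose nulls are itself)
  # normalizes to 1; a nonzero observed value over a zero null mean is NA
  ratio1 <- function(obs_v, null_v) {
    if (null_v > 0) return(obs_v / null_v)
    if (obs_v == null_v) 1 else NA_real_
  }
  gamma <- ratio1(obs$Cp, ncp)
  lambda <- ratio1(obs$Lp, nlp)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       null_cp_mean = ncp, null_lp_mean = nlp, n_nulls = n_nulls)
}

#' Trapezoidal area under a metric across the sparsity grid
#'
#' @param values Metric values, one per grid point.
#' @param grid Sorted sparsity grid of the same length.
#' @return Scalar trapezoidal integral.
#' @examples
#' auc_over_grid(c(0, 1), c(0, 1))  # 0.5
#' @export
auc_over_grid <- function(values, grid) {
  if (length(values) != length(grid))
    stop_edgedyn("values (%d) and grid (%d) differ in length",
                 length(values), length(grid))
  if (is.unsorted(grid)) stop_edgedyn("grid must be sorted increasing")
  if (length(grid) < 2L) stop_edgedyn("grid needs at least 2 points")
  sum(diff(grid) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Global and nodal metrics across a sparsity grid, with AUC
#'
#' Computes [global_metrics()], [null_normalize()] and [nodal_metrics()]
#' on each thresholded graph of a [threshold_proportional()] result and
#' appends trapezoidal AUC summaries.
#'
#' @param gs A `graph_set`.
#' @param n_nulls Nulls per graph for gamma/lambda/sigma (default 100;
#'   set 0 to skip small-world normalization).
#' @param rewires_per_edge Accepted swaps per edge per null.
#' @param seed Optional seed for the null ensembles.
#' @return List with `global` (data.frame, one row per S plus an `AUC`
#'   row; columns sparsity, Cp, Lp, gamma, lambda, sigma, Eglob, Eloc) and
#'   `nodal` (long data.frame: sparsity, roi, Dc, Bc, Ne, plus AUC rows).
#' @export
metric_table <- function(gs, n_nulls = 100L, rewires_per_edge = 10L,
                         seed = NULL) {
  stopifnot(inherits(gs, "graph_set"))
  grid <- gs$sparsity_grid
  glob <- vector("list", length(grid))
  nod <- vector("list", length(grid))
  seeds <- if (is.null(seed)) rep(list(NULL), length(grid))
           else as.list(seed + seq_along(grid))
  for (s in seq_along(grid)) {
    a <- gs$graphs[[s]]
    gm <- global_metrics(a)
    sw <- if (n_nulls > 0 && sum(a) / 2 >= 2)
      null_normalize(a, n_nulls, rewires_per_edge, seed = seeds[[s]])
    else list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
    glob[[s]] <- data.frame(sparsity = grid[s], Cp = gm$Cp, Lp = gm$Lp,
                            gamma = sw$gamma, lambda = sw$lambda,
                            sigma = sw$sigma, Eglob = gm$Eglob,
                            Eloc = gm$Eloc)
    nm <- nodal_metrics(a)
    nm$sparsity <- grid[s]
    nod[[s]] <- nm
  }
  glob <- do.call(rbind, glob)
  auc_row <- data.frame(sparsity = NA_real_, t(vapply(
    c("Cp", "Lp", "gamma", "lambda", "sigma", "Eglob", "Eloc"),
    function(m) auc_over_grid(glob[[m]], grid), numeric(1))))
  names(auc_row) <- names(glob)
  glob_out <- rbind(cbind(summary = "per_s", glob),
                    cbind(summary = "AUC", auc_row))
  nod <- do.call(rbind, nod)
  nod_auc <- do.call(rbind, lapply(split(nod, nod$roi), function(df) {
    df <- df[order(df$sparsity), ]
    data.frame(roi = df$roi[1L],
               Dc = auc_over_grid(df$Dc, grid),
               Bc = auc_over_grid(df$Bc, grid),
               Ne = auc_over_grid(df$Ne, grid),
               sparsity = NA_real_, stringsAsFactors = FALSE)
  }))
  nod_out <- rbind(cbind(summary = "per_s", nod),
                   cbind(summary = "AUC", nod_auc))
  rownames(glob_out) <- rownames(nod_out) <- NULL
  list(global = glob_out, nodal = nod_out)
}
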