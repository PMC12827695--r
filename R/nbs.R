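# Network-based statistic: edgewise two-sample t statistics, maximal
# connected suprathreshold components, and max-component-size permutation
# inference.

#' NBS configuration
#'
#' @param t_threshold Primary t threshold on edgewise statistics
#'   (default 2.105).
#' @param n_permutations Number of label permutations (default 5000).
#' @param alpha Component-level significance threshold (default 0.05).
#' @param seed Optional RNG seed.
#' @param tail `"greater"` (default; group A > group B), `"less"`, or
#'   `"both"`.
#' @return List of class `nbs_config`.
#' @export
nbs_config <- function(t_threshold = 2.105, n_permutations = 5000L,
                       alpha = 0.05, seed = NULL,
                       tail = c("greater", "less", "both")) {
  tail <- match.arg(tail)
  if (!is.numeric(t_threshold) || t_threshold <= 0)
    stop_edgedyn("'t_threshold' must be positive")
  n_permutations <- check_count(n_permutations, "n_permutations", min = 100L)
  if (alpha <= 0 || alpha >= 1) stop_edgedyn("'alpha' must be in (0, 1)")
  structure(list(t_threshold = t_threshold, n_permutations = n_permutations,
                 alpha = alpha, seed = seed, tail = tail),
            class = "nbs_config")
}

# column-wise pooled-variance two-sample t for rows `ga` (group A) vs the
# rest of `x` (subjects x edges); vectorized over edges.
pooled_t_cols <- function(x, ga) {
  na <- length(ga); nb <- nrow(x) - na
  xa <- x[ga, , drop = FALSE]; xb <- x[-ga, , drop = FALSE]
  ma <- colMeans(xa); mb <- colMeans(xb)
  ssa <- colSums(xa^2) - na * ma^2
  ssb <- colSums(xb^2) - nb * mb^2
  sp2 <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  (ma - mb) / se  # NaN where pooled variance is 0; callers decide
}

#' Edgewise two-sample t statistics
#'
#' Pooled-variance Student t (group A minus group B) for every edge,
#' df = n_A + n_B - 2. Edges with zero pooled variance get t = 0 with a
#' warning.
#'
#' @param fc_stack_a,fc_stack_b Numeric matrices, subjects x edges, with
#'   matching edge columns (e.g. rows of per-subject `edge_values` from
#'   [build_state_fc()]).
#' @return Numeric vector of t statistics, one per edge.
#' @export
edge_group_t <- function(fc_stack_a, fc_stack_b) {
  if (!is.matrix(fc_stack_a) || !is.matrix(fc_stack_b) ||
      ncol(fc_stack_a) != ncol(fc_stack_b))
    stop_edgedyn("fc stacks must be matrices with matching edge columns")
  if (nrow(fc_stack_a) < 2L || nrow(fc_stack_b) < 2L)
    stop_edgedyn("need at least 2 subjects per group")
  x <- rbind(fc_stack_a, fc_stack_b)
  t <- pooled_t_cols(x, seq_len(nrow(fc_stack_a)))
  if (any(!is.finite(t))) {
    warning("edges with zero pooled variance set to t = 0", call. = FALSE)
    t[!is.finite(t)] <- 0
  }
  t
}

suprathreshold <- function(t, threshold, tail) {
  switch(tail,
         greater = t > threshold,
         less = t < -threshold,
         both = abs(t) > threshold)
}

# connected components over a set of edges, via union-find on node ids;
# avoids igraph overhead inside the permutation loop.
components_from_edges <- function(ei, ej) {
  nodes <- sort(unique(c(ei, ej)))
  parent <- seq_along(nodes)
  id <- match(ei, nodes); jd <- match(ej, nodes)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_along(id)) {
    ri <- find(id[k]); rj <- find(jd[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comp_of_edge <- roots[id]  # both ends share a root
  split(seq_along(id), comp_of_edge)
}

#' Maximal connected components of suprathreshold edges
#'
#' Builds the graph of edges whose t statistic exceeds the threshold in the
#' chosen tail and returns its connected components, sized by edge count
#' (NBS "extent").
#'
#' @param t_values Edgewise t statistics in canonical edge order.
#' @param edge_idx E x 2 integer matrix of node pairs (see [edge_index()]).
#' @param t_threshold Primary threshold.
#' @param tail `"greater"`, `"less"`, or `"both"`.
#' @return List of components, each a list with sorted integer `nodes`,
#'   `edges` (matrix of node pairs), `size` (edge count); ordered by
#'   decreasing size then smallest node id. Empty list when no edge passes.
#' @export
extract_components <- function(t_values, edge_idx, t_threshold = 2.105,
                               tail = c("greater", "less", "both")) {
  tail <- match.arg(tail)
  keep <- which(suprathreshold(t_values, t_threshold, tail))
  if (length(keep) == 0L) return(list())
  ei <- edge_idx[keep, 1L]; ej <- edge_idx[keep, 2L]
  comps <- components_from_edges(ei, ej)
  out <- lapply(comps, function(rows) {
    list(nodes = sort(unique(c(ei[rows], ej[rows]))),
         edges = cbind(i = ei[rows], j = ej[rows]),
         edge_rows = keep[rows],
         size = length(rows))
  })
  out[order(-vapply(out, `[[`, integer(1), "size"),
            vapply(out, function(c) c$nodes[1L], integer(1)))]
}

#' Network-based statistic permutation test
#'
#' Computes observed suprathreshold components between two groups of
#' edgewise FC values, then permutes group labels to build the null
#' distribution of the maximal component size (edge count). Component
#' p-values use the +1 correction:
#' p = (1 + #\{null max >= observed size\}) / (n_permutations + 1).
#'
#' @param fc_stack_a,fc_stack_b Subjects x edges matrices (group A, B).
#' @param edge_idx E x 2 node-pair matrix ([edge_index()]).
#' @param config An [nbs_config()].
#' @return Object of class `nbs_result`: `edge_t`, `components` (each with
#'   `p_value` added), `max_component_null` (integer, length
#'   n_permutations), `config`, `n_a`, `n_b`.
#' @export
nbs_permutation <- function(fc_stack_a, fc_stack_b, edge_idx,
                            config = nbs_config()) {
  stopifnot(inherits(config, "nbs_config"))
  t_obs <- edge_group_t(fc_stack_a, fc_stack_b)
  if (length(t_obs) != nrow(edge_idx))
    stop_edgedyn("edge_idx rows (%d) != edge count (%d)",
                 nrow(edge_idx), length(t_obs))
  comps <- extract_components(t_obs, edge_idx, config$t_threshold, config$tail)
  na <- nrow(fc_stack_a); nb <- nrow(fc_stack_b)
  n <- na + nb
  if (choose(n, na) < config$n_permutations)
    warning(sprintf("only %d distinct label splits for %d requested permutations",
                    choose(n, na), config$n_permutations), call. = FALSE)
  x <- rbind(fc_stack_a, fc_stack_b)
  null_max <- with_seed(config$seed, {
    vapply(seq_len(config$n_permutations), function(p) {
      ga <- sample.int(n, na)
      tp <- pooled_t_cols(x, ga)
      tp[!is.finite(tp)] <- 0
      keep <- which(suprathreshold(tp, config$t_threshold, config$tail))
      if (length(keep) == 0L) return(0L)
      sizes <- lengths(components_from_edges(edge_idx[keep, 1L],
                                             edge_idx[keep, 2L]))
      max(sizes)
    }, integer(1))
  })
  for (k in seq_along(comps))
    comps[[k]]$p_value <-
      (1 + sum(null_max >= comps[[k]]$size)) / (config$n_permutations + 1)
  structure(list(edge_t = t_obs, components = comps,
                 max_component_null = null_max, config = config,
                 n_a = na, n_b = nb),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %d edges, %d component(s); tail '%s', T > %.3f, %d permutations\n",
              length(x$edge_t), length(x$components), x$config$tail,
              x$config$t_threshold, x$config$n_permutations))
  for (c in x$components)
    cat(sprintf("  component: %d nodes, %d edges, p = %.4g\n",
                length(c$nodes), c$size, c$p_value))
  invisible(x)
}
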