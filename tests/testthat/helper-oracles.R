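# Independent brute-force oracles. These re-derive quantities from first
# principles (BFS, path enumeration, verbatim rules) and must stay free of
# any package internals they are used to check.

# all-pairs shortest path lengths by BFS
bf_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    seen <- rep(FALSE, n); seen[s] <- TRUE
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(a[u, ] == 1)) {
          if (!seen[v]) { seen[v] <- TRUE; d[s, v] <- depth; nxt <- c(nxt, v) }
        }
      }
      frontier <- nxt
    }
  }
  d
}

# all shortest paths s -> t as lists of vertices (exponential; n <= 8 only)
bf_shortest_paths <- function(a, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  out <- list()
  for (u in which(a[s, ] == 1)) {
    if (d[u, t] == d[s, t] - 1) {
      for (p in bf_shortest_paths(a, d, u, t)) out[[length(out) + 1]] <- c(s, p)
    }
  }
  out
}

# pair-summed betweenness with fractional credit (each unordered pair once)
bf_betweenness <- function(a) {
  n <- nrow(a)
  d <- bf_distances(a)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- bf_shortest_paths(a, d, s, t)
    if (!length(paths)) next
    cnt <- numeric(n)
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      cnt[interior] <- cnt[interior] + 1
    }
    bc <- bc + cnt / length(paths)
  }
  bc
}

bf_global <- function(a) {
  n <- nrow(a)
  d <- bf_distances(a)
  k <- rowSums(a)
  tri <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    sum(a[nb, nb]) / 2
  }, numeric(1))
  cp <- mean(ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0))
  off <- row(d) != col(d)
  lp <- if (any(off & is.finite(d))) mean(d[off & is.finite(d)]) else 0
  inv <- ifelse(is.finite(d) & off, 1 / d, 0)
  eglob <- sum(inv) / (n * (n - 1))
  eloc <- mean(vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- a[nb, nb, drop = FALSE]
    ds <- bf_distances(sub)
    m <- nrow(sub)
    offs <- row(ds) != col(ds)
    sum(ifelse(is.finite(ds) & offs, 1 / ds, 0)) / (m * (m - 1))
  }, numeric(1)))
  ne <- {
    inv_rows <- ifelse(is.finite(d) & off, 1 / d, 0)
    rowSums(inv_rows) / (n - 1)
  }
  list(Cp = cp, Lp = lp, Eglob = eglob, Eloc = eloc, Ne = ne)
}

# Erdos-Renyi adjacency (possibly disconnected / empty)
random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a + t(a)
}

# verbatim scan of the trough rule
bf_troughs <- function(v) {
  out <- integer(0)
  for (t in 2:(length(v) - 1))
    if (v[t] < v[t - 1] && v[t] < v[t + 1]) out <- c(out, t)
  out
}

# verbatim peak rule: argmax strictly between consecutive troughs, earliest tie
bf_peaks <- function(v, troughs) {
  frames <- integer(0)
  if (length(troughs) < 2) return(list(frames = frames, amplitudes = numeric(0)))
  for (m in seq_len(length(troughs) - 1)) {
    best <- -Inf; best_f <- NA_integer_
    for (f in (troughs[m] + 1):(troughs[m + 1] - 1)) {
      if (v[f] > best) { best <- v[f]; best_f <- f }
    }
    frames <- c(frames, best_f)
  }
  list(frames = frames, amplitudes = v[frames])
}

# small ring lattice: each node connected to k/2 neighbours on each side
ring_lattice <- function(n, k) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i - 1 + s) %% n) + 1
    a[i, j] <- a[j, i] <- 1L
  }
  a
}
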