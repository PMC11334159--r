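# Fixture builders and independent brute-force oracles. Oracles are written
# as plain double loops / direct formulas, deliberately independent of the
# package's vectorized implementations.

make_packing <- function(centers, volumes = NULL, radii = NULL) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (is.null(volumes)) {
    if (is.null(radii)) radii <- rep(1, n)
    volumes <- 4 / 3 * pi * radii^3
  }
  packing(data.frame(
    id = sprintf("id%02d", seq_len(n)),
    acronym = sprintf("R%02d", seq_len(n)),
    x_mm = centers[, 1L], y_mm = centers[, 2L], z_mm = centers[, 3L],
    volume_mm3 = volumes
  ))
}

random_packing <- function(n, seed, span = 6, volume_range = c(0.1, 3)) {
  set.seed(seed)
  make_packing(matrix(runif(3 * n, 0, span), n, 3),
               volumes = runif(n, volume_range[1], volume_range[2]))
}

random_adjacency <- function(n, seed, density = 0.5, labels = NULL) {
  set.seed(seed + 1000)
  a <- matrix(rexp(n * n) * (runif(n * n) < density), n, n)
  diag(a) <- 0
  if (!is.null(labels)) dimnames(a) <- list(labels, labels)
  a
}

# --- oracles ---------------------------------------------------------------

oracle_distances <- function(pk) {
  x <- as.data.frame(pk)[, c("x_mm", "y_mm", "z_mm")]
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  }
  d
}

oracle_packing_stats <- function(pk) {
  d <- oracle_distances(pk)
  r <- pk$radius_mm
  overlaps <- c(); gaps <- c(); n <- nrow(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sep <- d[i, j] - (r[i] + r[j])
    if (sep < 0) overlaps <- c(overlaps, -sep)
    if (sep > 0) gaps <- c(gaps, sep)
  }
  list(total_overlap = sum(overlaps),
       mean_overlap = if (length(overlaps)) mean(overlaps) else 0,
       max_overlap = if (length(overlaps)) max(overlaps) else 0,
       total_gap = sum(gaps),
       mean_gap = if (length(gaps)) mean(gaps) else 0,
       max_gap = if (length(gaps)) max(gaps) else 0,
       n_overlapping_pairs = length(overlaps),
       n_pairs = n * (n - 1) / 2)
}

oracle_efficiency <- function(pk, adj) {
  d <- oracle_distances(pk)
  s <- 0
  for (i in seq_len(nrow(d))) for (j in seq_len(nrow(d))) {
    if (i != j && adj[i, j] > 0) s <- s + adj[i, j] / d[i, j]
  }
  s
}

oracle_wiring_cost <- function(pk) {
  d <- oracle_distances(pk)
  w <- 0
  for (i in seq_len(nrow(d) - 1)) for (j in (i + 1):nrow(d)) w <- w + d[i, j]
  w
}

oracle_percentile <- function(observed, values) {
  100 * length(which(sort(values) < observed)) / length(values)
}

oracle_zscore <- function(observed, values) {
  m <- sum(values) / length(values)
  v <- sum((values - m)^2) / (length(values) - 1)
  (observed - m) / sqrt(v)
}

# BFS shortest paths on a 0/1 directed adjacency, then mean inverse length.
oracle_global_efficiency <- function(a) {
  n <- nrow(a)
  total <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (v in which(a[u, ] == 1)) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    for (t in seq_len(n)) {
      if (t != s && is.finite(dist[t])) total <- total + 1 / dist[t]
    }
  }
  total / (n * (n - 1))
}

# Triangle-counting local clustering on a symmetric 0/1 matrix, degree-<2
# nodes contributing 0, averaged over all nodes.
oracle_clustering <- function(a) {
  a <- ((a + t(a)) > 0) * 1
  diag(a) <- 0
  n <- nrow(a)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (p in seq_along(nb)) for (q in seq_along(nb)) {
      if (p < q && a[nb[p], nb[q]] == 1) links <- links + 1
    }
    cc[v] <- 2 * links / (k * (k - 1))
  }
  mean(cc)
}
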