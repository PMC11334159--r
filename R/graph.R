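#' Binarize a weighted adjacency matrix
#'
#' @param adjacency Square non-negative matrix of projection volumes.
#' @param threshold Weights strictly greater than this become edges
#'   (default 0: any positive projection volume is an edge).
#' @return An object of class `binary_graph`: list with `adjacency`
#'   (0/1 matrix, zero diagonal) and `directed = TRUE`.
#' @export
binarize <- function(adjacency, threshold = 0) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("matrix must be square", call. = FALSE)
  if (any(adjacency < 0)) stop("weights must be non-negative", call. = FALSE)
  a <- (adjacency > threshold) * 1L
  diag(a) <- 0L
  structure(list(adjacency = a, directed = TRUE), class = "binary_graph")
}

# Internal: igraph object from a binary_graph.
as_igraph <- function(graph, symmetrize = FALSE) {
  a <- graph$adjacency
  if (symmetrize) {
    a <- ((a + t(a)) > 0) * 1L
    igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  } else {
    igraph::graph_from_adjacency_matrix(a, mode = "directed")
  }
}

#' Global efficiency of a binary graph
#'
#' Mean inverse shortest-path length over ordered node pairs,
#' `(1/(n(n-1))) * sum 1/l_ij`, with `1/Inf = 0` for disconnected pairs.
#' Computed on the directed graph.
#'
#' @param graph A [binarize()]d graph (n >= 2).
#' @return A number in \[0, 1\].
#' @export
global_efficiency <- function(graph) {
  n <- nrow(graph$adjacency)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  l <- igraph::distances(as_igraph(graph), mode = "out")
  inv <- 1 / l
  diag(inv) <- 0
  inv[is.infinite(l)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Mean local clustering coefficient
#'
#' Computed on the symmetrized graph: the average over all nodes of the
#' local clustering coefficient, with nodes of degree < 2 contributing 0.
#'
#' @param graph A [binarize()]d graph (n >= 3).
#' @return A number in \[0, 1\].
#' @export
clustering_coefficient <- function(graph) {
  if (nrow(graph$adjacency) < 3L) stop("need at least 3 nodes", call. = FALSE)
  g <- as_igraph(graph, symmetrize = TRUE)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Small-world index against degree-preserving rewired nulls
#'
#' sigma = (C / C_rand) / (L / L_rand) on the symmetrized graph, where C is
#' the mean local clustering coefficient, L the characteristic path length,
#' and the null values are means over `n_random` degree-preserving
#' rewirings (double-edge swaps, 10 x |E| swaps per sample). sigma > 1
#' indicates small-world structure. The symmetrized graph must be
#' connected; otherwise a report with `sigma = NA` and
#' `connected = FALSE` is returned rather than an error.
#'
#' @param graph A [binarize()]d graph.
#' @param n_random Size of the rewired null ensemble (default 100).
#' @param seed Integer seed; results are reproducible.
#' @return A list of class `small_world_report`: `sigma`, `connected`, `C`,
#'   `L`, `C_rand_mean`, `C_rand_sd`, `L_rand_mean`, `L_rand_sd`,
#'   `n_random`.
#' @export
small_world_index <- function(graph, n_random = 100L, seed = 1L) {
  g <- as_igraph(graph, symmetrize = TRUE)
  if (!igraph::is_connected(g)) {
    return(structure(list(sigma = NA_real_, connected = FALSE,
                          C = NA_real_, L = NA_real_,
                          C_rand_mean = NA_real_, C_rand_sd = NA_real_,
                          L_rand_mean = NA_real_, L_rand_sd = NA_real_,
                          n_random = as.integer(n_random)),
                     class = "small_world_report"))
  }
  C <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  L <- igraph::mean_distance(g, directed = FALSE)
  m <- igraph::ecount(g)
  c_rand <- numeric(n_random)
  l_rand <- numeric(n_random)
  run <- function() {
    for (k in seq_len(n_random)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10L * m))
      c_rand[k] <<- igraph::transitivity(gr, type = "localaverage",
                                         isolates = "zero")
      l_rand[k] <<- igraph::mean_distance(gr, directed = FALSE)
    }
  }
  with_isolated_seed(seed, run)
  sigma <- (C / mean(c_rand)) / (L / mean(l_rand))
  structure(list(sigma = sigma, connected = TRUE, C = C, L = L,
                 C_rand_mean = mean(c_rand), C_rand_sd = stats::sd(c_rand),
                 L_rand_mean = mean(l_rand), L_rand_sd = stats::sd(l_rand),
                 n_random = as.integer(n_random)),
            class = "small_world_report")
}

#' @export
print.small_world_report <- function(x, ...) {
  if (!x$connected) {
    cat("Small-world index undefined: symmetrized graph is disconnected\n")
  } else {
    cat(sprintf(
      "Small-world index sigma = %.3g (C = %.3g vs %.3g +/- %.2g; L = %.3g vs %.3g +/- %.2g; %d rewired nulls)\n",
      x$sigma, x$C, x$C_rand_mean, x$C_rand_sd, x$L, x$L_rand_mean,
      x$L_rand_sd, x$n_random))
  }
  invisible(x)
}

# Internal: run `fn` under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_isolated_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}
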