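#' Neural efficiency of a wired packing
#'
#' The neural efficiency of a spatial configuration is
#' \deqn{S = \sum_{i \ne j} I_{ij} / d_{ij}}
#' over ordered region pairs, where `I_ij` is the directed projection volume
#' (mm^3) from region i to region j and `d_ij` the center-to-center distance
#' (mm), giving S units of mm^2. S is large when strong projections span
#' short distances. The sum runs over ordered pairs because the projection
#' matrix is asymmetric; self-terms are excluded.
#'
#' @param packing A [packing()].
#' @param adjacency A square non-negative matrix of projection volumes
#'   (mm^3), rows = source regions, columns = targets, aligned to the
#'   packing order (validated via [as_weighted_adjacency()]).
#' @return An object of class `efficiency_value`: a list with `value` (mm^2)
#'   and `n_terms`, the number of ordered pairs with positive weight.
#' @export
neural_efficiency <- function(packing, adjacency) {
  adjacency <- as_weighted_adjacency(adjacency, packing)
  contrib <- edge_contributions(packing, adjacency)
  structure(list(value = sum(contrib), n_terms = sum(adjacency > 0)),
            class = "efficiency_value")
}

#' @export
print.efficiency_value <- function(x, ...) {
  cat(sprintf("Neural efficiency S = %.6g mm^2 (%d weighted ordered pairs)\n",
              x$value, x$n_terms))
  invisible(x)
}

#' Per-edge efficiency contributions
#'
#' @inheritParams neural_efficiency
#' @return An n x n matrix with entry (i, j) equal to `I_ij / d_ij` for
#'   i != j and 0 on the diagonal; the total equals [neural_efficiency()].
#' @export
edge_contributions <- function(packing, adjacency) {
  adjacency <- as_weighted_adjacency(adjacency, packing)
  d <- pairwise_distances(packing)
  off <- row(d) != col(d)
  degenerate <- off & d < 1e-9 & adjacency > 0
  if (any(degenerate)) {
    idx <- which(degenerate, arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0("degenerate geometry: regions %s and %s are ",
                        "(near-)coincident but carry weight %g"),
                 packing$acronym[idx[1L]], packing$acronym[idx[2L]],
                 adjacency[idx[1L], idx[2L]]), call. = FALSE)
  }
  contrib <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  nz <- off & adjacency > 0
  contrib[nz] <- adjacency[nz] / d[nz]
  contrib
}

#' Wiring cost of a packing
#'
#' The wiring cost is the total center-to-center distance
#' \deqn{W = \sum_{i < j} d_{ij}}
#' over unordered region pairs (mm), corresponding to equal-caliber
#' connections between every pair. Distances are symmetric, so summing
#' over ordered pairs would only double the value and move no optimum.
#'
#' @param packing A [packing()] with at least two regions.
#' @return An object of class `wiring_cost`: a list with `value` (mm) and
#'   `n_pairs`.
#' @export
wiring_cost <- function(packing) {
  d <- pairwise_distances(packing)
  v <- d[upper.tri(d)]
  structure(list(value = sum(v), n_pairs = length(v)), class = "wiring_cost")
}

#' @export
print.wiring_cost <- function(x, ...) {
  cat(sprintf("Wiring cost W = %.6g mm over %d pairs\n", x$value, x$n_pairs))
  invisible(x)
}
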