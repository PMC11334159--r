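#' Sampler configuration
#'
#' Settings for the rejection sampler that builds a geometry-matched
#' random-packing null ensemble. A proposal is accepted when each of the
#' six overlap/gap statistics of [packing_stats()] lies within a relative
#' `tolerance` of the reference packing's value. Statistics whose reference
#' value is exactly 0 have no relative scale; they are compared against the
#' absolute threshold `zero_abs_tol` instead (the proposal's value must not
#' exceed it).
#'
#' @param tolerance Relative tolerance for the six statistics (default
#'   0.05, i.e. within 5 percent of the reference).
#' @param n_accept_target Number of accepted configurations wanted.
#' @param max_proposals Proposal budget before giving up.
#' @param seed Integer seed for the proposal stream.
#' @param zero_abs_tol Absolute threshold (mm) replacing the relative test
#'   when a reference statistic is 0 (default 0.05 mm).
#' @param box_padding Extra margin (mm) added around the reference bounding
#'   box on every side (default 0: the box barely fits the reference).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(tolerance = 0.05, n_accept_target = 100L,
                           max_proposals = 1e5, seed = 1L,
                           zero_abs_tol = 0.05, box_padding = 0) {
  stopifnot(tolerance > 0, tolerance < 1 || tolerance == 1,
            n_accept_target >= 1L, max_proposals >= n_accept_target,
            zero_abs_tol > 0, box_padding >= 0)
  structure(list(tolerance = tolerance,
                 n_accept_target = as.integer(n_accept_target),
                 max_proposals = as.integer(max_proposals),
                 seed = as.integer(seed), zero_abs_tol = zero_abs_tol,
                 box_padding = box_padding),
            class = "sampler_config")
}

#' Propose one random configuration in a box
#'
#' Draws i.i.d. uniform centers for every region inside the given box;
#' radii are taken unchanged from the reference regions.
#'
#' @param packing The reference [packing()] supplying regions and radii.
#' @param box A list with `origin` and `upper` as from [bounding_box()].
#' @param rng A function drawing k uniform(0,1) deviates, or an integer
#'   seed.
#' @return A new [packing()] with proposed centers.
#' @export
propose_configuration <- function(packing, box = bounding_box(packing),
                                  rng = 1L) {
  if (!is.function(rng)) rng <- local_rng(rng)
  n <- nrow(packing)
  u <- matrix(rng(3L * n), n, 3L)
  centers <- sweep(u, 2L, box$upper - box$origin, "*")
  centers <- sweep(centers, 2L, box$origin, "+")
  set_centers(packing, centers)
}

#' Acceptance decision for a proposed packing
#'
#' Computes the six per-statistic relative errors
#' `|q_prop - q_ref| / |q_ref|` and accepts when all are at or below the
#' tolerance. When a reference statistic is 0 the error is reported as
#' `tolerance * q_prop / zero_abs_tol`, so the uniform rule "all errors <=
#' tolerance" is exactly the absolute test `q_prop <= zero_abs_tol`.
#'
#' @param proposal_stats [packing_stats()] of the proposal.
#' @param reference_stats [packing_stats()] of the reference packing.
#' @param config A [sampler_config()].
#' @param proposal_index Bookkeeping index recorded in the output.
#' @return A list of class `acceptance_record` with `accepted`, `stats`
#'   (the proposal's), `per_statistic_relative_errors` (named, length 6)
#'   and `proposal_index`.
#' @export
accept_packing <- function(proposal_stats, reference_stats,
                           config = sampler_config(), proposal_index = NA_integer_) {
  if (proposal_stats$n_pairs != reference_stats$n_pairs) {
    stop("proposal and reference describe different region counts", call. = FALSE)
  }
  keys <- c("total_overlap", "mean_overlap", "max_overlap",
            "total_gap", "mean_gap", "max_gap")
  q_prop <- unlist(proposal_stats[keys])
  q_ref <- unlist(reference_stats[keys])
  errors <- ifelse(q_ref != 0,
                   abs(q_prop - q_ref) / abs(q_ref),
                   config$tolerance * q_prop / config$zero_abs_tol)
  structure(list(accepted = all(errors <= config$tolerance),
                 stats = proposal_stats,
                 per_statistic_relative_errors = errors,
                 proposal_index = proposal_index),
            class = "acceptance_record")
}

# Internal fast path: precomputed pair geometry for proposal screening.
# Returns the six statistics of a center matrix without building packings.
make_stats_fn <- function(packing) {
  n <- nrow(packing)
  pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- pair[, 1L]; j <- pair[, 2L]
  rsum <- packing$radius_mm[i] + packing$radius_mm[j]
  function(centers) {
    sep <- sqrt(rowSums((centers[i, , drop = FALSE] -
                           centers[j, , drop = FALSE])^2)) - rsum
    overlaps <- -sep[sep < 0]
    gaps <- sep[sep > 0]
    c(total_overlap = sum(overlaps),
      mean_overlap = if (length(overlaps)) mean(overlaps) else 0,
      max_overlap = if (length(overlaps)) max(overlaps) else 0,
      total_gap = sum(gaps),
      mean_gap = if (length(gaps)) mean(gaps) else 0,
      max_gap = if (length(gaps)) max(gaps) else 0)
  }
}

#' Sample a geometry-matched random-packing ensemble
#'
#' Rejection sampling of spatial null configurations: centers are proposed
#' i.i.d. uniform inside the reference packing's bounding box (optionally
#' padded), and a proposal is retained when its six overlap/gap statistics
#' match the reference within the configured tolerance. The weighted
#' adjacency is held fixed across all samples, so accepted configurations
#' differ from the reference only in geometry; their neural efficiencies
#' form the null distribution.
#'
#' @param reference The reference [packing()] (>= 2 regions).
#' @param adjacency Aligned weighted adjacency of the reference.
#' @param config A [sampler_config()].
#' @return An [ensemble_result()] of kind `"random"` whose `values` are the
#'   accepted configurations' neural efficiencies (mm^2), with
#'   `accepted_stats` (6-column matrix), `accepted_positions` (list),
#'   `n_proposed`, `n_accepted`, `acceptance_rate`, `box` and `starved`
#'   fields. If nothing is accepted within the proposal budget the (empty)
#'   ensemble carries `starved = TRUE` and a classed warning
#'   (`hypopack_starvation`) suggests relaxing the tolerance.
#' @export
sample_ensemble <- function(reference, adjacency, config = sampler_config()) {
  if (nrow(reference) < 2L) stop("reference needs >= 2 regions", call. = FALSE)
  adjacency <- as_weighted_adjacency(adjacency, reference)
  ref_stats <- packing_stats(reference)
  keys <- c("total_overlap", "mean_overlap", "max_overlap",
            "total_gap", "mean_gap", "max_gap")
  q_ref <- unlist(ref_stats[keys])
  tol <- config$tolerance
  zat <- config$zero_abs_tol

  box <- bounding_box(reference)
  box$origin <- box$origin - config$box_padding
  box$upper <- box$upper + config$box_padding
  box$sides <- box$upper - box$origin

  n <- nrow(reference)
  rng <- local_rng(config$seed)
  stats_fn <- make_stats_fn(reference)
  eff_fn <- make_efficiency_fn(reference, adjacency)

  values <- numeric(0)
  acc_stats <- list()
  acc_pos <- list()
  n_proposed <- 0L
  chunk <- 512L
  while (n_proposed < config$max_proposals &&
         length(values) < config$n_accept_target) {
    todo <- min(chunk, config$max_proposals - n_proposed)
    u <- array(rng(3L * n * todo), dim = c(n, 3L, todo))
    for (t in seq_len(todo)) {
      n_proposed <- n_proposed + 1L
      centers <- sweep(u[, , t, drop = TRUE] , 2L, box$sides, "*")
      centers <- sweep(centers, 2L, box$origin, "+")
      q <- stats_fn(centers)
      ok <- all(ifelse(q_ref != 0, abs(q - q_ref) <= tol * abs(q_ref),
                       q <= zat))
      if (ok) {
        values <- c(values, eff_fn(centers))
        acc_stats[[length(acc_stats) + 1L]] <- q
        acc_pos[[length(acc_pos) + 1L]] <- centers
        if (length(values) >= config$n_accept_target) break
      }
    }
  }

  starved <- length(values) == 0L
  if (starved) {
    warning(structure(class = c("hypopack_starvation", "warning", "condition"),
                      list(message = sprintf(
                        paste0("no configuration accepted after %d proposals; ",
                               "consider relaxing `tolerance` (currently %g) or ",
                               "`zero_abs_tol`"), n_proposed, tol),
                        call = NULL)))
  }
  ensemble_result(values, kind = "random", settings = unclass(config),
                  seeds = config$seed,
                  extra = list(
                    accepted_stats = if (length(acc_stats))
                      do.call(rbind, acc_stats) else
                        matrix(numeric(0), 0L, 6L, dimnames = list(NULL, keys)),
                    accepted_positions = acc_pos,
                    reference_stats = ref_stats,
                    n_proposed = n_proposed,
                    n_accepted = length(values),
                    acceptance_rate = length(values) / n_proposed,
                    box = box,
                    starved = starved))
}

# Internal: efficiency of a center matrix with fixed radii/weights.
make_efficiency_fn <- function(packing, adjacency) {
  n <- nrow(packing)
  pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- pair[, 1L]; j <- pair[, 2L]
  w_pair <- adjacency[cbind(i, j)] + adjacency[cbind(j, i)]
  function(centers) {
    dvec <- sqrt(rowSums((centers[i, , drop = FALSE] -
                            centers[j, , drop = FALSE])^2))
    if (any(dvec < 1e-9 & w_pair > 0)) {
      stop("degenerate geometry: coincident centers with nonzero weight",
           call. = FALSE)
    }
    sum(w_pair[w_pair > 0] / dvec[w_pair > 0])
  }
}
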