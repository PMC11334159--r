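#' Optimizer configuration
#'
#' Settings for constrained repacking of the spheres. The overlap
#' constraint caps every unordered pair's overlap at `epsilon_max`; each
#' coordinate is bounded to `box_bounds`. Maximization of neural efficiency
#' is performed by minimizing `-S` by default (`objective_form =
#' "negative"`, better conditioned near S = 0); minimizing the literal
#' inverse `1/S` is available with `objective_form = "inverse"` and both
#' forms agree on the argmax.
#'
#' @param objective `"neural_efficiency_max"` or `"wiring_cost_min"`.
#' @param epsilon_max Per-pair overlap cap in mm (default 0.8 mm, the
#'   overlap scale observed in anatomically derived sphere models).
#' @param min_distance_frac Well-posedness guard: no pair's center distance
#'   may fall below this fraction of the pair's combined radii (default
#'   0.05). Without it, a pair of small spheres whose combined radii are
#'   below `epsilon_max` could collapse to coincidence, where the
#'   efficiency objective is unbounded. The guard only binds where the
#'   overlap cap is vacuous.
#' @param box_bounds Length-2 interval (mm) bounding every coordinate;
#'   default `c(0, 15)`. Results are insensitive to upper limits beyond
#'   the packing's extent.
#' @param n_restarts Number of random restarts for [run_restart_ensemble()].
#' @param seed Master seed; restart k uses `seed + k`.
#' @param ftol Inner-solver relative tolerance (L-BFGS-B `factr` =
#'   `ftol / .Machine$double.eps`).
#' @param maxit Inner-solver iteration cap per outer step.
#' @param outer_maxit Augmented-Lagrangian outer iteration cap.
#' @param feas_tol Feasibility tolerance (mm) for declaring convergence.
#' @param objective_form `"negative"` or `"inverse"` (efficiency only).
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(objective = c("neural_efficiency_max",
                                           "wiring_cost_min"),
                             epsilon_max = 0.8,
                             min_distance_frac = 0.05,
                             box_bounds = c(0, 15),
                             n_restarts = 100L,
                             seed = 1L,
                             ftol = 1e-10,
                             maxit = 400L,
                             outer_maxit = 50L,
                             feas_tol = 1e-6,
                             objective_form = c("negative", "inverse")) {
  objective <- match.arg(objective)
  objective_form <- match.arg(objective_form)
  stopifnot(epsilon_max >= 0, min_distance_frac > 0, min_distance_frac < 1,
            length(box_bounds) == 2L,
            box_bounds[1L] < box_bounds[2L], n_restarts >= 1L,
            ftol > 0, feas_tol > 0)
  structure(list(objective = objective, epsilon_max = epsilon_max,
                 min_distance_frac = min_distance_frac,
                 box_bounds = as.numeric(box_bounds),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 ftol = ftol, maxit = as.integer(maxit),
                 outer_maxit = as.integer(outer_maxit), feas_tol = feas_tol,
                 objective_form = objective_form),
            class = "optimizer_config")
}

#' Random start positions inside a box
#'
#' @param packing A [packing()] (only the region count is used).
#' @param box_bounds Length-2 interval (mm) for every coordinate.
#' @param seed Integer seed; identical seeds give identical positions.
#' @return An n x 3 matrix of i.i.d. uniform coordinates.
#' @export
random_start <- function(packing, box_bounds = c(0, 15), seed = 1L) {
  stopifnot(length(box_bounds) == 2L, box_bounds[1L] <= box_bounds[2L])
  n <- nrow(packing)
  rng <- local_rng(seed)
  matrix(rng(3L * n) * (box_bounds[2L] - box_bounds[1L]) + box_bounds[1L],
         nrow = n, ncol = 3L)
}

# Internal: returns a function drawing k uniform(0,1) deviates from an
# isolated RNG stream so package randomness never disturbs the user's
# .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  function(k) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    u <- stats::runif(k)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    u
  }
}

# Internal objective/gradient factory. x is the flattened n x 3 center
# matrix (column-major). Returns f(x) to MINIMIZE and its gradient.
#
# For the efficiency objective, 1/d is unbounded as a pair collapses, which
# would let the singularity outrun any finite constraint penalty. Distances
# are therefore floored at half the pairwise feasibility limit
# (r_i + r_j - epsilon_max): the floor lies strictly inside the infeasible
# zone, so the surrogate equals the true objective (with exact gradients)
# everywhere the overlap constraint holds, while staying bounded below.
make_objective <- function(packing, adjacency, config) {
  n <- nrow(packing)
  pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- pair[, 1L]; j <- pair[, 2L]
  if (config$objective == "neural_efficiency_max") {
    w_pair <- adjacency[cbind(i, j)] + adjacency[cbind(j, i)]
    dfloor <- 0.5 * pair_min_distance(packing, config)
  } else {
    w_pair <- NULL
    dfloor <- NULL
  }
  list(
    n = n, i = i, j = j,
    # value of S or W plus gradient pieces, shared by objective and reports
    fn = function(x) {
      p <- matrix(x, n, 3L)
      dvec <- sqrt(rowSums((p[i, , drop = FALSE] - p[j, , drop = FALSE])^2))
      if (config$objective == "wiring_cost_min") {
        sum(dvec)
      } else {
        s <- sum(w_pair / pmax(dvec, dfloor))
        if (config$objective_form == "inverse") 1 / max(s, 1e-12) else -s
      }
    },
    gr = function(x) {
      p <- matrix(x, n, 3L)
      diff <- p[i, , drop = FALSE] - p[j, , drop = FALSE]
      dvec <- pmax(sqrt(rowSums(diff^2)), 1e-12)
      if (config$objective == "wiring_cost_min") {
        coef <- 1 / dvec                      # dW/dd = 1
      } else {
        coef <- ifelse(dvec > dfloor, w_pair / dvec^3, 0)  # flat below floor
        if (config$objective_form == "inverse") {
          s <- sum(w_pair / pmax(dvec, dfloor))
          coef <- coef / max(s, 1e-12)^2      # d(1/S) = (1/S^2) dS-terms
        }
      }
      g <- matrix(0, n, 3L)
      contrib <- diff * coef
      for (a in 1L:3L) {
        g[, a] <- g[, a] + tapply_sum(contrib[, a], i, n) -
          tapply_sum(contrib[, a], j, n)
      }
      as.vector(g)
    },
    # raw objective on the paper's scale (S in mm^2 or W in mm)
    report = function(x) {
      p <- matrix(x, n, 3L)
      dvec <- pmax(sqrt(rowSums((p[i, , drop = FALSE] - p[j, , drop = FALSE])^2)),
                   1e-12)
      if (config$objective == "wiring_cost_min") sum(dvec) else sum(w_pair / dvec)
    }
  )
}

# Internal: fast grouped sum into a length-n vector.
tapply_sum <- function(values, index, n) {
  out <- numeric(n)
  acc <- rowsum(values, index)
  out[as.integer(rownames(acc))] <- acc
  out
}

# Internal: per-pair minimum admissible center distance,
# max(r_i + r_j - epsilon_max, min_distance_frac * (r_i + r_j)).
pair_min_distance <- function(packing, config) {
  n <- nrow(packing)
  pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
  rsum <- packing$radius_mm[pair[, 1L]] + packing$radius_mm[pair[, 2L]]
  pmax(rsum - config$epsilon_max, config$min_distance_frac * rsum)
}

# Internal: pairwise constraint residuals g = d_min_pair - d (feasible when
# <= 0) and the gradient of sum(mult * g) wrt x.
make_constraints <- function(packing, config) {
  n <- nrow(packing)
  pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- pair[, 1L]; j <- pair[, 2L]
  rsum <- pair_min_distance(packing, config)
  list(
    residual = function(x) {
      p <- matrix(x, n, 3L)
      dvec <- sqrt(rowSums((p[i, , drop = FALSE] - p[j, , drop = FALSE])^2))
      rsum - dvec
    },
    grad_weighted = function(x, mult) {
      p <- matrix(x, n, 3L)
      diff <- p[i, , drop = FALSE] - p[j, , drop = FALSE]
      dvec <- pmax(sqrt(rowSums(diff^2)), 1e-12)
      coef <- -mult / dvec                    # d(-d)/dx_i = -(x_i-x_j)/d
      g <- matrix(0, n, 3L)
      contrib <- diff * coef
      for (a in 1L:3L) {
        g[, a] <- g[, a] + tapply_sum(contrib[, a], i, n) -
          tapply_sum(contrib[, a], j, n)
      }
      as.vector(g)
    }
  )
}

#' Optimize sphere positions under overlap constraints
#'
#' Repositions the spheres to maximize neural efficiency or minimize wiring
#' cost subject to (a) every coordinate lying in `box_bounds` and (b) every
#' unordered pair overlapping by at most `epsilon_max`. The solver is an
#' augmented-Lagrangian (Powell-Hestenes-Rockafellar) outer loop over
#' box-constrained L-BFGS-B inner solves, with analytic gradients of both
#' the objective and the constraints.
#'
#' @param packing A [packing()]; radii and weights stay fixed, only centers
#'   move.
#' @param adjacency Aligned weighted adjacency (ignored for wiring cost).
#' @param config An [optimizer_config()].
#' @param start Optional n x 3 start matrix; defaults to [random_start()]
#'   with `config$seed`.
#' @return An object of class `optimization_result`: list with `positions`
#'   (n x 3 mm), `objective_value` (S in mm^2 or W in mm, on the natural
#'   scale), `start_positions`, `start_objective`, `converged`,
#'   `n_iterations` (total inner iterations), `constraint_violation`
#'   (max residual, mm) and the `config`.
#' @export
optimize_packing <- function(packing, adjacency = NULL, config = optimizer_config(),
                             start = NULL) {
  n <- nrow(packing)
  if (n < 2L) stop("need at least 2 regions", call. = FALSE)
  if (config$objective == "neural_efficiency_max") {
    if (is.null(adjacency)) stop("adjacency required for efficiency objective",
                                 call. = FALSE)
    adjacency <- as_weighted_adjacency(adjacency, packing)
    if (sum(adjacency) == 0) stop("all projection weights are zero", call. = FALSE)
  }
  if (is.null(start)) start <- random_start(packing, config$box_bounds, config$seed)
  start <- as.matrix(start)
  stopifnot(nrow(start) == n, ncol(start) == 3L)

  # Feasibility of the box itself: the largest sphere pair must fit.
  side <- config$box_bounds[2L] - config$box_bounds[1L]
  r2 <- sort(packing$radius_mm, decreasing = TRUE)[1:2]
  if (sum(r2) - config$epsilon_max > sqrt(3) * side) {
    stop("box too small: the two largest spheres cannot satisfy the overlap cap",
         call. = FALSE)
  }

  obj <- make_objective(packing, adjacency, config)
  con <- make_constraints(packing, config)
  x <- as.vector(start)
  lower <- rep(config$box_bounds[1L], 3L * n)
  upper <- rep(config$box_bounds[2L], 3L * n)

  m <- length(con$residual(x))
  lambda <- numeric(m)
  rho <- 10
  total_iter <- 0L
  inner_ok <- FALSE
  prev_viol <- Inf

  for (outer in seq_len(config$outer_maxit)) {
    al_fn <- function(x) {
      g <- con$residual(x)
      obj$fn(x) + sum(pmax(0, lambda + rho * g)^2 - lambda^2) / (2 * rho)
    }
    al_gr <- function(x) {
      g <- con$residual(x)
      mult <- pmax(0, lambda + rho * g)
      obj$gr(x) + con$grad_weighted(x, mult)
    }
    fit <- stats::optim(x, al_fn, al_gr, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = config$maxit,
                                       factr = config$ftol / .Machine$double.eps))
    x <- fit$par
    total_iter <- total_iter + fit$counts[["function"]]
    g <- con$residual(x)
    viol <- max(0, g)
    lambda <- pmax(0, lambda + rho * g)
    inner_ok <- fit$convergence %in% c(0L, 1L)
    if (viol <= config$feas_tol && fit$convergence == 0L && outer >= 3L) break
    if (viol > 0.25 * prev_viol) rho <- min(rho * 4, 1e10)
    prev_viol <- viol
  }

  g <- con$residual(x)
  viol <- max(0, g)
  structure(list(
    positions = matrix(x, n, 3L,
                       dimnames = list(packing$acronym, c("x_mm", "y_mm", "z_mm"))),
    objective_value = obj$report(x),
    start_positions = start,
    start_objective = obj$report(as.vector(start)),
    converged = inner_ok && viol <= config$feas_tol,
    n_iterations = total_iter,
    constraint_violation = viol,
    config = config
  ), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  unit <- if (x$config$objective == "wiring_cost_min") "mm" else "mm^2"
  cat(sprintf(
    "Packing optimization (%s): objective %.6g %s, %sconverged, max violation %.2e mm\n",
    x$config$objective, x$objective_value, unit,
    if (x$converged) "" else "NOT ", x$constraint_violation))
  invisible(x)
}

#' Run a random-restart optimization ensemble
#'
#' Repeats [optimize_packing()] from `n_restarts` random starts (restart k
#' is seeded with `seed + k`), collecting the distribution of local optima.
#' Nonconvergent restarts are kept as flagged entries, never dropped
#' silently.
#'
#' @inheritParams optimize_packing
#' @param keep_positions Keep every restart's optimal positions (memory
#'   scales with `n_restarts`); the best restart's positions are always
#'   kept.
#' @return An [ensemble_result()] of kind `"optimized"` with per-restart
#'   `values` (natural scale), `converged` flags, `seeds`, and
#'   `best` (the best converged optimization_result).
#' @export
run_restart_ensemble <- function(packing, adjacency = NULL,
                                 config = optimizer_config(),
                                 keep_positions = FALSE) {
  values <- numeric(config$n_restarts)
  converged <- logical(config$n_restarts)
  seeds <- config$seed + seq_len(config$n_restarts)
  positions <- if (keep_positions) vector("list", config$n_restarts) else NULL
  best <- NULL
  maximizing <- config$objective == "neural_efficiency_max"
  for (k in seq_len(config$n_restarts)) {
    start <- random_start(packing, config$box_bounds, seeds[k])
    res <- optimize_packing(packing, adjacency, config, start = start)
    values[k] <- res$objective_value
    converged[k] <- res$converged
    if (keep_positions) positions[[k]] <- res$positions
    if (res$converged &&
        (is.null(best) ||
         (maximizing && res$objective_value > best$objective_value) ||
         (!maximizing && res$objective_value < best$objective_value))) {
      best <- res
    }
  }
  ensemble_result(values, kind = "optimized",
                  settings = unclass(config), seeds = seeds,
                  extra = list(converged = converged, best = best,
                               positions = positions))
}
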