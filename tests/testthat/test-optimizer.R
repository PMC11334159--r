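two_sphere <- function() {
  list(packing = make_packing(rbind(c(1, 1, 1), c(2, 1, 1))),
       adjacency = matrix(c(0, 4, 0, 0), 2, 2, byrow = TRUE))
}

test_that("random starts are deterministic, uniform and box-respecting", {
  pk <- random_packing(5, seed = 1)
  expect_identical(random_start(pk, c(0, 15), seed = 7),
                   random_start(pk, c(0, 15), seed = 7))
  expect_false(identical(random_start(pk, c(0, 15), seed = 7),
                         random_start(pk, c(0, 15), seed = 8)))

  # degenerate box collapses all positions to the point
  expect_equal(random_start(pk, c(3, 3), seed = 1),
               matrix(3, 5, 3))

  # empirical mean of one coordinate within 3 standard errors of midpoint
  draws <- vapply(1:2000, function(k) random_start(pk, c(0, 10), seed = k)[1, 1],
                  numeric(1))
  se <- 10 / sqrt(12) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 5), 3 * se)
  expect_true(all(draws >= 0 & draws <= 10))
})

test_that("analytic gradients match finite differences", {
  pk <- random_packing(5, seed = 3, span = 3)
  adj <- random_adjacency(5, seed = 3)
  for (objective in c("neural_efficiency_max", "wiring_cost_min")) {
    for (form in c("negative", "inverse")) {
      cfg <- optimizer_config(objective, objective_form = form)
      obj <- hypopack:::make_objective(pk, adj, cfg)
      con <- hypopack:::make_constraints(pk, cfg)
      x <- as.vector(as.matrix(as.data.frame(pk)[, c("x_mm", "y_mm", "z_mm")]))
      h <- 1e-6
      num <- vapply(seq_along(x), function(k) {
        e <- numeric(length(x)); e[k] <- h
        (obj$fn(x + e) - obj$fn(x - e)) / (2 * h)
      }, numeric(1))
      expect_equal(obj$gr(x), num, tolerance = 1e-5)

      mult <- runif(length(con$residual(x)))
      numc <- vapply(seq_along(x), function(k) {
        e <- numeric(length(x)); e[k] <- h
        (sum(mult * con$residual(x + e)) - sum(mult * con$residual(x - e))) / (2 * h)
      }, numeric(1))
      expect_equal(con$grad_weighted(x, mult), numc, tolerance = 1e-5)
    }
  }
})

test_that("two-sphere efficiency maximization reaches the analytic optimum", {
  ts <- two_sphere()
  cfg <- optimizer_config("neural_efficiency_max", epsilon_max = 0,
                          n_restarts = 20, seed = 5)
  ens <- run_restart_ensemble(ts$packing, ts$adjacency, cfg)
  expect_true(all(ens$converged))
  expect_true(all(abs(ens$values - 2.0) < 1e-4))
})

test_that("both maximization forms agree on the optimum", {
  ts <- two_sphere()
  for (form in c("negative", "inverse")) {
    cfg <- optimizer_config("neural_efficiency_max", epsilon_max = 0,
                            n_restarts = 5, seed = 2, objective_form = form)
    ens <- run_restart_ensemble(ts$packing, ts$adjacency, cfg)
    expect_true(all(abs(ens$values - 2.0) < 1e-4), label = form)
  }
})

test_that("three-unit-sphere wiring cost reaches the equilateral optimum", {
  tri <- make_packing(matrix(runif(9, 0, 10), 3, 3))
  cfg <- optimizer_config("wiring_cost_min", epsilon_max = 0,
                          n_restarts = 20, seed = 5)
  ens <- run_restart_ensemble(tri, NULL, cfg)
  expect_true(all(ens$converged))
  expect_true(all(abs(ens$values - 6.0) < 1e-4))
})

test_that("optimizer agrees with a grid-search oracle on three spheres", {
  # For three spheres the efficiency depends on positions only through the
  # three pairwise distances, so exhaustive search over (d12, d13, d23) on
  # a coarse lattice (refined locally) under triangle-inequality and
  # minimum-distance feasibility is an independent oracle. Any feasible
  # distance triple is realizable as a triangle in 3-D, and the box is
  # large enough to hold it.
  pk <- random_packing(3, seed = 14, span = 4)
  adj <- random_adjacency(3, seed = 14)
  adj[adj == 0 & row(adj) != col(adj)] <- 0.3  # fully weighted
  cfg <- optimizer_config("neural_efficiency_max", epsilon_max = 0.1,
                          n_restarts = 8, seed = 4, box_bounds = c(0, 8))
  ens <- run_restart_ensemble(pk, adj, cfg)
  best <- max(ens$values[ens$converged])

  dmin <- hypopack:::pair_min_distance(pk, cfg)
  w <- c(adj[1, 2] + adj[2, 1], adj[1, 3] + adj[3, 1], adj[2, 3] + adj[3, 2])
  s_of <- function(d) sum(w / d)
  search <- function(lo, hi, steps) {
    grids <- lapply(1:3, function(p) seq(lo[p], hi[p], length.out = steps))
    best_d <- NULL; best_s <- -Inf
    for (a in grids[[1]]) for (b in grids[[2]]) for (cc in grids[[3]]) {
      if (a > b + cc || b > a + cc || cc > a + b) next  # not a triangle
      s <- s_of(c(a, b, cc))
      if (s > best_s) { best_s <- s; best_d <- c(a, b, cc) }
    }
    list(d = best_d, s = best_s)
  }
  coarse <- search(dmin, dmin * 3, 15)
  span <- (dmin * 3 - dmin) / 14
  fine <- search(pmax(dmin, coarse$d - span), coarse$d + span, 21)
  expect_lt(abs(best - fine$s) / fine$s, 0.01)
})

test_that("converged results are feasible and improve on their start", {
  pk <- random_packing(5, seed = 6, span = 3)
  adj <- random_adjacency(5, seed = 6)
  cfg <- optimizer_config("neural_efficiency_max", n_restarts = 6, seed = 9,
                          box_bounds = c(0, 10))
  dmin <- hypopack:::pair_min_distance(pk, cfg)
  pair <- which(upper.tri(diag(5)), arr.ind = TRUE)
  for (k in 1:6) {
    start <- random_start(pk, c(0, 10), seed = 100 + k)
    res <- optimize_packing(pk, adj, cfg, start = start)
    if (!res$converged) next
    d <- as.matrix(dist(res$positions))
    expect_true(all(dmin - d[pair] <= 1e-6 + 1e-9))
    expect_true(all(res$positions >= -1e-9 & res$positions <= 10 + 1e-9))
    expect_gte(res$objective_value, res$start_objective - 1e-9)
  }
})

test_that("restart ensembles are deterministic and expose multi-modality", {
  sc <- synth_config(n_regions = 6, seed = 1, edge_density = 0.8,
                     distance_decay_lambda = 1)
  gt <- generate_ground_truth_efficient(sc)
  cfg <- optimizer_config("neural_efficiency_max", n_restarts = 10, seed = 21)
  e1 <- run_restart_ensemble(gt$packing, gt$adjacency, cfg)
  e2 <- run_restart_ensemble(gt$packing, gt$adjacency, cfg)
  expect_identical(e1$values, e2$values)
  expect_identical(e1$seeds, cfg$seed + 1:10)

  # distinct local optima separated by far more than solver tolerance
  conv <- e1$values[e1$converged]
  expect_gte(length(unique(round(conv, 6))), 2)
  expect_gt(diff(range(conv)), 10 * cfg$feas_tol)

  # singleton ensemble equals a direct call with the derived seed
  cfg1 <- optimizer_config("neural_efficiency_max", n_restarts = 1, seed = 21)
  single <- run_restart_ensemble(gt$packing, gt$adjacency, cfg1)
  direct <- optimize_packing(gt$packing, gt$adjacency, cfg1,
                             start = random_start(gt$packing, cfg1$box_bounds,
                                                  seed = 22))
  expect_equal(single$values, direct$objective_value)
})

test_that("translating box and start together leaves the optimum unchanged", {
  ts <- two_sphere()
  cfg0 <- optimizer_config("neural_efficiency_max", epsilon_max = 0,
                           box_bounds = c(0, 8), n_restarts = 1, seed = 1)
  cfg5 <- optimizer_config("neural_efficiency_max", epsilon_max = 0,
                           box_bounds = c(5, 13), n_restarts = 1, seed = 1)
  start <- random_start(ts$packing, c(0, 8), seed = 33)
  r0 <- optimize_packing(ts$packing, ts$adjacency, cfg0, start = start)
  r5 <- optimize_packing(ts$packing, ts$adjacency, cfg5, start = start + 5)
  expect_equal(r0$objective_value, r5$objective_value, tolerance = 1e-6)
})

test_that("infeasible box/epsilon combinations are rejected", {
  big <- make_packing(rbind(c(0, 0, 0), c(1, 0, 0)), radii = c(4, 4))
  cfg <- optimizer_config("wiring_cost_min", epsilon_max = 0,
                          box_bounds = c(0, 2))
  expect_error(optimize_packing(big, NULL, cfg), "box too small")
})
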