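test_that("proposals are reproducible and contained in the box", {
  pk <- random_packing(6, seed = 3, span = 3)
  box <- bounding_box(pk)
  p1 <- propose_configuration(pk, box, rng = 11L)
  p2 <- propose_configuration(pk, box, rng = 11L)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
  expect_identical(p1$radius_mm, pk$radius_mm)

  rng <- hypopack:::local_rng(4L)
  for (k in 1:200) {
    x <- hypopack:::centers_of(propose_configuration(pk, box, rng))
    expect_true(all(sweep(x, 2, box$origin, "-") >= -1e-12))
    expect_true(all(sweep(x, 2, box$upper, "-") <= 1e-12))
  }
})

test_that("proposal coordinates are uniform in the box", {
  pk <- random_packing(4, seed = 1, span = 4)
  box <- bounding_box(pk)
  rng <- hypopack:::local_rng(9L)
  xs <- replicate(3000, hypopack:::centers_of(propose_configuration(pk, box, rng))[1, 1])
  edges <- seq(box$origin[1], box$upper[1], length.out = 11)
  counts <- table(cut(xs, edges))
  p <- chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("acceptance implements the six-clause tolerance rule", {
  pk <- random_packing(5, seed = 8, span = 2)
  ref <- packing_stats(pk)
  cfg <- sampler_config(tolerance = 0.05)

  # identical proposal accepted with zero errors
  rec <- accept_packing(ref, ref, cfg)
  expect_true(rec$accepted)
  expect_equal(unname(rec$per_statistic_relative_errors), rep(0, 6))

  # one statistic off by 10% at 5% tolerance is rejected with that error
  off <- ref
  off$total_gap <- ref$total_gap * 1.10
  rec <- accept_packing(off, ref, cfg)
  expect_false(rec$accepted)
  expect_equal(unname(rec$per_statistic_relative_errors["total_gap"]), 0.10,
               tolerance = 1e-9)

  # randomized stats decided by an explicit six-clause boolean oracle
  keys <- c("total_overlap", "mean_overlap", "max_overlap",
            "total_gap", "mean_gap", "max_gap")
  set.seed(42)
  for (k in 1:200) {
    prop <- ref
    for (key in keys) prop[[key]] <- ref[[key]] * runif(1, 0.9, 1.1)
    oracle <- all(vapply(keys, function(key) {
      q_ref <- ref[[key]]
      if (q_ref != 0) abs(prop[[key]] - q_ref) / abs(q_ref) <= cfg$tolerance
      else prop[[key]] <= cfg$zero_abs_tol
    }, logical(1)))
    expect_identical(accept_packing(prop, ref, cfg)$accepted, oracle)
  }
})

test_that("zero-valued reference statistics use the absolute threshold", {
  # spread spheres: no overlaps, so the three overlap references are 0
  pk <- make_packing(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0)))
  ref <- packing_stats(pk)
  expect_identical(ref$n_overlapping_pairs, 0L)
  cfg <- sampler_config(tolerance = 0.05, zero_abs_tol = 0.05)

  prop <- ref
  prop$total_overlap <- 0.04  # below the absolute threshold
  prop$total_gap <- ref$total_gap
  expect_true(accept_packing(prop, ref, cfg)$accepted)
  prop$total_overlap <- 0.06  # above it
  expect_false(accept_packing(prop, ref, cfg)$accepted)
})

test_that("mismatched region counts are rejected", {
  a <- packing_stats(random_packing(4, seed = 1))
  b <- packing_stats(random_packing(5, seed = 1))
  expect_error(accept_packing(a, b), "region counts")
})

test_that("a wide-open gate accepts the first proposals", {
  pk <- random_packing(4, seed = 2, span = 2)
  adj <- random_adjacency(4, seed = 2, labels = pk$acronym)
  cfg <- sampler_config(tolerance = 1.0, zero_abs_tol = 1e6,
                        n_accept_target = 1, max_proposals = 50, seed = 1)
  ens <- sample_ensemble(pk, adj, cfg)
  expect_identical(ens$n_accepted, 1L)
  expect_lte(ens$n_proposed, 50L)
})

test_that("sampling is deterministic in the seed", {
  pk <- random_packing(4, seed = 5, span = 1.6)
  adj <- random_adjacency(4, seed = 5, labels = pk$acronym)
  cfg <- sampler_config(tolerance = 0.25, n_accept_target = 20,
                        max_proposals = 2e4, seed = 77, zero_abs_tol = 0.05)
  e1 <- sample_ensemble(pk, adj, cfg)
  e2 <- sample_ensemble(pk, adj, cfg)
  expect_identical(e1$values, e2$values)
  expect_identical(e1$n_proposed, e2$n_proposed)
  e3 <- sample_ensemble(pk, adj, sampler_config(tolerance = 0.25,
                                                n_accept_target = 20,
                                                max_proposals = 2e4, seed = 78,
                                                zero_abs_tol = 0.05))
  expect_false(identical(e1$values, e3$values))
})

test_that("no acceptance leaks: every accepted packing re-passes the gate", {
  pk <- random_packing(5, seed = 9, span = 1.8)
  adj <- random_adjacency(5, seed = 9, labels = pk$acronym)
  cfg <- sampler_config(tolerance = 0.3, n_accept_target = 1e4,
                        max_proposals = 1e4, seed = 13, zero_abs_tol = 0.05)
  ens <- sample_ensemble(pk, adj, cfg)
  expect_identical(ens$n_proposed, 10000L)
  expect_gt(ens$n_accepted, 0)
  ref <- packing_stats(pk)
  for (k in seq_len(ens$n_accepted)) {
    re <- set_centers(pk, ens$accepted_positions[[k]])
    rec <- accept_packing(packing_stats(re), ref, cfg)
    expect_true(rec$accepted)
    # stored stats agree with recomputation from positions
    expect_equal(unname(ens$accepted_stats[k, ]),
                 unname(unlist(unclass(packing_stats(re))[colnames(ens$accepted_stats)])),
                 tolerance = 1e-9)
    # efficiency values recompute identically under the fixed adjacency
    expect_equal(ens$values[k], neural_efficiency(re, adj)$value,
                 tolerance = 1e-9)
  }
})

test_that("accepted-ensemble statistic means sit near the reference", {
  pk <- random_packing(5, seed = 9, span = 1.8)
  adj <- random_adjacency(5, seed = 9, labels = pk$acronym)
  cfg <- sampler_config(tolerance = 0.2, n_accept_target = 200,
                        max_proposals = 5e4, seed = 29, zero_abs_tol = 0.05)
  ens <- sample_ensemble(pk, adj, cfg)
  expect_gt(ens$n_accepted, 10)
  ref <- unlist(unclass(packing_stats(pk))[colnames(ens$accepted_stats)])
  means <- colMeans(ens$accepted_stats)
  for (key in names(ref)) {
    if (ref[[key]] != 0) {
      expect_lt(abs(means[[key]] - ref[[key]]) / ref[[key]], cfg$tolerance)
    } else {
      expect_lte(means[[key]], cfg$zero_abs_tol)
    }
  }
})

test_that("acceptance rate is self-consistent across independent seeds", {
  pk <- random_packing(4, seed = 21, span = 1.5)
  adj <- random_adjacency(4, seed = 21, labels = pk$acronym)
  run <- function(seed) {
    cfg <- sampler_config(tolerance = 0.25, n_accept_target = 1e4,
                          max_proposals = 1e4, seed = seed,
                          zero_abs_tol = 0.05)
    sample_ensemble(pk, adj, cfg)
  }
  e1 <- run(101); e2 <- run(202)
  p <- (e1$n_accepted + e2$n_accepted) / (e1$n_proposed + e2$n_proposed)
  se <- sqrt(2 * p * (1 - p) / 1e4)
  expect_gt(e1$n_accepted, 0)
  expect_lt(abs(e1$acceptance_rate - e2$acceptance_rate), 3 * se + 1e-9)
})

test_that("starvation is reported, not silent", {
  pk <- make_packing(rbind(c(0, 0, 0), c(2.0001, 0, 0)))
  adj <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  # impossible gate: tiny tolerance around a knife-edge reference
  cfg <- sampler_config(tolerance = 1e-6, n_accept_target = 5,
                        max_proposals = 200, seed = 3, zero_abs_tol = 1e-9)
  expect_warning(ens <- sample_ensemble(pk, adj, cfg), "relaxing",
                 class = "hypopack_starvation")
  expect_true(ens$starved)
  expect_identical(ens$n_accepted, 0L)
})
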