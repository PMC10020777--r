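test_that("search coefficient support is [-2,-1) U (1,2] and C is 2*r4", {
  expect_equal(sample_search_coefficients(list(r1 = 1, r2 = 0, r3 = 0.5,
                                               r4 = 0.284))$A, -2)
  expect_equal(sample_search_coefficients(list(r1 = 0, r2 = 0.3, r3 = 1,
                                               r4 = 0))$A, 2)
  expect_equal(sample_search_coefficients(list(r1 = 1, r2 = 0, r3 = 0,
                                               r4 = 0.284))$C, 0.568)
  set.seed(11)
  A <- replicate(1e5, sample_search_coefficients()$A)
  expect_true(all((A >= -2 & A < -1) | (A > 1 & A <= 2)))
  expect_false(any(A >= -1 & A <= 1))
  # both branches of the coin are exercised
  expect_gt(mean(A < 0), 0.45)
  expect_lt(mean(A < 0), 0.55)
})

test_that("searching update reproduces the worked step and clamps to bounds", {
  spec <- quad_spec()
  upd <- searching_update(c(-0.451, 1.913), c(1.983, 0.562),
                          A = -1.8945, C = 0.568, spec)
  expect_equal(upd$D, c(1.577, 1.594), tolerance = 5e-3)
  expect_equal(upd$position, c(4.972, 3.582), tolerance = 5e-3)
  # zero-distance fixed point: C * X_sct = X_m
  sct <- c(2, 1)
  upd0 <- searching_update(0.5 * sct, sct, A = 1.7, C = 0.5, spec)
  expect_equal(upd0$position, sct)
  # out-of-box component is clamped to the violated bound
  updc <- searching_update(c(3.114, -3.367), c(1.983, 0.562),
                           A = 1.987, C = 0.876, spec)
  expect_lt(updc$raw[2], -5)
  expect_equal(updc$position, c(-0.753, -5), tolerance = 5e-3)
  expect_error(
    searching_update(c(0, 0), c(1, 1), 1, 1,
                     objective_spec(function(x) NaN, c(-5, -5), c(5, 5))),
    "non-finite")
})

test_that("prey is the mean of the k best with index tie-breaks", {
  pos <- rbind(c(-3.308, -3.625), c(-0.3487, -2.967), c(-1.521, -5.000),
               c(4, 4))
  vals <- c(-6.024, -1.675, -0.334, 50)
  pp <- compute_prey_position(pos, vals, k = 3, sense = "minimize")
  expect_equal(pp$prey, c(-1.726, -3.864), tolerance = 5e-3)
  expect_identical(pp$alphas, c(1L, 2L, 3L))
  pp2 <- compute_prey_position(rbind(c(-1.493, -2.573), c(-0.749, -2.441),
                                     c(-0.667, -2.511)),
                               c(1, 2, 3), k = 3, sense = "minimize")
  expect_equal(pp2$prey, c(-0.970, -2.508), tolerance = 5e-3)
  # k = 1 returns the single best agent's position
  expect_equal(compute_prey_position(pos, vals, 1, "minimize")$prey,
               pos[1, ])
  # ties broken by lower index, under both senses
  tied <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_identical(compute_prey_position(tied, c(1, 1, 2), 1,
                                         "minimize")$alphas, 1L)
  expect_identical(compute_prey_position(tied, c(2, 2, 1), 1,
                                         "maximize")$alphas, 1L)
})

test_that("encircling update matches the printed distances and closed form", {
  spec <- quad_spec()
  upd <- encircling_update(c(1.977, -1.052), prey = c(-1.726, -3.864),
                           t = 1, Z_enc = 3, b = 1, spec)
  expect_equal(upd$D, c(3.703, 2.812), tolerance = 5e-3)
  expect_equal(upd$l, 1 / 3, tolerance = 1e-4)
  # at l = -1, cos(-2*pi) = 1 and the agent lands at prey + D * exp(-b)
  prey <- c(0.5, -0.5); x <- c(2, 1)
  upd2 <- encircling_update(x, prey, t = 3, Z_enc = 3, b = 1, spec)
  expect_equal(upd2$position, prey + abs(prey - x) * exp(-1), tolerance = 1e-12)
})

test_that("attacking update reproduces the worked candidate and is greedy", {
  spec <- quad_spec()
  upd <- attacking_update(c(-0.619, -2.527), value = -3.142,
                          prey = c(-0.970, -2.508), A = 0.237, C = 1.689, spec)
  expect_equal(upd$candidate, c(-1.211, -2.914), tolerance = 5e-3)
  expect_true(upd$accepted)
  expect_equal(upd$candidate_value, -4.650, tolerance = 5e-3)
  # A = 0 lands exactly on the prey
  upd0 <- attacking_update(c(1, 1), value = 11, prey = c(0.2, 0.1),
                           A = 0, C = 1.3, spec)
  expect_equal(upd0$candidate, c(0.2, 0.1))
  # worse candidate is rejected and the position kept
  at_min <- QUAD_ARGMIN
  updk <- attacking_update(at_min, value = spec$objective(at_min),
                           prey = c(4, 4), A = 0.9, C = 1.8, spec)
  expect_false(updk$accepted)
  expect_equal(updk$position, at_min)
})

test_that("greedy phase-best equals an exhaustive scan on random histories", {
  set.seed(42)
  for (i in 1:1000) {
    n_hist <- sample(1:10, 1)
    vals <- stats::rnorm(n_hist)
    pos <- matrix(stats::rnorm(n_hist * 3), n_hist, 3)
    sense <- sample(c("minimize", "maximize"), 1)
    g <- greedy_select_best(pos, vals, sense)
    # brute-force oracle: scan every entry
    best_i <- 1L
    for (j in seq_len(n_hist)) {
      if ((sense == "minimize" && vals[j] < vals[best_i]) ||
          (sense == "maximize" && vals[j] > vals[best_i])) best_i <- j
    }
    expect_identical(g$index, best_i)
    expect_identical(g$value, vals[best_i])
  }
  # length-1 history is the identity
  g1 <- greedy_select_best(matrix(1:2, 1), 5, "minimize")
  expect_equal(g1$position, 1:2)
})

test_that("cartesian distance matches a termwise brute-force oracle", {
  expect_equal(cartesian_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(cartesian_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(7)
  x <- stats::rnorm(7); y <- stats::rnorm(7)
  acc <- 0
  for (i in 1:7) acc <- acc + (x[i] - y[i])^2
  expect_equal(cartesian_distance(x, y), sqrt(acc))
  expect_equal(cartesian_distance(x, y), cartesian_distance(y, x))
  expect_error(cartesian_distance(1:2, 1:3), "equal length")
})

test_that("collision resolution relocates the weaker agent of close pairs", {
  spec <- quad_spec()
  pos <- rbind(c(0, 0), c(0.9, 0), c(4, 4))
  vals <- apply(pos, 1, spec$objective)
  set.seed(3)
  res <- detect_and_resolve_collisions(pos, vals, delta = 0.5, spec)
  weaker <- if (vals[1] > vals[2]) 1L else 2L
  stronger <- setdiff(1:2, weaker)
  expect_identical(res$relocated, weaker)
  expect_equal(res$positions[stronger, ], pos[stronger, ])
  expect_equal(res$positions[3, ], pos[3, ])
  expect_true(all(res$positions >= -5 & res$positions <= 5))
  expect_equal(res$values[weaker], spec$objective(res$positions[weaker, ]))
  # boundary: exactly 2*delta apart is NOT a collision (strict inequality)
  pos2 <- rbind(c(0, 0), c(1, 0))
  res2 <- detect_and_resolve_collisions(pos2, c(1, 2), delta = 0.5, spec)
  expect_length(res2$relocated, 0)
  expect_equal(res2$positions, pos2)
  # equal fitness: the lower-index agent stays
  set.seed(4)
  res3 <- detect_and_resolve_collisions(rbind(c(0, 0), c(0.1, 0)), c(1, 1),
                                        delta = 0.5, spec)
  expect_identical(res3$relocated, 2L)
})

test_that("scout selection produces the stated cluster sizes", {
  set.seed(10)
  sc <- select_scouts(10, 3)
  expect_length(sc$scouts, 3)
  expect_true(all(is.na(sc$cluster[sc$scouts])))
  sizes <- tabulate(sc$cluster, nbins = 3)
  expect_identical(sort(sizes, decreasing = TRUE), c(3L, 3L, 1L))
  # n = 7, lambda = 4 -> sizes (1,1,1,0) under the ceiling rule
  sc2 <- select_scouts(7, 4)
  expect_identical(sort(tabulate(sc2$cluster, nbins = 4),
                        decreasing = TRUE), c(1L, 1L, 1L, 0L))
  # single cluster holds all nine non-scouts
  sc3 <- select_scouts(10, 1)
  expect_identical(tabulate(sc3$cluster, nbins = 1), 9L)
  expect_error(select_scouts(5, 6), "lambda")
})
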