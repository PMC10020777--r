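test_that("sigmoid has the standard shape", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1), 0.731059, tolerance = 1e-6)
  expect_equal(sigmoid(100), 1)
  expect_equal(sigmoid(-100), 0, tolerance = 1e-30)
  x <- seq(-6, 6, by = 0.25)
  expect_true(all(diff(sigmoid(x)) > 0))
  expect_equal(sigmoid(-x), 1 - sigmoid(x))
})

test_that("binarize follows the printed rule and its conventional mirror", {
  # injected rand = 0.6 at x = 0 (sigmoid 0.5): paper rule -> 1, conventional -> 0
  expect_identical(binarize(0, rule = "paper", rand = 0.6), 1L)
  expect_identical(binarize(0, rule = "conventional", rand = 0.6), 0L)
  set.seed(21)
  big <- binarize(rep(-10, 1e5), rule = "paper")
  expect_gt(mean(big), 0.999) # sigmoid(-10) ~ 0 so rand >= it almost surely
  # empirical bit probabilities match 1 - sigmoid (paper) and sigmoid (conv.)
  for (x in c(-1, 0, 1.5)) {
    p_paper <- mean(binarize(rep(x, 1e5), rule = "paper"))
    p_conv <- mean(binarize(rep(x, 1e5), rule = "conventional"))
    expect_equal(p_paper, 1 - sigmoid(x), tolerance = 0.01)
    expect_equal(p_conv, sigmoid(x), tolerance = 0.01)
  }
  expect_true(all(binarize(stats::rnorm(100)) %in% c(0L, 1L)))
})

test_that("run_brpo is deterministic, monotone and never evaluates empty subsets", {
  mask <- c(1, 1, 1, rep(0, 9))
  fit <- function(bits) sum(bits[mask == 1]) - sum(bits[mask == 0])
  cfg <- rpo_config(n = 10, Z = 12, xi = 4, seed = 31)
  r1 <- run_brpo(fit, f = 12, config = cfg)
  r2 <- run_brpo(fit, f = 12, config = cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_bits, r2$best_bits)
  expect_true(all(unlist(lapply(r1$trace, function(tr)
    rowSums(tr$bits) >= 1))))
  expect_true(all(unlist(lapply(r1$trace, function(tr)
    tr$bits %in% c(0L, 1L)))))
  # best-so-far across the trace is nondecreasing
  best_per_iter <- vapply(r1$trace, function(tr) max(tr$values), numeric(1))
  expect_true(all(diff(cummax(best_per_iter)) >= 0))
  expect_gte(r1$best_fitness, max(best_per_iter) - 1e-12)
})

test_that("a single feature is always selected when f = 1", {
  r <- run_brpo(function(bits) 42, f = 1,
                config = rpo_config(n = 4, Z = 3, xi = 2, seed = 1))
  expect_identical(r$best_bits, 1L)
  expect_equal(r$best_fitness, 42)
})

test_that("constant fitness triggers the early stop at the first boundary", {
  cfg <- rpo_config(n = 6, Z = 30, xi = 3, seed = 9)
  r <- run_brpo(function(bits) 50, f = 8, config = cfg)
  expect_true(r$early_stopped)
  expect_identical(r$iterations_run, partition_iterations(30)$Z_srch)
  # explicit opt-out is honored
  cfg2 <- rpo_config(n = 6, Z = 30, xi = 3, seed = 9, early_stop = FALSE)
  r2 <- run_brpo(function(bits) 50, f = 8, config = cfg2)
  expect_identical(r2$iterations_run, 30L)
})

test_that("subset recovery beats a uniformly random baseline", {
  # fitness rewards bits inside a fixed 3-bit mask and punishes the rest
  mask <- c(1, 1, 1, rep(0, 9))
  fit <- function(bits) sum(bits[mask == 1]) - sum(bits[mask == 0])
  overlaps <- vapply(1:10, function(s) {
    r <- run_brpo(fit, f = 12, config = rpo_config(n = 20, Z = 30, xi = 4,
                                                   seed = s))
    sum(r$best_bits[mask == 1])
  }, numeric(1))
  # random-subset baseline: expected overlap of a uniform subset of the
  # median selected size, computed by simulation
  set.seed(1000)
  sizes <- vapply(1:10, function(s) {
    r <- run_brpo(fit, f = 12, config = rpo_config(n = 20, Z = 30, xi = 4,
                                                   seed = s))
    sum(r$best_bits)
  }, numeric(1))
  base <- replicate(2000, {
    pick <- sample.int(12, stats::median(sizes))
    sum(mask[pick])
  })
  expect_gte(stats::median(overlaps), stats::median(base))
  expect_gt(mean(overlaps), mean(base))
})
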