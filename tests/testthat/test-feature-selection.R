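test_that("preprocess imputes medians and modes deterministically", {
  raw <- rpo_dataset(
    data.frame(num = c(1, NA, 3, 10),
               cat = c("a", "b", NA, "b"),
               clean = c(0.5, 0.1, -0.2, 0)),
    labels = c("negative", "negative", "positive", "positive")
  )
  pp <- preprocess(raw)
  expect_true(is.matrix(pp$features))
  expect_false(anyNA(pp$features))
  expect_equal(pp$features[2, "num"], 3, ignore_attr = TRUE) # median of {1, 3, 10}
  expect_equal(pp$features[, "cat"], c(1, 2, 2, 2),
               ignore_attr = TRUE) # mode 'b' imputed, integer-coded
  expect_equal(pp$features[, "clean"], raw$features$clean,
               ignore_attr = TRUE) # no missing -> unchanged
  expect_identical(preprocess(raw)$features, pp$features)
  # all-missing columns are rejected
  bad <- rpo_dataset(data.frame(x = c(NA_real_, NA_real_), y = c(1, 2)),
                     labels = c("negative", "positive"))
  expect_error(preprocess(bad), "entirely missing")
  # 20% missingness leaves zero missing cells after preprocessing
  synth <- generate_clinical(synth_config(n_samples = 300, n_features = 20,
                                          n_informative = 4,
                                          missing_rate = 0.2, seed = 8))
  expect_gt(sum(is.na(as.matrix(synth$features))), 0)
  expect_identical(sum(is.na(preprocess(synth)$features)), 0L)
})

test_that("dataset round-trips through delimited text", {
  d <- generate_clinical(synth_config(n_samples = 50, n_features = 6,
                                      n_informative = 2, missing_rate = 0.1,
                                      categorical_fraction = 0.3, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_dataset(path, label_col = "label")
  expect_identical(as.character(back$labels), as.character(d$labels))
  expect_identical(back$feature_names, d$feature_names)
  expect_error(read_dataset(path, label_col = "nope"), "label column")
})

test_that("NB fitness is exact on separable data and deterministic", {
  d <- separable_dataset()
  pp <- preprocess(d)
  split <- nb_split(pp$labels, ratio = 0.7, seed = 5)
  expect_equal(nb_fitness(c(1, 0), pp, split), 100)
  expect_identical(nb_fitness(c(1, 1), pp, split),
                   nb_fitness(c(1, 1), pp, split))
  expect_error(nb_fitness(c(0, 0), pp, split), "empty")
  expect_error(nb_fitness(c(1, 0, 0), pp, split), "length")
})

test_that("NB accuracy is at chance on pure noise and near the Bayes rate", {
  # balanced classes, noise-only features -> accuracy near 50
  noise <- generate_clinical(synth_config(n_samples = 1200, n_features = 8,
                                          n_informative = 0,
                                          positive_fraction = 0.5,
                                          missing_rate = 0,
                                          categorical_fraction = 0, seed = 17))
  pp <- preprocess(noise)
  split <- nb_split(pp$labels, seed = 7)
  accs <- vapply(1:5, function(s)
    nb_fitness(rep(1, 8), pp, nb_split(pp$labels, seed = s)), numeric(1))
  expect_true(all(abs(accs - 50) <= 5))
  # one informative feature with effect size d: Bayes accuracy = pnorm(d/2)
  d <- 2
  tg <- two_gaussian_dataset(n = 4000, d = d)
  pp2 <- preprocess(tg)
  acc <- nb_fitness(1, pp2, nb_split(pp2$labels, seed = 2))
  expect_lt(abs(acc / 100 - stats::pnorm(d / 2)), 0.03)
})

test_that("metrics pool correctly and flag degenerate predictions", {
  # perfect classifier: every metric 1
  m <- evaluate_metrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(m$accuracy, 100)
  expect_equal(m$macro_precision, 1)
  expect_equal(m$macro_recall, 1)
  expect_equal(m$f_measure, 1)
  # binary counts TP=9 FP=1 FN=1 TN=89 -> micro precision = recall = 0.98
  truth <- c(rep("pos", 10), rep("neg", 90))
  pred <- c(rep("pos", 9), "neg", "pos", rep("neg", 89))
  m2 <- evaluate_metrics(truth, pred)
  expect_equal(m2$micro_precision, 0.98)
  expect_equal(m2$micro_recall, 0.98)
  expect_equal(m2$accuracy, 98)
  # all-one-class predictor: recalls 1 and 0, macro recall 0.5
  m3 <- evaluate_metrics(c("a", "a", "b", "b"), c("a", "a", "a", "a"))
  expect_equal(m3$macro_recall, 0.5)
  expect_identical(m3$zero_prediction_classes, "b")
  expect_equal(m3$per_class$precision[m3$per_class$class == "b"], 0)
  # property: micro precision = micro recall = accuracy/100 on random reports
  set.seed(33)
  for (i in 1:20) {
    t <- sample(c("x", "y", "z"), 50, replace = TRUE)
    p <- sample(c("x", "y", "z"), 50, replace = TRUE)
    mm <- evaluate_metrics(t, p)
    expect_equal(mm$micro_precision, mm$accuracy / 100)
    expect_equal(mm$micro_recall, mm$accuracy / 100)
    expect_true(all(c(mm$macro_precision, mm$macro_recall, mm$f_measure)
                    >= 0))
    expect_true(all(c(mm$macro_precision, mm$macro_recall, mm$f_measure)
                    <= 1))
  }
  expect_error(evaluate_metrics(1:3, 1:4), "equal length")
})

test_that("execution time metric is the plain product n * z", {
  expect_identical(execution_time_metric(25, 50), 1250L)
  expect_identical(execution_time_metric(10, 0), 0L)
  expect_identical(execution_time_metric(50, 37), 1850L)
  expect_error(execution_time_metric(-1, 5), "non-negative")
})

test_that("the experiment grid emits one well-formed row per cell", {
  d <- generate_clinical(synth_config(n_samples = 200, n_features = 10,
                                      n_informative = 3, missing_rate = 0.1,
                                      categorical_fraction = 0.2,
                                      positive_fraction = 0.3, seed = 12))
  rep <- run_fs_experiment(d, n_grid = c(6, 8), z_grid = c(6, 9),
                           xi = 3, k = 2, seed = 5)
  expect_identical(nrow(rep), 4L)
  expect_true(all(rep$n_selected >= 1))
  expect_true(all(rep$execution_time == rep$n * rep$z_realized))
  expect_true(all(abs(rep$micro_precision - rep$accuracy / 100) < 1e-12))
  # n * z is monotone in n at fixed z (full-budget cells)
  full <- rep[rep$z_realized == rep$z, ]
  if (nrow(full) >= 2) {
    for (z in unique(full$z)) {
      sub <- full[full$z == z, ]
      expect_true(all(diff(sub$execution_time[order(sub$n)]) >= 0))
    }
  }
  expect_true(all(rep$informative_overlap >= 0))
})
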