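#' Stratified train/test split
#'
#' Creates one fixed split per run so fitness values are comparable across
#' agents and iterations. Sampling is stratified by class: `ratio` of each
#' class goes to training (at least one sample of each class is kept on
#' both sides).
#'
#' @param labels Factor of class labels.
#' @param ratio Training fraction, default 0.7.
#' @param seed Integer seed for the split draw (independent of the
#'   optimizer seed).
#' @return List with integer vectors `train` and `test`.
#' @export
nb_split <- function(labels, ratio = 0.7, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  train <- integer(0)
  for (cl in levels(droplevels(labels))) {
    idx <- which(labels == cl)
    n_tr <- min(max(1L, round(ratio * length(idx))), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# Gaussian Naive Bayes: per-class feature means/variances with a variance
# floor to avoid degenerate likelihoods on (near-)constant columns.
nb_train <- function(X, y, var_floor = 1e-9) {
  y <- droplevels(y)
  classes <- levels(y)
  stats_by_class <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    v <- apply(Xc, 2, stats::var)
    v[!is.finite(v)] <- 0
    list(mu = mu, var = pmax(v, var_floor),
         log_prior = log(nrow(Xc) / nrow(X)))
  })
  names(stats_by_class) <- classes
  structure(list(classes = classes, stats = stats_by_class),
            class = "rpo_nb")
}

nb_predict <- function(model, X) {
  scores <- vapply(model$classes, function(cl) {
    s <- model$stats[[cl]]
    model$stats[[cl]]$log_prior +
      rowSums(matrix(stats::dnorm(t(X), mean = s$mu, sd = sqrt(s$var),
                                  log = TRUE),
                     ncol = ncol(X), byrow = TRUE))
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) scores <- matrix(scores, nrow = 1L)
  factor(model$classes[max.col(scores, ties.method = "first")],
         levels = model$classes)
}

#' Naive Bayes subset accuracy
#'
#' Wrapper fitness: trains a Gaussian Naive Bayes on the training partition
#' restricted to the selected feature columns and returns the percent
#' accuracy on the test partition. Deterministic given the data and split.
#'
#' @param bits Integer 0/1 vector over the feature columns; at least one 1.
#' @param data A preprocessed [rpo_dataset()] (numeric matrix features, no
#'   missing values; see [preprocess()]).
#' @param split A split from [nb_split()].
#' @param var_floor Variance floor of the Gaussian likelihoods.
#' @return Accuracy in `[0, 100]`.
#' @export
nb_fitness <- function(bits, data, split, var_floor = 1e-9) {
  stopifnot(inherits(data, "rpo_dataset"))
  X <- data$features
  if (!is.matrix(X) || !is.numeric(X) || anyNA(X)) {
    stop("`data` must be preprocessed first (numeric matrix, no NAs); see preprocess()",
         call. = FALSE)
  }
  bits <- as.integer(bits)
  if (length(bits) != ncol(X)) {
    stop("`bits` length must equal the feature count", call. = FALSE)
  }
  if (sum(bits) == 0L) {
    stop("cannot score the empty feature subset", call. = FALSE)
  }
  sel <- which(bits == 1L)
  model <- nb_train(X[split$train, sel, drop = FALSE], data$labels[split$train],
                    var_floor = var_floor)
  pred <- nb_predict(model, X[split$test, sel, drop = FALSE])
  truth <- factor(as.character(data$labels[split$test]),
                  levels = model$classes)
  100 * mean(pred == truth)
}

#' Build a cached NB fitness closure for [run_brpo()]
#'
#' @inheritParams nb_fitness
#' @return A function `bits -> percent accuracy` closed over the dataset and
#'   the fixed split.
#' @export
make_nb_fitness <- function(data, split, var_floor = 1e-9) {
  force(data); force(split); force(var_floor)
  function(bits) nb_fitness(bits, data, split, var_floor = var_floor)
}
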