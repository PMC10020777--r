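#' Synthetic clinical dataset configuration
#'
#' Default values emulate the shape of a public COVID-19 laboratory-test
#' table: 5644 cases, 110 mixed-type features, roughly 10 percent positive
#' class (559/5644), heavy missingness, and a small informative subset.
#' The statistical structure is deliberately simple: informative continuous
#' features are class-conditional unit-variance Gaussians separated by
#' `effect_size` standard deviations, all other features are class-blind
#' noise, a fraction of columns is discretized into quartile codes, and
#' missing cells are masked uniformly at random. Simplicity buys
#' analyzability - the Bayes error of each informative feature is known in
#' closed form, which the test-suite uses for calibration.
#'
#' @param n_samples Number of rows (default 5644).
#' @param n_features Number of feature columns (default 110).
#' @param n_informative Number of informative features (default 10).
#' @param positive_fraction Expected positive-class fraction (default
#'   559/5644).
#' @param effect_size Standardized mean shift of informative features
#'   between classes (default 1).
#' @param missing_rate Fraction of feature cells masked to `NA`, in
#'   `[0, 1)` (default 0.6, emulating heavily missing clinical panels).
#' @param categorical_fraction Fraction of columns discretized to quartile
#'   codes (default 0.2).
#' @param fixed_counts If `TRUE`, draw exactly
#'   `round(positive_fraction * n_samples)` positives; otherwise binomial
#'   sampling (default).
#' @param seed Integer seed.
#' @return Object of class `rpo_synth_config`.
#' @export
synth_config <- function(n_samples = 5644L, n_features = 110L,
                         n_informative = 10L,
                         positive_fraction = 559 / 5644,
                         effect_size = 1, missing_rate = 0.6,
                         categorical_fraction = 0.2,
                         fixed_counts = FALSE, seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_features <- as.integer(n_features)
  n_informative <- as.integer(n_informative)
  if (n_samples < 4L) stop("`n_samples` too small", call. = FALSE)
  if (n_informative < 0L || n_informative > n_features) {
    stop("`n_informative` must lie in [0, n_features]", call. = FALSE)
  }
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop("`positive_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  if (categorical_fraction < 0 || categorical_fraction > 1) {
    stop("`categorical_fraction` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_samples = n_samples, n_features = n_features,
         n_informative = n_informative,
         positive_fraction = positive_fraction, effect_size = effect_size,
         missing_rate = missing_rate,
         categorical_fraction = categorical_fraction,
         fixed_counts = isTRUE(fixed_counts), seed = as.integer(seed)),
    class = "rpo_synth_config"
  )
}

#' Generate a synthetic clinical-style classification table
#'
#' See [synth_config()] for the generative model. The first
#' `n_informative` columns carry the class signal (their indices are
#' returned in `informative_mask`); categorical columns are chosen at
#' random, preferring noise columns first so that discretization does not
#' silently erode the configured effect size unless more categorical
#' columns are requested than noise columns exist.
#'
#' @param cfg An [synth_config()].
#' @return An [rpo_dataset()] with raw features (a data.frame containing
#'   `NA`s and character-coded categorical columns) and the ground-truth
#'   `informative_mask`.
#' @examples
#' d <- generate_clinical(synth_config(n_samples = 200, n_features = 12,
#'                                     n_informative = 3, seed = 42))
#' table(d$labels)
#' @export
generate_clinical <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "rpo_synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  f <- cfg$n_features

  n_pos <- if (cfg$fixed_counts) {
    round(cfg$positive_fraction * n)
  } else {
    stats::rbinom(1, n, cfg$positive_fraction)
  }
  n_pos <- min(max(n_pos, 2L), n - 2L) # both classes on both split sides
  y <- rep("negative", n)
  y[sample.int(n, n_pos)] <- "positive"

  X <- matrix(stats::rnorm(n * f), n, f)
  if (cfg$n_informative > 0L) {
    shift <- matrix(cfg$effect_size,
                    nrow = sum(y == "positive"), ncol = cfg$n_informative)
    X[y == "positive", seq_len(cfg$n_informative)] <-
      X[y == "positive", seq_len(cfg$n_informative)] + shift
  }
  mask <- c(rep(1L, cfg$n_informative), rep(0L, f - cfg$n_informative))

  df <- as.data.frame(X)
  names(df) <- sprintf("feat_%03d", seq_len(f))

  n_cat <- round(cfg$categorical_fraction * f)
  if (n_cat > 0L) {
    shuf <- function(v) if (length(v) <= 1L) v else sample(v)
    noise_first <- c(shuf(which(mask == 0L)), shuf(which(mask == 1L)))
    cat_cols <- noise_first[seq_len(n_cat)]
    for (j in cat_cols) {
      q <- stats::quantile(df[[j]], probs = c(0.25, 0.5, 0.75))
      df[[j]] <- paste0("level_", findInterval(df[[j]], q) + 1L)
    }
  }

  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * f) < cfg$missing_rate, n, f)
    # never blank out a whole column
    for (j in seq_len(f)) if (all(miss[, j])) miss[sample.int(n, 1L), j] <- FALSE
    for (j in seq_len(f)) df[[j]][miss[, j]] <- NA
  }

  rpo_dataset(df, y, feature_names = names(df), informative_mask = mask)
}
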