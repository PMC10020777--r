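# shared fixtures built in code

quad_spec <- function() builtin_objective("quadratic2d")

# analytic optimum of the example quadratic
QUAD_MIN <- -19 / 3
QUAD_ARGMIN <- c(-8 / 3, -10 / 3)

# small, fully separable dataset: one feature splits the classes at 0
separable_dataset <- function(n = 60) {
  x <- c(seq(-3, -1, length.out = n / 2), seq(1, 3, length.out = n / 2))
  noise <- rep(c(0.3, -0.2, 0.1), length.out = n)
  rpo_dataset(
    cbind(signal = x, junk = noise),
    labels = rep(c("negative", "positive"), each = n / 2)
  )
}

# deterministic balanced two-gaussian dataset for NB calibration
two_gaussian_dataset <- function(n = 4000, d = 2, seed = 99) {
  set.seed(seed)
  y <- rep(c("negative", "positive"), each = n / 2)
  x <- stats::rnorm(n) + ifelse(y == "positive", d, 0)
  rpo_dataset(cbind(f1 = x), labels = y)
}
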