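#' Define a box-bounded objective
#'
#' Bundles a scalar objective function with its search box and optimization
#' sense. All optimizer routines consume this object; positions are always
#' clamped back into `[lower, upper]` componentwise after an update.
#'
#' @param objective Function mapping a numeric vector of length
#'   `length(lower)` to a single finite numeric value. Must be pure.
#' @param lower,upper Numeric vectors of equal length giving the box bounds;
#'   `lower[i] < upper[i]` is required for every component.
#' @param sense `"minimize"` (default) or `"maximize"`. "Best" always means
#'   optimal under this sense.
#' @param name Optional display name.
#' @return An object of class `rpo_objective` with fields `objective`,
#'   `lower`, `upper`, `dimension`, `sense`, `name`.
#' @examples
#' sp <- objective_spec(function(x) sum(x^2), lower = c(-5, -5), upper = c(5, 5))
#' sp$dimension
#' @export
objective_spec <- function(objective, lower, upper,
                           sense = c("minimize", "maximize"),
                           name = NULL) {
  sense <- match.arg(sense)
  if (!is.function(objective)) {
    stop("`objective` must be a function", call. = FALSE)
  }
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) < 1L) {
    stop("`lower` and `upper` must be numeric vectors of equal positive length",
         call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop("bounds must be finite with lower[i] < upper[i] for all i",
         call. = FALSE)
  }
  structure(
    list(objective = objective, lower = lower, upper = upper,
         dimension = length(lower), sense = sense,
         name = if (is.null(name)) "objective" else as.character(name)),
    class = "rpo_objective"
  )
}

#' @export
print.rpo_objective <- function(x, ...) {
  cat(sprintf("<rpo_objective> %s: %d-dimensional, %s\n",
              x$name, x$dimension, x$sense))
  cat("  lower:", paste(signif(x$lower, 4), collapse = ", "), "\n")
  cat("  upper:", paste(signif(x$upper, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Built-in benchmark objectives
#'
#' Registry of ready-made objective specifications:
#' \describe{
#'   \item{`"quadratic2d"`}{\eqn{f(x) = x_1^2 - x_1 x_2 + x_2^2 + 2 x_1 +
#'     4 x_2 + 3} on \eqn{[-5,5]^2}, minimized. Its analytic minimum is
#'     \eqn{-19/3} at \eqn{(-8/3, -10/3)}.}
#'   \item{`"sphere"`}{\eqn{f(x) = \sum_i x_i^2} on \eqn{[-5,5]^u},
#'     minimized.}
#' }
#'
#' @param name Objective name.
#' @param dimension Dimensionality, only used by objectives of free dimension
#'   (`"sphere"`); `"quadratic2d"` is fixed at 2.
#' @return An [objective_spec()] object.
#' @examples
#' builtin_objective("quadratic2d")$objective(c(-8 / 3, -10 / 3))
#' @export
builtin_objective <- function(name = c("quadratic2d", "sphere"),
                              dimension = 2L) {
  name <- match.arg(name)
  switch(name,
    quadratic2d = objective_spec(
      function(x) x[1]^2 - x[1] * x[2] + x[2]^2 + 2 * x[1] + 4 * x[2] + 3,
      lower = c(-5, -5), upper = c(5, 5), sense = "minimize",
      name = "quadratic2d"
    ),
    sphere = objective_spec(
      function(x) sum(x^2),
      lower = rep(-5, dimension), upper = rep(5, dimension),
      sense = "minimize", name = "sphere"
    )
  )
}

# clamp a position back into the box, componentwise
clamp_box <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

# evaluate the objective, failing loudly on non-finite values
eval_objective <- function(spec, x, context = NULL) {
  v <- spec$objective(x)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    stop(sprintf("objective returned a non-finite value%s at position (%s)",
                 if (is.null(context)) "" else paste0(" [", context, "]"),
                 paste(signif(x, 6), collapse = ", ")),
         call. = FALSE)
  }
  as.numeric(v)
}

# TRUE if `a` is strictly better than `b` under the sense
is_better <- function(a, b, sense) {
  if (sense == "minimize") a < b else a > b
}

# index of the best value under the sense; ties broken by lowest index
which_best <- function(values, sense) {
  if (sense == "minimize") which.min(values) else which.max(values)
}
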