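#' Optimizer configuration
#'
#' Collects the run parameters shared by the continuous optimizer
#' ([run_rpo()]) and the binary variant ([run_brpo()]).
#'
#' @param n Number of search agents (population size).
#' @param Z Total number of iterations; split uniformly over the three
#'   phases by [partition_iterations()], so `Z >= 3`.
#' @param xi Scaling factor controlling the scout count,
#'   `2 <= xi <= n`; the number of scouts is `lambda = ceiling(n / xi)`.
#' @param k Number of alpha (leader) agents whose mean position defines the
#'   virtual prey during the encircling and attacking phases; validated
#'   against `1 <= k <= n`, default `min(3, n)`.
#' @param b Shape constant of the logarithmic spiral used in the encircling
#'   phase (default 1).
#' @param delta Safety-shield half-width; two agents closer than `2 * delta`
#'   are in collision (default 0).
#' @param n_ck Number of collision checkpoints in the attacking phase
#'   (default 0 = no checkpoints).
#' @param collision Logical; enable collision detection at checkpoint
#'   iterations (default `FALSE`).
#' @param seed Integer seed driving every random draw of a run.
#' @param early_stop Logical; stop the run at a phase boundary once the
#'   global best improves by less than `early_stop_tol` over the phase.
#'   Default `FALSE` for the continuous optimizer ([run_brpo()] defaults it
#'   to `TRUE`).
#' @param early_stop_tol Plateau tolerance for the early stop (default
#'   `1e-7`).
#' @return An object of class `rpo_config`.
#' @examples
#' cfg <- rpo_config(n = 10, Z = 11, xi = 4, seed = 1)
#' cfg$lambda
#' @export
rpo_config <- function(n = 10L, Z = 50L, xi = 4, k = min(3L, n), b = 1,
                       delta = 0, n_ck = 0L, collision = FALSE,
                       seed = 1L, early_stop = FALSE,
                       early_stop_tol = 1e-7) {
  n <- as.integer(n)
  Z <- as.integer(Z)
  if (n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  if (Z < 3L) stop("`Z` must be at least 3 (one iteration per phase)",
                   call. = FALSE)
  if (xi < 2 || xi > n) {
    stop("`xi` must satisfy 2 <= xi <= n", call. = FALSE)
  }
  lambda <- as.integer(ceiling(n / xi))
  if (lambda < 1L || lambda > n) {
    stop("derived scout count lambda = ceiling(n/xi) is out of [1, n]",
         call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L || k > n) stop("`k` must satisfy 1 <= k <= n", call. = FALSE)
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  n_ck <- as.integer(n_ck)
  if (n_ck < 0L) stop("`n_ck` must be >= 0", call. = FALSE)
  structure(
    list(n = n, Z = Z, xi = xi, lambda = lambda, k = k, b = b,
         delta = delta, n_ck = n_ck, collision = isTRUE(collision),
         seed = as.integer(seed), early_stop = isTRUE(early_stop),
         # records whether the caller set early_stop explicitly, so the
         # binary variant can default it to TRUE without overriding users
         early_stop_set = if (missing(early_stop)) NULL else TRUE,
         early_stop_tol = early_stop_tol),
    class = "rpo_config"
  )
}

#' @export
print.rpo_config <- function(x, ...) {
  cat("<rpo_config>\n")
  cat(sprintf("  agents n = %d, iterations Z = %d (split %s)\n",
              x$n, x$Z, paste(unlist(partition_iterations(x$Z)),
                              collapse = "/")))
  cat(sprintf("  xi = %g -> lambda = %d scouts; k = %d alphas; b = %g\n",
              x$xi, x$lambda, x$k, x$b))
  cat(sprintf("  collision = %s (delta = %g, n_ck = %d); seed = %d\n",
              x$collision, x$delta, x$n_ck, x$seed))
  cat(sprintf("  early stop = %s (tol %g)\n", x$early_stop,
              x$early_stop_tol))
  invisible(x)
}
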