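#' Split the iteration budget over the three phases
#'
#' The total budget `Z` is distributed uniformly: searching and encircling
#' each receive `floor(Z/3)` iterations and attacking takes the remainder
#' `Z - 2 * floor(Z/3)`, so the attacking phase absorbs the one or two
#' leftover iterations.
#'
#' @param Z Total iteration count, `Z >= 3`.
#' @return A list of class `rpo_schedule` with integer fields `Z`,
#'   `Z_srch`, `Z_enc`, `Z_att` summing to `Z`.
#' @examples
#' partition_iterations(10) # 3 / 3 / 4
#' @export
partition_iterations <- function(Z) {
  Z <- as.integer(Z)
  if (is.na(Z) || Z < 3L) {
    stop("`Z` must be an integer >= 3 so each phase runs at least once",
         call. = FALSE)
  }
  third <- Z %/% 3L
  structure(
    list(Z = Z, Z_srch = third, Z_enc = third, Z_att = Z - 2L * third),
    class = "rpo_schedule"
  )
}

#' Spiral parameter schedule for the encircling phase
#'
#' `l = 1 - 2 t / Z_enc` decreases strictly from just under 1 down to
#' exactly -1 at the last encircling iteration; it controls both the radius
#' (through `exp(b * l)`) and the angle (through `cos(2 * pi * l)`) of the
#' logarithmic spiral.
#'
#' @param t Iteration index within the phase, `1 <= t <= Z_enc`.
#' @param Z_enc Number of encircling iterations.
#' @return The scalar `l`.
#' @export
encircling_l_schedule <- function(t, Z_enc) {
  if (Z_enc < 1L) stop("encircling phase is empty (Z_enc = 0)", call. = FALSE)
  if (any(t < 1L) || any(t > Z_enc)) {
    stop("`t` must lie in [1, Z_enc]", call. = FALSE)
  }
  1 - 2 * t / Z_enc
}

#' Attack coefficient schedule
#'
#' `a = 2 - 2 t / Z_att` decreases linearly from just under 2 to exactly 0
#' at the final attacking iteration. The attack coefficient is then drawn as
#' `A = 2 * a * r1 - a`, uniform on `[-a, a]`, so late iterations take ever
#' smaller steps around the prey.
#'
#' @param t Iteration index within the phase, `1 <= t <= Z_att`.
#' @param Z_att Number of attacking iterations.
#' @return The scalar `a`.
#' @export
attack_coefficient_schedule <- function(t, Z_att) {
  if (Z_att < 1L) stop("attacking phase is empty (Z_att = 0)", call. = FALSE)
  if (any(t < 1L) || any(t > Z_att)) {
    stop("`t` must lie in [1, Z_att]", call. = FALSE)
  }
  2 - t * (2 / Z_att)
}

#' Checkpoint iterations for collision detection
#'
#' Collision checks in the attacking phase run only at checkpoint
#' iterations. With `n_ck` uniformly placed checkpoints the i-th check runs
#' after iteration `floor(Z_att / n_ck) * i - 1`; indices falling outside
#' `[1, Z_att]` are dropped, and `n_ck = 0` disables checkpointing.
#'
#' @param Z_att Number of attacking iterations.
#' @param n_ck Number of requested checkpoints, `>= 0`.
#' @return Sorted integer vector of checkpoint iterations (possibly empty).
#' @examples
#' checkpoint_iterations(7, 3) # 1, 3, 5
#' @export
checkpoint_iterations <- function(Z_att, n_ck) {
  Z_att <- as.integer(Z_att)
  n_ck <- as.integer(n_ck)
  if (n_ck < 0L) stop("`n_ck` must be >= 0", call. = FALSE)
  if (n_ck == 0L || Z_att < 1L) return(integer(0))
  idx <- (Z_att %/% n_ck) * seq_len(n_ck) - 1L
  sort(unique(idx[idx >= 1L & idx <= Z_att]))
}
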