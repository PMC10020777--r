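#' Draw the searching-phase coefficient pair
#'
#' One scalar pair `(A, C)` is drawn per agent per searching iteration and
#' broadcast over all components. The exploration coefficient is
#' `A = r1 * (-2 + r2) + (1 - r1) * (1 + r3)` with `r1` a fair coin,
#' `r2` uniform on `[0, 1)` and `r3` uniform on `(0, 1]`, so `A` always has
#' magnitude in `(1, 2]` (support `[-2, -1) U (1, 2]`) and agents are pushed
#' far away from their reference scout. `C = 2 * r4` with `r4` uniform on
#' `[0, 1]` perturbs the scout position inside the distance term.
#'
#' @param r Optional list with fields `r1`, `r2`, `r3`, `r4` to inject fixed
#'   draws (used by the worked-example replay); when `NULL` the draws come
#'   from the current RNG state in the order r1, r2, r3, r4.
#' @return List with numeric scalars `A` and `C`.
#' @export
sample_search_coefficients <- function(r = NULL) {
  if (is.null(r)) {
    r <- list(r1 = as.numeric(stats::runif(1) < 0.5), r2 = stats::runif(1),
              r3 = 1 - stats::runif(1), r4 = stats::runif(1))
  }
  A <- r$r1 * (-2 + r$r2) + (1 - r$r1) * (1 + r$r3)
  C <- 2 * r$r4
  list(A = A, C = C)
}

#' Searching-phase position update
#'
#' A non-scout agent moves relative to the scout of its cluster:
#' `D = |C * X_sct - X|` componentwise and `X_new = X_sct - A * D`, clamped
#' back into the box.
#'
#' @param position Current agent position.
#' @param scout_position Position of the agent's cluster scout.
#' @param A,C Coefficient pair from [sample_search_coefficients()].
#' @param spec An [objective_spec()].
#' @param context Optional string naming the agent/iteration for error
#'   messages.
#' @return List with `position` (clamped), `value` (objective there) and
#'   `raw` (the unclamped update, useful for bound diagnostics).
#' @export
searching_update <- function(position, scout_position, A, C, spec,
                             context = NULL) {
  D <- abs(C * scout_position - position)
  raw <- scout_position - A * D
  new_pos <- clamp_box(raw, spec$lower, spec$upper)
  list(position = new_pos, value = eval_objective(spec, new_pos, context),
       raw = raw, D = D)
}

#' Virtual prey position
#'
#' The prey (the unknown optimum) is approximated by the componentwise mean
#' of the positions of the `k` best agents under the optimization sense;
#' ranking ties are broken by lower agent index.
#'
#' @param positions Numeric matrix, one agent per row.
#' @param values Objective value per agent.
#' @param k Number of alpha agents, `1 <= k <= nrow(positions)`.
#' @param sense `"minimize"` or `"maximize"`.
#' @return List with `prey` (numeric vector) and `alphas` (the row indices
#'   of the k leaders in rank order).
#' @export
compute_prey_position <- function(positions, values, k,
                                  sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  n <- nrow(positions)
  if (k < 1 || k > n) stop("`k` must satisfy 1 <= k <= n", call. = FALSE)
  ord <- if (identical(sense, "maximize")) {
    order(-values, seq_len(n)) # tie -> lower index, also when maximizing
  } else {
    order(values, seq_len(n))
  }
  alphas <- ord[seq_len(k)]
  prey <- colMeans(positions[alphas, , drop = FALSE])
  list(prey = prey, alphas = alphas)
}

#' Encircling-phase spiral update
#'
#' The agent spirals around the virtual prey: with `D = |X_prey - X|` and
#' `l = 1 - 2 t / Z_enc`, the new position is
#' `X_new = D * exp(b * l) * cos(2 * pi * l) + X_prey`, clamped into the
#' box. At the final encircling iteration `l = -1` and the agent lands at
#' `X_prey + D * exp(-b)`.
#'
#' @inheritParams searching_update
#' @param prey Virtual prey position.
#' @param t Iteration index within the encircling phase.
#' @param Z_enc Number of encircling iterations.
#' @param b Spiral shape constant.
#' @return List with `position`, `value`, `D` and `l`.
#' @export
encircling_update <- function(position, prey, t, Z_enc, b, spec,
                              context = NULL) {
  l <- encircling_l_schedule(t, Z_enc)
  D <- abs(prey - position)
  raw <- D * exp(b * l) * cos(2 * pi * l) + prey
  new_pos <- clamp_box(raw, spec$lower, spec$upper)
  list(position = new_pos, value = eval_objective(spec, new_pos, context),
       D = D, l = l)
}

#' Attacking-phase update with per-step greedy retention
#'
#' The candidate `X_prey - A * |C * X_prey - X|` (clamped) replaces the
#' current position only if it improves the objective under the sense;
#' otherwise the agent keeps its position, ready to strike again.
#'
#' @inheritParams searching_update
#' @param value Objective value at `position`.
#' @param prey Virtual prey position.
#' @return List with `position`, `value` (the retained pair),
#'   `candidate`, `candidate_value` and `accepted`.
#' @export
attacking_update <- function(position, value, prey, A, C, spec,
                             context = NULL) {
  D <- abs(C * prey - position)
  raw <- prey - A * D
  cand <- clamp_box(raw, spec$lower, spec$upper)
  cand_val <- eval_objective(spec, cand, context)
  if (is_better(cand_val, value, spec$sense)) {
    list(position = cand, value = cand_val, candidate = cand,
         candidate_value = cand_val, accepted = TRUE, D = D)
  } else {
    list(position = position, value = value, candidate = cand,
         candidate_value = cand_val, accepted = FALSE, D = D)
  }
}

#' End-of-phase greedy selection
#'
#' After the searching and encircling phases each agent scans every position
#' it visited during the phase (including the position it entered the phase
#' with) and returns to the best one under the sense; ties keep the earliest
#' entry.
#'
#' @param history_positions Matrix of visited positions, one per row.
#' @param history_values Objective value per row.
#' @param sense `"minimize"` or `"maximize"`.
#' @return List with `position`, `value` and `index` of the chosen entry.
#' @export
greedy_select_best <- function(history_positions, history_values,
                               sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  if (length(history_values) < 1L) {
    stop("history is empty", call. = FALSE)
  }
  i <- which_best(history_values, sense)
  list(position = history_positions[i, ], value = history_values[i],
       index = i)
}

#' Euclidean distance between two agents
#'
#' @param x,y Numeric vectors of equal length.
#' @return The Euclidean norm of `x - y`.
#' @export
cartesian_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  sqrt(sum((x - y)^2))
}

#' Detect and resolve agent collisions
#'
#' Every unordered pair of agents strictly closer than `2 * delta` is in
#' collision: the agent with the worse objective value (ties: the higher
#' index) escapes to a fresh uniform position in the box and its objective
#' is recomputed. All pairs are evaluated against the pre-resolution
#' positions in a single sweep, then all escapes are applied.
#'
#' @param positions Numeric matrix, one agent per row.
#' @param values Objective value per agent.
#' @param delta Safety-shield half-width (`>= 0`); `delta = 0` disables all
#'   collisions because the condition is strict.
#' @param spec An [objective_spec()].
#' @return List with updated `positions`, `values` and the integer vector
#'   `relocated` of escaped agent indices.
#' @export
detect_and_resolve_collisions <- function(positions, values, delta, spec) {
  n <- nrow(positions)
  relocate <- logical(n)
  if (delta > 0 && n >= 2L) {
    for (g in seq_len(n - 1L)) {
      for (h in seq.int(g + 1L, n)) {
        if (cartesian_distance(positions[g, ], positions[h, ]) < 2 * delta) {
          loser <- if (is_better(values[h], values[g], spec$sense)) g else h
          relocate[loser] <- TRUE
        }
      }
    }
  }
  for (m in which(relocate)) {
    positions[m, ] <- spec$lower +
      stats::runif(spec$dimension) * (spec$upper - spec$lower)
    values[m] <- eval_objective(spec, positions[m, ],
                                context = paste0("collision escape of agent ", m))
  }
  list(positions = positions, values = values, relocated = which(relocate))
}

#' Draw scouts and cluster assignments
#'
#' `lambda` agents are drawn uniformly to act as scouts for one searching
#' iteration; the remaining agents are shuffled and dealt into `lambda`
#' clusters of `ceiling((n - lambda) / lambda)` members each, with trailing
#' clusters possibly smaller (or empty) when the division is uneven.
#'
#' @param n Number of agents.
#' @param lambda Number of scouts, `1 <= lambda <= n`.
#' @return List with `scouts` (integer vector of length `lambda`) and
#'   `cluster` (integer vector of length `n`: cluster id of each member,
#'   `NA` for scouts). Member `m` of cluster `i` is led by agent
#'   `scouts[i]`.
#' @export
select_scouts <- function(n, lambda) {
  if (lambda < 1 || lambda > n) {
    stop("`lambda` must satisfy 1 <= lambda <= n", call. = FALSE)
  }
  scouts <- sample.int(n, lambda)
  members <- setdiff(seq_len(n), scouts)
  members <- if (length(members) > 1L) sample(members) else members
  cluster <- rep(NA_integer_, n)
  if (length(members) > 0L) {
    size <- ceiling(length(members) / lambda)
    ids <- rep(seq_len(lambda), each = size)[seq_along(members)]
    cluster[members] <- ids
  }
  list(scouts = scouts, cluster = cluster)
}
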