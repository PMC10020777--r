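#' Run the continuous red piranha optimizer
#'
#' Executes the three sequential phases on a box-bounded objective:
#' \enumerate{
#'   \item \strong{Searching} (`floor(Z/3)` iterations): each iteration
#'     draws `lambda` scouts and deals the remaining agents into clusters;
#'     non-scouts take large, coefficient-driven steps relative to their
#'     cluster scout (exploration). Scouts hold their positions for the
#'     iteration. Greedy selection at the end of the phase returns every
#'     agent to the best position it visited.
#'   \item \strong{Encircling} (`floor(Z/3)` iterations): the virtual prey
#'     is recomputed each iteration as the mean of the `k` best agents, and
#'     every agent moves along a contracting logarithmic spiral around it;
#'     greedy selection again closes the phase.
#'   \item \strong{Attacking} (remaining iterations): agents strike at the
#'     prey with a shrinking coefficient (`a` decays linearly to 0) and keep
#'     a new position only if it improves (per-step greedy). Optional
#'     collision detection runs at checkpoint iterations: of any pair closer
#'     than `2 * delta`, the weaker agent escapes to a random position.
#' }
#'
#' All randomness flows from `config$seed`, set once at the start; the draw
#' order is: initialization (agent by agent), then per searching iteration
#' the scout/cluster draws followed by per-agent coefficient draws in agent
#' index order, then per attacking iteration the per-agent `r1`, `r2` draws
#' and any collision escapes. Identical seeds give identical traces.
#'
#' @param spec An [objective_spec()].
#' @param config An [rpo_config()].
#' @return An object of class `rpo_result`: list with `best_position`,
#'   `best_fitness`, `trace` (one record per executed iteration with fields
#'   `phase`, `t`, `positions`, `values` and, where defined, `prey`),
#'   `iterations_run` (realized iteration count `z_o` if the early stop
#'   fired, else `Z`), `schedule`, `config`, and `spec_name`.
#' @examples
#' res <- run_rpo(builtin_objective("quadratic2d"),
#'                rpo_config(n = 10, Z = 12, xi = 4, seed = 7))
#' res$best_fitness
#' @export
run_rpo <- function(spec, config) {
  stopifnot(inherits(spec, "rpo_objective"), inherits(config, "rpo_config"))
  set.seed(config$seed)
  sched <- partition_iterations(config$Z)
  n <- config$n
  u <- spec$dimension
  sense <- spec$sense

  # initialization: x = lower + rand * (upper - lower), agent by agent
  positions <- matrix(NA_real_, n, u)
  for (m in seq_len(n)) {
    positions[m, ] <- spec$lower + stats::runif(u) * (spec$upper - spec$lower)
  }
  values <- vapply(seq_len(n), function(m)
    eval_objective(spec, positions[m, ], context = paste0("init agent ", m)),
    numeric(1))

  best_idx <- which_best(values, sense)
  best_position <- positions[best_idx, ]
  best_fitness <- values[best_idx]
  trace <- list()
  iterations_run <- 0L
  stopped <- FALSE

  note_best <- function(pos_mat, val_vec) {
    i <- which_best(val_vec, sense)
    if (is_better(val_vec[i], best_fitness, sense)) {
      best_position <<- pos_mat[i, ]
      best_fitness <<- val_vec[i]
    }
  }

  plateaued <- function(before, after) {
    config$early_stop && abs(before - after) < config$early_stop_tol
  }

  # -- searching phase ------------------------------------------------------
  best_before <- best_fitness
  hist_pos <- lapply(seq_len(n), function(m) positions[m, , drop = FALSE])
  hist_val <- lapply(seq_len(n), function(m) values[m])
  for (t in seq_len(sched$Z_srch)) {
    sc <- select_scouts(n, config$lambda)
    for (m in seq_len(n)) {
      if (m %in% sc$scouts) next
      coef <- sample_search_coefficients()
      upd <- searching_update(positions[m, ], positions[sc$scouts[sc$cluster[m]], ],
                              coef$A, coef$C, spec,
                              context = sprintf("searching t=%d agent %d", t, m))
      positions[m, ] <- upd$position
      values[m] <- upd$value
      hist_pos[[m]] <- rbind(hist_pos[[m]], upd$position)
      hist_val[[m]] <- c(hist_val[[m]], upd$value)
    }
    iterations_run <- iterations_run + 1L
    trace[[length(trace) + 1L]] <- list(phase = "searching", t = t,
                                        positions = positions, values = values,
                                        scouts = sc$scouts)
  }
  for (m in seq_len(n)) {
    g <- greedy_select_best(hist_pos[[m]], hist_val[[m]], sense)
    positions[m, ] <- g$position
    values[m] <- g$value
  }
  note_best(positions, values)
  if (plateaued(best_before, best_fitness)) stopped <- TRUE

  # -- encircling phase -----------------------------------------------------
  if (!stopped && sched$Z_enc > 0L) {
    best_before <- best_fitness
    hist_pos <- lapply(seq_len(n), function(m) positions[m, , drop = FALSE])
    hist_val <- lapply(seq_len(n), function(m) values[m])
    for (t in seq_len(sched$Z_enc)) {
      pp <- compute_prey_position(positions, values, config$k, sense)
      for (m in seq_len(n)) {
        upd <- encircling_update(positions[m, ], pp$prey, t, sched$Z_enc,
                                 config$b, spec,
                                 context = sprintf("encircling t=%d agent %d", t, m))
        positions[m, ] <- upd$position
        values[m] <- upd$value
        hist_pos[[m]] <- rbind(hist_pos[[m]], upd$position)
        hist_val[[m]] <- c(hist_val[[m]], upd$value)
      }
      iterations_run <- iterations_run + 1L
      trace[[length(trace) + 1L]] <- list(phase = "encircling", t = t,
                                          positions = positions,
                                          values = values, prey = pp$prey)
    }
    for (m in seq_len(n)) {
      g <- greedy_select_best(hist_pos[[m]], hist_val[[m]], sense)
      positions[m, ] <- g$position
      values[m] <- g$value
    }
    note_best(positions, values)
    if (plateaued(best_before, best_fitness)) stopped <- TRUE
  }

  # -- attacking phase ------------------------------------------------------
  if (!stopped && sched$Z_att > 0L) {
    ck <- if (config$collision) {
      checkpoint_iterations(sched$Z_att, config$n_ck)
    } else integer(0)
    for (t in seq_len(sched$Z_att)) {
      pp <- compute_prey_position(positions, values, config$k, sense)
      a <- attack_coefficient_schedule(t, sched$Z_att)
      for (m in seq_len(n)) {
        A <- 2 * a * stats::runif(1) - a
        C <- 2 * stats::runif(1)
        upd <- attacking_update(positions[m, ], values[m], pp$prey, A, C, spec,
                                context = sprintf("attacking t=%d agent %d", t, m))
        positions[m, ] <- upd$position
        values[m] <- upd$value
      }
      note_best(positions, values) # before any collision escape discards a value
      if (t %in% ck) {
        res <- detect_and_resolve_collisions(positions, values,
                                             config$delta, spec)
        positions <- res$positions
        values <- res$values
      }
      iterations_run <- iterations_run + 1L
      trace[[length(trace) + 1L]] <- list(phase = "attacking", t = t,
                                          positions = positions,
                                          values = values, prey = pp$prey)
      note_best(positions, values)
    }
  }

  structure(
    list(best_position = best_position, best_fitness = best_fitness,
         trace = trace, iterations_run = iterations_run,
         schedule = sched, config = config, spec_name = spec$name,
         early_stopped = stopped),
    class = "rpo_result"
  )
}

#' @export
print.rpo_result <- function(x, ...) {
  cat("<rpo_result>", x$spec_name, "\n")
  cat(sprintf("  best fitness: %.6g\n", x$best_fitness))
  cat("  best position:", paste(signif(x$best_position, 6), collapse = ", "),
      "\n")
  cat(sprintf("  iterations run: %d of %d%s\n", x$iterations_run,
              x$schedule$Z, if (x$early_stopped) " (early stop)" else ""))
  invisible(x)
}
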