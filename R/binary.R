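#' Sigmoid transfer function
#'
#' `1 / (1 + exp(-x))`, mapping a continuous position component to a
#' probability used by [binarize()].
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

#' Binarize a continuous position
#'
#' Converts a real-valued position update to a bit vector, one independent
#' uniform draw per component. Two transfer rules are available:
#' \describe{
#'   \item{`"paper"` (default)}{bit = 1 iff `rand >= sigmoid(x)`. Note this
#'     inverts the conventional transfer: larger components make a 1 LESS
#'     likely. It is kept as the default because it is the printed rule of
#'     the source method; selection pressure then comes from greedy
#'     retention rather than from the transfer direction.}
#'   \item{`"conventional"`}{bit = 1 iff `rand < sigmoid(x)`, the usual
#'     binary-swarm convention.}
#' }
#'
#' @param x_cont Numeric vector (a continuous position update).
#' @param rule `"paper"` or `"conventional"`.
#' @param rand Optional vector of uniform draws to inject (recycled to
#'   `length(x_cont)`); by default drawn from the current RNG state.
#' @return Integer 0/1 vector of `length(x_cont)`.
#' @export
binarize <- function(x_cont, rule = c("paper", "conventional"), rand = NULL) {
  rule <- match.arg(rule)
  if (is.null(rand)) rand <- stats::runif(length(x_cont))
  rand <- rep_len(rand, length(x_cont))
  s <- sigmoid(x_cont)
  bits <- if (rule == "paper") as.integer(rand >= s) else as.integer(rand < s)
  bits
}

# guarantee a non-empty subset: flip one uniformly chosen bit to 1
repair_empty <- function(bits) {
  if (sum(bits) == 0L) bits[sample.int(length(bits), 1L)] <- 1L
  bits
}

#' Run the binary red piranha optimizer
#'
#' Feature-subset search over `f`-bit vectors, maximizing a user-supplied
#' fitness (typically a classifier accuracy in `[0, 100]`, see
#' [make_nb_fitness()]). The three phases reuse the continuous update rules:
#' current bit vectors enter the update equations directly as 0/1 reals, the
#' virtual prey is the real-valued mean of the `k` best bit vectors (it is
#' binarized only for reporting in the trace), and every continuous update
#' is passed through [binarize()] before fitness evaluation. All-zero
#' results are repaired by setting one random bit. Greedy selection closes
#' the searching and encircling phases; the attacking phase is per-step
#' greedy. Collision checks are disabled by default in binary space; set
#' `config$collision = TRUE` for an experimental Hamming-distance variant
#' (collision iff Hamming distance `< 2 * delta`).
#'
#' Fitness values are cached by bit pattern, so re-visited subsets cost
#' nothing. The early stop (on by default here) fires at a phase boundary
#' once the best fitness improves by less than `config$early_stop_tol`.
#'
#' @param fitness Function mapping an integer 0/1 vector of length `f` (with
#'   at least one 1) to a single finite numeric value; higher is better.
#' @param f Number of bits (features).
#' @param config An [rpo_config()]; `early_stop` defaults to `TRUE` for the
#'   binary variant unless the config sets it explicitly.
#' @param transfer Transfer rule passed to [binarize()].
#' @return An object of class `brpo_result`: list with `best_bits`,
#'   `best_fitness`, `trace` (per-iteration phase, bit matrix, fitness
#'   vector, and binarized prey where defined), `iterations_run`,
#'   `evaluations` (distinct subsets scored), `schedule` and `config`.
#' @examples
#' fit <- function(bits) 100 * mean(bits == c(1, 1, 0, 0, 0))
#' res <- run_brpo(fit, f = 5, config = rpo_config(n = 8, Z = 9, seed = 3))
#' res$best_bits
#' @export
run_brpo <- function(fitness, f, config,
                     transfer = c("paper", "conventional")) {
  transfer <- match.arg(transfer)
  stopifnot(is.function(fitness), inherits(config, "rpo_config"))
  f <- as.integer(f)
  if (f < 1L) stop("`f` must be >= 1", call. = FALSE)
  early_stop <- config$early_stop
  if (!isTRUE(early_stop) && is.null(config$early_stop_set)) {
    early_stop <- TRUE # spec default for the binary variant
  }
  set.seed(config$seed)
  sched <- partition_iterations(config$Z)
  n <- config$n
  sense <- "maximize"

  cache <- new.env(parent = emptyenv())
  evaluations <- 0L
  score <- function(bits, context) {
    if (sum(bits) == 0L) {
      stop("cannot evaluate the empty feature subset", call. = FALSE)
    }
    key <- paste(bits, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- fitness(bits)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("fitness returned a non-finite value [%s] for subset %s",
                   context, key), call. = FALSE)
    }
    evaluations <<- evaluations + 1L
    cache[[key]] <- as.numeric(v)
    cache[[key]]
  }

  # random binary initialization, agent by agent
  bits <- matrix(NA_integer_, n, f)
  for (m in seq_len(n)) {
    bits[m, ] <- repair_empty(as.integer(stats::runif(f) < 0.5))
  }
  values <- vapply(seq_len(n), function(m)
    score(bits[m, ], paste0("init agent ", m)), numeric(1))

  best_idx <- which.max(values)
  best_bits <- bits[best_idx, ]
  best_fitness <- values[best_idx]
  trace <- list()
  iterations_run <- 0L
  stopped <- FALSE

  note_best <- function(bit_mat, val_vec) {
    i <- which.max(val_vec)
    if (val_vec[i] > best_fitness) {
      best_bits <<- bit_mat[i, ]
      best_fitness <<- val_vec[i]
    }
  }
  plateaued <- function(before, after) {
    early_stop && abs(before - after) < config$early_stop_tol
  }
  step_to_bits <- function(x_cont, context) {
    b <- repair_empty(binarize(x_cont, rule = transfer))
    list(bits = b, value = score(b, context))
  }

  # -- searching ------------------------------------------------------------
  best_before <- best_fitness
  hist_bits <- lapply(seq_len(n), function(m) bits[m, , drop = FALSE])
  hist_val <- lapply(seq_len(n), function(m) values[m])
  for (t in seq_len(sched$Z_srch)) {
    sc <- select_scouts(n, config$lambda)
    for (m in seq_len(n)) {
      if (m %in% sc$scouts) next
      coef <- sample_search_coefficients()
      scout <- as.numeric(bits[sc$scouts[sc$cluster[m]], ])
      D <- abs(coef$C * scout - as.numeric(bits[m, ]))
      upd <- step_to_bits(scout - coef$A * D,
                          sprintf("searching t=%d agent %d", t, m))
      bits[m, ] <- upd$bits
      values[m] <- upd$value
      hist_bits[[m]] <- rbind(hist_bits[[m]], upd$bits)
      hist_val[[m]] <- c(hist_val[[m]], upd$value)
    }
    iterations_run <- iterations_run + 1L
    trace[[length(trace) + 1L]] <- list(phase = "searching", t = t,
                                        bits = bits, values = values)
  }
  for (m in seq_len(n)) {
    g <- greedy_select_best(hist_bits[[m]], hist_val[[m]], sense)
    bits[m, ] <- g$position
    values[m] <- g$value
  }
  note_best(bits, values)
  if (plateaued(best_before, best_fitness)) stopped <- TRUE

  # -- encircling -----------------------------------------------------------
  if (!stopped && sched$Z_enc > 0L) {
    best_before <- best_fitness
    hist_bits <- lapply(seq_len(n), function(m) bits[m, , drop = FALSE])
    hist_val <- lapply(seq_len(n), function(m) values[m])
    for (t in seq_len(sched$Z_enc)) {
      pp <- compute_prey_position(bits, values, config$k, sense)
      l <- encircling_l_schedule(t, sched$Z_enc)
      for (m in seq_len(n)) {
        D <- abs(pp$prey - as.numeric(bits[m, ]))
        upd <- step_to_bits(D * exp(config$b * l) * cos(2 * pi * l) + pp$prey,
                            sprintf("encircling t=%d agent %d", t, m))
        bits[m, ] <- upd$bits
        values[m] <- upd$value
        hist_bits[[m]] <- rbind(hist_bits[[m]], upd$bits)
        hist_val[[m]] <- c(hist_val[[m]], upd$value)
      }
      iterations_run <- iterations_run + 1L
      trace[[length(trace) + 1L]] <- list(phase = "encircling", t = t,
                                          bits = bits, values = values,
                                          prey_binary = binarize(pp$prey,
                                                                 rule = transfer))
    }
    for (m in seq_len(n)) {
      g <- greedy_select_best(hist_bits[[m]], hist_val[[m]], sense)
      bits[m, ] <- g$position
      values[m] <- g$value
    }
    note_best(bits, values)
    if (plateaued(best_before, best_fitness)) stopped <- TRUE
  }

  # -- attacking ------------------------------------------------------------
  if (!stopped && sched$Z_att > 0L) {
    ck <- if (config$collision) {
      checkpoint_iterations(sched$Z_att, config$n_ck)
    } else integer(0)
    for (t in seq_len(sched$Z_att)) {
      pp <- compute_prey_position(bits, values, config$k, sense)
      a <- attack_coefficient_schedule(t, sched$Z_att)
      for (m in seq_len(n)) {
        A <- 2 * a * stats::runif(1) - a
        C <- 2 * stats::runif(1)
        D <- abs(C * pp$prey - as.numeric(bits[m, ]))
        cand <- step_to_bits(pp$prey - A * D,
                             sprintf("attacking t=%d agent %d", t, m))
        if (cand$value > values[m]) { # per-step greedy
          bits[m, ] <- cand$bits
          values[m] <- cand$value
        }
      }
      note_best(bits, values)
      if (t %in% ck && config$delta > 0) {
        # Hamming-distance collision variant for binary space
        for (g in seq_len(n - 1L)) {
          for (h in seq.int(g + 1L, n)) {
            if (sum(bits[g, ] != bits[h, ]) < 2 * config$delta) {
              loser <- if (values[h] > values[g]) g else h
              bits[loser, ] <- repair_empty(as.integer(stats::runif(f) < 0.5))
              values[loser] <- score(bits[loser, ],
                                     paste0("collision escape agent ", loser))
            }
          }
        }
      }
      iterations_run <- iterations_run + 1L
      trace[[length(trace) + 1L]] <- list(phase = "attacking", t = t,
                                          bits = bits, values = values,
                                          prey_binary = binarize(pp$prey,
                                                                 rule = transfer))
    }
  }

  structure(
    list(best_bits = best_bits, best_fitness = best_fitness, trace = trace,
         iterations_run = iterations_run, evaluations = evaluations,
         schedule = sched, config = config, transfer = transfer,
         early_stopped = stopped),
    class = "brpo_result"
  )
}

#' @export
print.brpo_result <- function(x, ...) {
  cat("<brpo_result>\n")
  cat(sprintf("  best fitness: %.6g with %d of %d bits set\n",
              x$best_fitness, sum(x$best_bits), length(x$best_bits)))
  cat(sprintf("  iterations run: %d of %d%s; %d distinct subsets scored\n",
              x$iterations_run, x$schedule$Z,
              if (x$early_stopped) " (early stop)" else "", x$evaluations))
  invisible(x)
}
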