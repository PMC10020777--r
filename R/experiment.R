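#' Feature-selection experiment over an (n, z) grid
#'
#' Runs the binary optimizer with the Naive Bayes fitness for every
#' combination of agent count and iteration budget, and reports one row per
#' grid cell: the best subset found, its metrics on the held-out test
#' partition, and the nominal execution-time metric `n * z_o`.
#'
#' @param data An [rpo_dataset()]; preprocessed automatically if its
#'   features are not yet a complete numeric matrix.
#' @param n_grid Integer vector of agent counts (e.g. `c(25, 50, 75, 100)`).
#' @param z_grid Integer vector of iteration budgets (e.g. `seq(50, 500, 50)`).
#' @param xi,k,b,collision,delta,n_ck Optimizer parameters, see
#'   [rpo_config()].
#' @param transfer Transfer rule for [binarize()].
#' @param split_ratio,split_seed Train/test split controls ([nb_split()]);
#'   the split is created once and shared by all cells.
#' @param seed Base seed; cell `i` runs with seed `seed + i - 1`.
#' @return A data.frame of class `rpo_fs_report` with columns `n`, `z`,
#'   `z_realized`, `execution_time`, `accuracy`, `micro_precision`,
#'   `micro_recall`, `macro_precision`, `macro_recall`, `f_measure`,
#'   `n_selected`, `informative_overlap` (`NA` without ground truth) and
#'   `selected` (semicolon-joined feature names). The selected bit vectors
#'   are attached as the `bits` attribute.
#' @export
run_fs_experiment <- function(data, n_grid = c(25L, 50L), z_grid = c(50L, 100L),
                              xi = 4, k = 3L, b = 1, collision = FALSE,
                              delta = 0, n_ck = 0L,
                              transfer = c("paper", "conventional"),
                              split_ratio = 0.7, split_seed = 101L,
                              seed = 1L) {
  transfer <- match.arg(transfer)
  stopifnot(inherits(data, "rpo_dataset"))
  if (!is.matrix(data$features) || anyNA(data$features)) {
    data <- preprocess(data)
  }
  split <- nb_split(data$labels, ratio = split_ratio, seed = split_seed)
  fit <- make_nb_fitness(data, split)
  f <- ncol(data$features)

  grid <- expand.grid(n = as.integer(n_grid), z = as.integer(z_grid),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  bits_list <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- rpo_config(n = grid$n[i], Z = grid$z[i], xi = xi,
                      k = min(k, grid$n[i]), b = b, collision = collision,
                      delta = delta, n_ck = n_ck, seed = seed + i - 1L)
    res <- run_brpo(fit, f = f, config = cfg, transfer = transfer)
    sel <- which(res$best_bits == 1L)
    model <- nb_train(data$features[split$train, sel, drop = FALSE],
                      data$labels[split$train])
    pred <- nb_predict(model, data$features[split$test, sel, drop = FALSE])
    met <- evaluate_metrics(data$labels[split$test], pred)
    overlap <- if (is.null(data$informative_mask)) NA_real_ else {
      sum(res$best_bits == 1L & data$informative_mask == 1L)
    }
    rows[[i]] <- data.frame(
      n = grid$n[i], z = grid$z[i], z_realized = res$iterations_run,
      execution_time = execution_time_metric(grid$n[i], res$iterations_run),
      accuracy = met$accuracy, micro_precision = met$micro_precision,
      micro_recall = met$micro_recall, macro_precision = met$macro_precision,
      macro_recall = met$macro_recall, f_measure = met$f_measure,
      n_selected = length(sel), informative_overlap = overlap,
      selected = paste(data$feature_names[sel], collapse = ";"),
      stringsAsFactors = FALSE
    )
    bits_list[[i]] <- res$best_bits
  }
  out <- do.call(rbind, rows)
  attr(out, "bits") <- bits_list
  class(out) <- c("rpo_fs_report", class(out))
  out
}
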