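#' Construct a classification dataset object
#'
#' Light container used throughout the feature-selection pipeline.
#'
#' @param features A data.frame (raw; may contain `NA`s and factors) or a
#'   numeric matrix (preprocessed), one row per sample.
#' @param labels Factor or character vector with exactly the two levels
#'   `negative` and `positive` represented.
#' @param feature_names Optional column names (defaults to those of
#'   `features`).
#' @param informative_mask Optional 0/1 vector marking the truly informative
#'   columns (available for synthetic data only).
#' @return Object of class `rpo_dataset`.
#' @export
rpo_dataset <- function(features, labels, feature_names = colnames(features),
                        informative_mask = NULL) {
  labels <- factor(as.character(labels), levels = c("negative", "positive"))
  if (any(is.na(labels))) {
    stop("labels must all be 'negative' or 'positive'", call. = FALSE)
  }
  if (nlevels(droplevels(labels)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree on the number of samples",
         call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- sprintf("feat_%03d", seq_len(ncol(features)))
  }
  if (!is.null(informative_mask) &&
      length(informative_mask) != ncol(features)) {
    stop("informative_mask length must equal the feature count", call. = FALSE)
  }
  structure(
    list(features = features, labels = labels,
         feature_names = as.character(feature_names),
         informative_mask = informative_mask),
    class = "rpo_dataset"
  )
}

#' @export
print.rpo_dataset <- function(x, ...) {
  cat(sprintf("<rpo_dataset> %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == "positive"), sum(x$labels == "negative")))
  if (!is.null(x$informative_mask)) {
    cat(sprintf("  ground truth: %d informative features\n",
                sum(x$informative_mask)))
  }
  invisible(x)
}

#' Read a delimited classification dataset
#'
#' Parses a delimited text file with a header row into an [rpo_dataset()].
#' The label column is recoded to `positive` / `negative` via
#' `positive_token`; every other retained column becomes a feature.
#'
#' @param path File path (comma-, tab- or semicolon-delimited; guessed from
#'   the extension, override with `sep`).
#' @param label_col Name of the label column.
#' @param positive_token Value in `label_col` marking the positive class;
#'   all other values map to `negative`.
#' @param drop_cols Character vector of identifier/administrative columns to
#'   discard.
#' @param sep Field separator; default `","` for `.csv`, `"\t"` otherwise.
#' @return An [rpo_dataset()] with raw (unimputed) features.
#' @export
read_dataset <- function(path, label_col = "label",
                         positive_token = "positive",
                         drop_cols = NULL, sep = NULL) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (!label_col %in% names(raw)) {
    stop(sprintf("label column '%s' not present in %s", label_col, path),
         call. = FALSE)
  }
  labels <- ifelse(raw[[label_col]] == positive_token, "positive", "negative")
  keep <- setdiff(names(raw), c(label_col, drop_cols))
  if (length(keep) < 1L) stop("no feature columns left after dropping",
                              call. = FALSE)
  rpo_dataset(raw[, keep, drop = FALSE], labels, feature_names = keep)
}

#' Write a dataset as delimited text
#'
#' Emits a CSV with one `label` column (`positive`/`negative`) plus the
#' feature columns, compatible with [read_dataset()].
#'
#' @param data An [rpo_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "rpo_dataset"))
  out <- cbind(data.frame(label = as.character(data$labels),
                          stringsAsFactors = FALSE),
               as.data.frame(data$features))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Impute and encode a raw dataset
#'
#' Deterministic preprocessing ahead of fitness evaluation: numeric columns
#' are median-imputed; non-numeric (categorical) columns are mode-imputed
#' (ties: first level alphabetically) and then integer-coded. Columns that
#' are entirely missing are rejected. The result stores features as a
#' numeric matrix with no missing cells.
#'
#' @param data An [rpo_dataset()] with raw features.
#' @param drop_cols Optional further columns to discard before imputation.
#' @return An [rpo_dataset()] whose `features` is a complete numeric matrix.
#' @export
preprocess <- function(data, drop_cols = NULL) {
  stopifnot(inherits(data, "rpo_dataset"))
  df <- as.data.frame(data$features)
  mask <- data$informative_mask
  if (!is.null(drop_cols)) {
    keep <- !(names(df) %in% drop_cols)
    df <- df[, keep, drop = FALSE]
    if (!is.null(mask)) mask <- mask[keep]
  }
  all_missing <- vapply(df, function(col) all(is.na(col)), logical(1))
  if (any(all_missing)) {
    stop("column(s) entirely missing: ",
         paste(names(df)[all_missing], collapse = ", "), call. = FALSE)
  }
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) {
      col[is.na(col)] <- stats::median(col, na.rm = TRUE)
      col
    } else {
      col <- as.character(col)
      lev <- sort(unique(col[!is.na(col)]))
      tab <- table(factor(col, levels = lev))
      col[is.na(col)] <- names(tab)[which.max(tab)]
      as.integer(factor(col, levels = lev))
    }
  })
  mat <- do.call(cbind, cols)
  storage.mode(mat) <- "double"
  colnames(mat) <- names(df)
  rpo_dataset(mat, data$labels, feature_names = names(df),
              informative_mask = mask)
}
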