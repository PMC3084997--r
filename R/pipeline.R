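# End-to-end training: class balancing, stratified 10-fold
# cross-validation, MCC-maximizing cutoff selection and final model
# production.

#' Construct a labelled dataset
#'
#' @param ids Example identifiers.
#' @param X Feature matrix, one row per example.
#' @param y Binary 0/1 labels.
#' @return A \code{labelled_dataset} list.
#' @export
labelled_dataset <- function(ids, X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y), length(ids) == length(y),
            all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("both classes must be present")
  structure(list(ids = as.character(ids), X = X, y = as.integer(y)),
            class = "labelled_dataset")
}

#' Balance two classes by seeded down-sampling
#'
#' The larger class is down-sampled without replacement to the size of
#' the smaller, and the two classes are interleaved (positive, negative,
#' positive, ...) in the returned dataset.
#'
#' @param positives,negatives Feature matrices (rownames are ids), one
#'   row per example.
#' @param seed Integer seed for the subsample.
#' @return A [labelled_dataset()] with equal class counts.
#' @export
balance <- function(positives, negatives, seed = 1L) {
  stopifnot(is.matrix(positives), is.matrix(negatives))
  if (nrow(positives) == 0 || nrow(negatives) == 0)
    stop("both classes must be non-empty")
  n <- min(nrow(positives), nrow(negatives))
  with_seed(seed, {
    keep_p <- if (nrow(positives) > n) sort(sample.int(nrow(positives), n))
              else seq_len(nrow(positives))
    keep_n <- if (nrow(negatives) > n) sort(sample.int(nrow(negatives), n))
              else seq_len(nrow(negatives))
    P <- positives[keep_p, , drop = FALSE]
    N <- negatives[keep_n, , drop = FALSE]
    ord <- as.vector(rbind(seq_len(n), n + seq_len(n)))  # interleave
    X <- rbind(P, N)[ord, , drop = FALSE]
    y <- rep(c(1L, 0L), n)
    ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("ex", seq_along(y))
    labelled_dataset(ids, X, y)
  })
}

# seeded stratified fold assignment; every class is spread round-robin
# over the folds
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    assign <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

#' Stratified k-fold cross-validation
#'
#' Assigns seeded stratified folds, trains one network per fold on the
#' remaining folds, scores the held-out fold, pools the held-out scores
#' (each example is scored exactly once), computes the pooled AROC and
#' selects the MCC-maximizing cutoff on the pooled scores.
#'
#' @param data A [labelled_dataset()].
#' @param config A [train_config()].
#' @param folds Number of folds (default 10).
#' @param seed Seed for fold assignment and per-fold weight
#'   initialization.
#' @return A \code{cv_result} list: \code{fold} assignment, pooled
#'   \code{scores} and \code{labels} (in dataset order), \code{auroc},
#'   \code{cutoff}, \code{mcc}.
#' @export
crossvalidate <- function(data, config = train_config(), folds = 10L,
                          seed = 1L) {
  stopifnot(inherits(data, "labelled_dataset"))
  n <- length(data$y)
  if (n < folds) stop("fewer examples than folds")
  if (min(table(data$y)) < folds)
    stop("too few examples of one class to stratify ", folds, " folds")
  fold <- stratified_folds(data$y, folds, seed)
  scores <- numeric(n)
  reg <- colnames(data$X)
  if (is.null(reg)) reg <- paste0("f", seq_len(ncol(data$X)))
  for (k in seq_len(folds)) {
    hold <- fold == k
    model <- init_model(seed + k, mode = config$mode,
                        n_input = ncol(data$X), features = reg)
    fit <- train(model, data$X[!hold, , drop = FALSE], data$y[!hold], config)
    scores[hold] <- forward(fit, data$X[hold, , drop = FALSE])
  }
  sel <- select_cutoff(scores, data$y)
  structure(list(fold = fold, scores = scores, labels = data$y,
                 auroc = auroc(scores, data$y),
                 cutoff = sel$cutoff, mcc = sel$mcc),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds, pooled AROC %.3f, cutoff %.3f (MCC %.3f)\n",
              max(x$fold), x$auroc, x$cutoff, x$mcc))
  invisible(x)
}

#' Select the MCC-maximizing decision cutoff
#'
#' Candidate cutoffs are the unique observed scores; the rule score >=
#' cutoff is positive; ties break toward the smallest cutoff. Shared
#' with [max_mcc_sweep()].
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 truth labels (both classes required).
#' @return List with \code{cutoff} and \code{mcc}.
#' @export
select_cutoff <- function(scores, labels) max_mcc_sweep(scores, labels)

#' Fit the final model on all data
#'
#' Trains on the full dataset for the configured fixed cycle count and
#' installs the cross-validation-selected cutoff, mode tag and scaling
#' specification.
#'
#' @param data A [labelled_dataset()].
#' @param config A [train_config()] (early stopping is disabled for the
#'   final fixed-cycle fit).
#' @param cutoff_source A \code{cv_result} from [crossvalidate()] on the
#'   same data.
#' @param seed Seed for weight initialization.
#' @param scaling The \code{scaling_spec} the feature matrix was built
#'   with; stored in the model.
#' @return Trained \code{mlp_model} carrying the selected cutoff.
#' @export
fit_final <- function(data, config = train_config(), cutoff_source,
                      seed = 1L, scaling = default_scaling()) {
  stopifnot(inherits(data, "labelled_dataset"),
            inherits(cutoff_source, "cv_result"))
  if (length(cutoff_source$labels) != length(data$y))
    stop("cutoff_source does not match the dataset")
  reg <- colnames(data$X)
  if (is.null(reg)) reg <- paste0("f", seq_len(ncol(data$X)))
  if (ncol(data$X) == 428 && identical(reg, feature_names()))
    sc <- scaling
  else  # non-standard featurization: store identity bounds
    sc <- structure(data.frame(name = reg, lower = 0, upper = 1,
                               stringsAsFactors = FALSE),
                    class = c("scaling_spec", "data.frame"))
  config$early_stopping <- FALSE
  model <- init_model(seed, mode = config$mode, n_input = ncol(data$X),
                      features = reg, scaling = sc)
  model <- train(model, data$X, data$y, config)
  model$cutoff <- cutoff_source$cutoff
  model
}
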