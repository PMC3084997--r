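# Feed-forward 428-100-1 network with logistic units, trained by
# per-example back-propagation on squared error, with optional early
# stopping on a held-out validation split.

sigmoid <- function(z) 1 / (1 + exp(-z))

# evaluate `expr` under a temporary RNG seed, restoring the caller's
# RNG state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default decision cutoff for a network mode
#'
#' The published operating points: 0.517 for PDB mode (positives drawn
#' from solved PDB structures) and 0.418 for SG mode (positives drawn
#' from structural-genomics pipeline outcomes). A freshly initialized
#' model carries the preset; cutoffs selected by cross-validation
#' override it.
#'
#' @param mode \code{"PDB"} or \code{"SG"}.
#' @return Cutoff in (0, 1).
#' @export
default_cutoff <- function(mode = c("PDB", "SG")) {
  switch(match.arg(mode), PDB = 0.517, SG = 0.418)
}

#' Default training-cycle count for a network mode
#'
#' The cycle optima found for the two modes: 2100 (PDB) and 1600 (SG).
#' Used for fixed-cycle training when early stopping is disabled.
#'
#' @param mode \code{"PDB"} or \code{"SG"}.
#' @return Integer cycle count.
#' @export
default_cycles <- function(mode = c("PDB", "SG")) {
  switch(match.arg(mode), PDB = 2100L, SG = 1600L)
}

#' Initialize a network model
#'
#' Weights are drawn uniformly from [-0.1, 0.1] under the given seed;
#' biases start at zero. The input-to-hidden matrix is stored with one
#' row per hidden unit (\code{n_hidden} x \code{n_input}).
#'
#' @param seed Integer RNG seed.
#' @param mode \code{"PDB"} or \code{"SG"} (tags the model and sets the
#'   preset cutoff and cycle count).
#' @param n_input,n_hidden Layer sizes; defaults 428 and 100.
#' @param scaling The \code{scaling_spec} the model expects its inputs to
#'   have been scaled with.
#' @param features Feature-name registry matching the input order.
#' @return An \code{mlp_model} object.
#' @export
init_model <- function(seed, mode = c("PDB", "SG"),
                       n_input = 428L, n_hidden = 100L,
                       scaling = default_scaling(),
                       features = feature_names()) {
  mode <- match.arg(mode)
  stopifnot(n_input >= 1, n_hidden >= 1, length(features) == n_input)
  w <- with_seed(seed, stats::runif(n_hidden * n_input + n_hidden, -0.1, 0.1))
  structure(list(
    w_ih = matrix(w[seq_len(n_hidden * n_input)], n_hidden, n_input),
    b_h = rep(0, n_hidden),
    w_ho = w[n_hidden * n_input + seq_len(n_hidden)],
    b_o = 0,
    mode = mode,
    cutoff = default_cutoff(mode),
    cycles = default_cycles(mode),
    scaling = scaling,
    features = features
  ), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %d-%d-1 logistic network, mode %s\n",
              ncol(x$w_ih), nrow(x$w_ih), x$mode))
  cat(sprintf("  cutoff %.6f, cycles %d\n", x$cutoff, x$cycles))
  invisible(x)
}

check_features <- function(model, x) {
  if (is.matrix(x)) {
    if (ncol(x) != ncol(model$w_ih))
      stop("feature matrix has ", ncol(x), " columns; model expects ",
           ncol(model$w_ih))
    if (!is.null(colnames(x)) && !identical(colnames(x), model$features))
      stop("feature-name registry mismatch between input and model")
  } else {
    if (length(x) != ncol(model$w_ih))
      stop("feature vector has length ", length(x), "; model expects ",
           ncol(model$w_ih))
    if (!is.null(names(x)) && !identical(names(x), model$features))
      stop("feature-name registry mismatch between input and model")
  }
  invisible(TRUE)
}

#' Forward pass
#'
#' \code{sigmoid(w_ho . sigmoid(W_ih x + b_h) + b_o)}; a pure function of
#' the model and the input.
#'
#' @param model An \code{mlp_model}.
#' @param x Feature vector (length \code{n_input}) or matrix with one row
#'   per example. Named inputs are checked against the model's registry.
#' @return Score(s) in (0, 1).
#' @export
forward <- function(model, x) {
  check_features(model, x)
  if (is.matrix(x)) {
    h <- sigmoid(tcrossprod(x, model$w_ih) +
                   matrix(model$b_h, nrow(x), length(model$b_h), byrow = TRUE))
    as.numeric(sigmoid(h %*% model$w_ho + model$b_o))
  } else {
    h <- sigmoid(as.numeric(model$w_ih %*% x) + model$b_h)
    sigmoid(sum(model$w_ho * h) + model$b_o)
  }
}

# analytic gradient of the squared error 0.5*(yhat - y)^2 for a single
# example; returned in the same shapes as the weights
mlp_gradient <- function(model, x, y) {
  h_lin <- as.numeric(model$w_ih %*% x) + model$b_h
  h <- sigmoid(h_lin)
  o <- sigmoid(sum(model$w_ho * h) + model$b_o)
  delta_o <- (o - y) * o * (1 - o)
  delta_h <- (model$w_ho * delta_o) * h * (1 - h)
  list(w_ih = outer(delta_h, x), b_h = delta_h,
       w_ho = delta_o * h, b_o = delta_o)
}

mean_sq_error <- function(model, X, y) {
  p <- forward(model, X)
  mean((p - y)^2)
}

#' Training configuration
#'
#' @param mode \code{"PDB"} or \code{"SG"}; sets the default fixed cycle
#'   count (2100 / 1600).
#' @param learning_rate Back-propagation step size; default 0.01.
#' @param cycles Fixed number of passes over the data when early stopping
#'   is off, and the maximum when it is on; defaults to
#'   [default_cycles()] for the mode.
#' @param early_stopping If TRUE, a seeded stratified validation split is
#'   monitored and the best-validation weights are returned.
#' @param val_fraction Fraction of examples held out for validation;
#'   default 0.1.
#' @param patience Cycles without validation improvement before stopping;
#'   default 100.
#' @param seed Seed controlling example shuffling and the validation
#'   split.
#' @return A \code{train_config} list.
#' @export
train_config <- function(mode = c("PDB", "SG"), learning_rate = 0.01,
                         cycles = NULL, early_stopping = FALSE,
                         val_fraction = 0.1, patience = 100L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(cycles)) cycles <- default_cycles(mode)
  stopifnot(learning_rate > 0, cycles >= 1, patience >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(mode = mode, learning_rate = learning_rate,
                 cycles = as.integer(cycles),
                 early_stopping = isTRUE(early_stopping),
                 val_fraction = val_fraction,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Train a network by per-example back-propagation
#'
#' One cycle is one pass over all examples in a freshly shuffled (seeded)
#' order, updating the weights after each example (stochastic gradient
#' descent on squared error, targets 1 for the positive class and 0 for
#' the negative). With early stopping, a seeded stratified validation
#' split is monitored each cycle and the weights from the
#' best-validation-error cycle are returned.
#'
#' @param model Initial \code{mlp_model} (see [init_model()]).
#' @param X Feature matrix, one row per example, already scaled.
#' @param y Binary labels (0/1), one per row of \code{X}.
#' @param config A [train_config()].
#' @return The trained \code{mlp_model}; \code{$cycles} holds the number
#'   of cycles actually adopted and \code{attr(, "trace")} a data frame
#'   of per-cycle training (and validation) mean squared error.
#' @export
train <- function(model, X, y, config = train_config()) {
  stopifnot(inherits(model, "mlp_model"), is.matrix(X),
            nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    stop("training data must contain both classes")
  check_features(model, X)

  with_seed(config$seed, {
    n <- nrow(X)
    if (config$early_stopping) {
      pos <- which(y == 1); neg <- which(y == 0)
      n_vp <- max(1L, round(length(pos) * config$val_fraction))
      n_vn <- max(1L, round(length(neg) * config$val_fraction))
      val_idx <- c(sample(pos, n_vp), sample(neg, n_vn))
      train_idx <- setdiff(seq_len(n), val_idx)
      if (length(unique(y[train_idx])) < 2)
        stop("training partition lost a class; reduce val_fraction")
    } else {
      train_idx <- seq_len(n)
      val_idx <- integer(0)
    }

    w_ih <- model$w_ih; b_h <- model$b_h
    w_ho <- model$w_ho; b_o <- model$b_o
    lr <- config$learning_rate
    Xt <- X[train_idx, , drop = FALSE]
    dimnames(Xt) <- NULL  # keep weight matrices free of inherited names
    yt <- y[train_idx]
    nt <- nrow(Xt)

    best <- list(err = Inf, cycle = 0L, w_ih = w_ih, b_h = b_h,
                 w_ho = w_ho, b_o = b_o)
    trace_train <- numeric(0); trace_val <- numeric(0)
    since_best <- 0L

    for (cycle in seq_len(config$cycles)) {
      ord <- sample.int(nt)
      for (i in ord) {
        x <- Xt[i, ]
        h <- sigmoid(as.numeric(w_ih %*% x) + b_h)
        o <- sigmoid(sum(w_ho * h) + b_o)
        delta_o <- (o - yt[i]) * o * (1 - o)
        delta_h <- (w_ho * delta_o) * h * (1 - h)
        w_ih <- w_ih - lr * outer(delta_h, x)
        b_h <- b_h - lr * delta_h
        w_ho <- w_ho - lr * delta_o * h
        b_o <- b_o - lr * delta_o
      }
      cur <- model
      cur$w_ih <- w_ih; cur$b_h <- b_h; cur$w_ho <- w_ho; cur$b_o <- b_o
      err_train <- mean_sq_error(cur, Xt, yt)
      if (!is.finite(err_train)) stop("non-finite training loss at cycle ", cycle)
      trace_train <- c(trace_train, err_train)
      if (config$early_stopping) {
        err_val <- mean_sq_error(cur, X[val_idx, , drop = FALSE], y[val_idx])
        trace_val <- c(trace_val, err_val)
        if (err_val < best$err) {
          best <- list(err = err_val, cycle = cycle, w_ih = w_ih, b_h = b_h,
                       w_ho = w_ho, b_o = b_o)
          since_best <- 0L
        } else {
          since_best <- since_best + 1L
          if (since_best >= config$patience) break
        }
      }
    }

    if (config$early_stopping) {
      model$w_ih <- best$w_ih; model$b_h <- best$b_h
      model$w_ho <- best$w_ho; model$b_o <- best$b_o
      model$cycles <- best$cycle
    } else {
      model$w_ih <- w_ih; model$b_h <- b_h
      model$w_ho <- w_ho; model$b_o <- b_o
      model$cycles <- config$cycles
    }
    trace <- data.frame(cycle = seq_along(trace_train), train_mse = trace_train)
    if (config$early_stopping) trace$val_mse <- trace_val
    attr(model, "trace") <- trace
    model
  })
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Save a model to a versioned plain-text file
#'
#' Full-precision decimal serialization of the weights, cutoff, cycle
#' count, scaling specification and feature registry. Loading the file
#' reproduces the model bit for bit.
#'
#' @param model An \code{mlp_model}.
#' @param path Output path.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  nh <- nrow(model$w_ih); ni <- ncol(model$w_ih)
  lines <- c(
    "crystalnn-model 1",
    paste("mode", model$mode),
    paste("cutoff", fmt_num(model$cutoff)),
    paste("cycles", model$cycles),
    paste("n_input", ni),
    paste("n_hidden", nh),
    paste0("features\t", paste(model$features, collapse = "\t")),
    paste0("scaling_lower\t", paste(fmt_num(model$scaling$lower), collapse = "\t")),
    paste0("scaling_upper\t", paste(fmt_num(model$scaling$upper), collapse = "\t")),
    paste0("b_h\t", paste(fmt_num(model$b_h), collapse = "\t")),
    paste0("w_ho\t", paste(fmt_num(model$w_ho), collapse = "\t")),
    paste0("b_o\t", fmt_num(model$b_o)),
    vapply(seq_len(nh), function(r)
      paste0("w_ih\t", paste(fmt_num(model$w_ih[r, ]), collapse = "\t")),
      character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

field_nums <- function(line, name) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (parts[1] != name) stop("model file: expected field '", name,
                             "', found '", parts[1], "'")
  as.numeric(parts[-1])
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to a model file.
#' @return The \code{mlp_model}, bitwise identical to the saved one.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 12 || lines[1] != "crystalnn-model 1")
    stop("unrecognized or truncated model file (expected 'crystalnn-model 1')")
  kv <- function(i, key) {
    parts <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (parts[1] != key) stop("model file: expected '", key, "' on line ", i)
    parts[2]
  }
  mode <- kv(2, "mode")
  if (!mode %in% c("PDB", "SG")) stop("unknown model mode: ", mode)
  cutoff <- as.numeric(kv(3, "cutoff"))
  cycles <- as.integer(kv(4, "cycles"))
  ni <- as.integer(kv(5, "n_input"))
  nh <- as.integer(kv(6, "n_hidden"))
  features <- strsplit(lines[7], "\t", fixed = TRUE)[[1]][-1]
  if (length(features) != ni)
    stop("model file: feature registry length ", length(features),
         " does not match n_input ", ni)
  sl <- field_nums(lines[8], "scaling_lower")
  su <- field_nums(lines[9], "scaling_upper")
  b_h <- field_nums(lines[10], "b_h")
  w_ho <- field_nums(lines[11], "w_ho")
  b_o <- field_nums(lines[12], "b_o")
  if (length(sl) != ni || length(su) != ni)
    stop("model file: scaling spec length does not match n_input")
  if (length(b_h) != nh || length(w_ho) != nh)
    stop("model file: hidden-layer size does not match n_hidden")
  w_lines <- lines[-(1:12)]
  if (length(w_lines) != nh)
    stop("model file: expected ", nh, " weight rows, found ", length(w_lines))
  w_ih <- do.call(rbind, lapply(w_lines, field_nums, name = "w_ih"))
  if (ncol(w_ih) != ni)
    stop("model file: weight row length does not match n_input")
  structure(list(
    w_ih = w_ih, b_h = b_h, w_ho = w_ho, b_o = b_o,
    mode = mode, cutoff = cutoff, cycles = cycles,
    scaling = structure(data.frame(name = features, lower = sl, upper = su,
                                   stringsAsFactors = FALSE),
                        class = c("scaling_spec", "data.frame")),
    features = features
  ), class = "mlp_model")
}
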