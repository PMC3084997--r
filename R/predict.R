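# Whole-sequence prediction: featurize, score, classify at the model's
# cutoff. This is the programmatic surface behind the command-line
# `predict` subcommand (inst/cli/crystalnn.R).

#' Score protein sequences with a trained model
#'
#' Assembles the feature vector for each record (using supplied
#' annotation masks where available and the built-in heuristic
#' annotators otherwise), runs the forward pass and classifies at the
#' model's decision cutoff (score >= cutoff is the positive,
#' crystallizable class).
#'
#' @param object Trained \code{mlp_model}.
#' @param records Data frame from [read_fasta()] (columns id, seq).
#' @param tracks Optional named list (by annotation kind) of named lists
#'   (by id) of 0/1 masks, as from [read_annotation_mask()].
#' @param ... Unused.
#' @return Data frame with one row per record: \code{id}, \code{score},
#'   \code{class} (0/1), \code{heuristic_masks} (TRUE when any
#'   annotation track fell back to the built-in heuristics).
#' @export
predict.mlp_model <- function(object, records, tracks = NULL, ...) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  kinds <- c("helix", "strand", "disorder", "transmembrane")
  fallback <- vapply(records$id, function(id)
    any(vapply(kinds, function(k) is.null(tracks[[k]][[id]]), logical(1))),
    logical(1))
  if (any(fallback))
    message(sum(fallback), " sequence(s) scored with built-in heuristic ",
            "annotation masks; supply external predictor masks for real work")
  sc <- structure(data.frame(name = object$features,
                             lower = object$scaling$lower,
                             upper = object$scaling$upper,
                             stringsAsFactors = FALSE),
                  class = c("scaling_spec", "data.frame"))
  X <- feature_matrix(records, tracks, sc)
  colnames(X) <- object$features
  score <- forward(object, X)
  data.frame(id = records$id, score = score,
             class = as.integer(score >= object$cutoff),
             heuristic_masks = unname(fallback),
             stringsAsFactors = FALSE)
}
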