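# Sliding-window scoring for construct design: a 61-residue window is
# passed along the sequence and the network score reported at the central
# residue. Whole-sequence annotation tracks are sliced per window, while
# composition, pI, hydrophobicity, length and molecular weight are
# computed directly on each window subsequence.

#' Sliding-window score profile
#'
#' Scores every window of \code{windowsize} residues with a trained
#' model. Annotation fractions come from the whole-protein tracks
#' restricted to the window; all sequence-intrinsic features are computed
#' on the window subsequence itself. Windows never wrap or pad, so the
#' first and last \code{floor(windowsize/2)} residues receive no score;
#' for the default size 61 the centers run from position 31 to L-30.
#'
#' @param sequence Residue string of length >= \code{windowsize}.
#' @param model Trained \code{mlp_model}.
#' @param tracks Named list of whole-sequence 0/1 masks (\code{helix},
#'   \code{strand}, \code{disorder}, \code{transmembrane}); \code{NULL}
#'   uses [heuristic_annotate()].
#' @param windowsize Odd window length, default 61.
#' @param id Identifier recorded on the profile.
#' @return A \code{window_profile}: list with \code{id}, \code{windowsize},
#'   \code{seq_length}, \code{centers} (1-based), \code{scores},
#'   \code{mode}.
#' @export
profile_sequence <- function(sequence, model, tracks = NULL,
                             windowsize = 61L, id = "seq") {
  stopifnot(inherits(model, "mlp_model"), windowsize >= 3,
            windowsize %% 2 == 1)
  L <- nchar(sequence)
  if (L < windowsize)
    stop("sequence length ", L, " is shorter than the window (", windowsize,
         "); score the whole sequence with predict() instead")
  kinds <- c("helix", "strand", "disorder", "transmembrane")
  if (is.null(tracks))
    tracks <- stats::setNames(lapply(kinds, heuristic_annotate,
                                     sequence = sequence), kinds)
  for (k in kinds)
    if (length(tracks[[k]]) != L)
      stop("track '", k, "' does not cover the whole sequence")
  half <- (windowsize - 1L) %/% 2L
  starts <- seq_len(L - windowsize + 1L)
  feats <- lapply(starts, function(s) {
    win <- substr(sequence, s, s + windowsize - 1L)
    wtracks <- lapply(tracks, function(m) m[s:(s + windowsize - 1L)])
    assemble_features(win, wtracks, model$scaling)
  })
  X <- do.call(rbind, feats)
  colnames(X) <- model$features
  structure(list(id = id, windowsize = as.integer(windowsize),
                 seq_length = L, centers = starts + half,
                 scores = forward(model, X), mode = model$mode),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("window_profile '%s': %d centers (window %d, length %d), score range [%.3f, %.3f]\n",
              x$id, length(x$centers), x$windowsize, x$seq_length,
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' High-scoring regions of a window profile
#'
#' Maximal runs of consecutive window centers with score strictly above
#' the threshold, expanded to the residues covered by the member windows
#' (first center - half window to last center + half window, clipped to
#' the sequence).
#'
#' @param profile A \code{window_profile}.
#' @param threshold Score threshold, default 0.9.
#' @return Data frame with columns \code{start}, \code{end} (1-based,
#'   inclusive); zero rows when no center passes.
#' @export
high_score_regions <- function(profile, threshold = 0.9) {
  stopifnot(inherits(profile, "window_profile"),
            length(profile$scores) > 0)
  half <- (profile$windowsize - 1L) %/% 2L
  above <- profile$scores > threshold
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(
    start = pmax(1L, profile$centers[starts_i[keep]] - half),
    end = pmin(profile$seq_length, profile$centers[ends_i[keep]] + half))
}
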