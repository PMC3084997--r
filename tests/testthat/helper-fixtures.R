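# Shared fixtures: random sequences, toy models, identity scaling.

random_sequence <- function(n, seed, alphabet = amino_acids()) {
  set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

identity_scaling <- function(names) {
  structure(data.frame(name = names, lower = 0, upper = 1,
                       stringsAsFactors = FALSE),
            class = c("scaling_spec", "data.frame"))
}

# small network over k plain features, for gradient and training tests
toy_model <- function(seed = 1, n_input = 5, n_hidden = 3, mode = "PDB") {
  nm <- paste0("f", seq_len(n_input))
  init_model(seed, mode, n_input = n_input, n_hidden = n_hidden,
             scaling = identity_scaling(nm), features = nm)
}

# two shifted Gaussian clouds squashed into [0,1]; linearly separable
# for large shift
gaussian_data <- function(n_per_class, dim = 5, shift = 1, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * dim, shift), n_per_class),
             matrix(rnorm(n_per_class * dim, -shift), n_per_class))
  X <- pmin(pmax((X + 5) / 10, 0), 1)
  colnames(X) <- paste0("f", seq_len(dim))
  list(X = X, y = rep(c(1, 0), each = n_per_class))
}

all_tracks <- function(sequence) {
  kinds <- c("helix", "strand", "disorder", "transmembrane")
  stats::setNames(lapply(kinds, heuristic_annotate, sequence = sequence),
                  kinds)
}

# hand-built window profile for region-extraction tests
fake_profile <- function(scores, windowsize = 61, seq_length = NULL) {
  half <- (windowsize - 1) %/% 2
  centers <- seq_along(scores) + half
  if (is.null(seq_length)) seq_length <- length(scores) + windowsize - 1
  structure(list(id = "fake", windowsize = as.integer(windowsize),
                 seq_length = as.integer(seq_length), centers = centers,
                 scores = scores, mode = "PDB"),
            class = "window_profile")
}
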