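# The 428-dimensional sequence feature vector: 20 amino-acid frequencies,
# 400 dipeptide frequencies, isoelectric point, mean GES hydrophobicity,
# helix/strand/disorder/transmembrane annotation fractions, sequence length
# and molecular weight, each min-max scaled to [0,1].

seq_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  strsplit(sequence, "")[[1]]
}

#' Feature name registry
#'
#' The fixed, ordered names of the 428 features: \code{aa_A..aa_Y}
#' (alphabetical), \code{dp_AA..dp_YY} (row-major: first residue, then
#' second, each alphabetical), then \code{pI}, \code{mean_ges},
#' \code{frac_helix}, \code{frac_strand}, \code{frac_disorder},
#' \code{length}, \code{frac_tm}, \code{mol_weight}. The registry is
#' embedded in every model file so that feature-order mismatches are
#' detectable.
#'
#' @return Character vector of length 428.
#' @export
feature_names <- function() {
  aa <- amino_acids()
  c(paste0("aa_", aa),
    paste0("dp_", rep(aa, each = 20), rep(aa, times = 20)),
    "pI", "mean_ges", "frac_helix", "frac_strand", "frac_disorder",
    "length", "frac_tm", "mol_weight")
}

#' Amino-acid frequencies
#'
#' Count of each standard residue divided by the number of standard
#' residues; ambiguity letters are excluded from both numerator and
#' denominator. Errors if the sequence has no standard residue.
#'
#' @param sequence Residue string.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_frequencies <- function(sequence) {
  ch <- seq_chars(sequence)
  ch <- ch[ch %in% amino_acids()]
  if (length(ch) == 0)
    stop("sequence contains no standard residue")
  counts <- table(factor(ch, levels = amino_acids()))
  stats::setNames(as.numeric(counts) / length(ch),
                  paste0("aa_", amino_acids()))
}

#' Dipeptide frequencies
#'
#' Overlapping adjacent residue pairs; pairs containing an ambiguity
#' letter are skipped; counts are divided by the number of counted pairs.
#' Order is row-major (first residue, then second, each alphabetical).
#' A sequence with no countable pair yields all zeros.
#'
#' @param sequence Residue string.
#' @return Named numeric vector of length 400.
#' @export
dipeptide_frequencies <- function(sequence) {
  aa <- amino_acids()
  nm <- paste0("dp_", rep(aa, each = 20), rep(aa, times = 20))
  ch <- seq_chars(sequence)
  out <- stats::setNames(numeric(400), nm)
  if (length(ch) < 2) return(out)
  first <- ch[-length(ch)]
  second <- ch[-1]
  keep <- first %in% aa & second %in% aa
  if (!any(keep)) return(out)
  pair <- paste0("dp_", first[keep], second[keep])
  counts <- table(factor(pair, levels = nm))
  stats::setNames(as.numeric(counts) / sum(keep), nm)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the free termini and the ionizable side
#' chains (D, E, C, Y, H, K, R) using the pKa set of [pka_table()].
#' Ambiguity letters are treated as non-ionizable.
#'
#' @param sequence Residue string.
#' @param ph pH value(s).
#' @return Net charge (vectorized over \code{ph}).
#' @export
peptide_charge <- function(sequence, ph) {
  ch <- seq_chars(sequence)
  tab <- pka_table()
  counts <- stats::setNames(rep(1, 2), c("Nterm", "Cterm"))
  side <- table(ch[ch %in% tab$group])
  counts <- c(counts, stats::setNames(as.numeric(side), names(side)))
  vapply(ph, function(p) {
    q <- 0
    for (g in names(counts)) {
      row <- tab[tab$group == g, ]
      frac <- if (row$charge > 0) {
        1 / (1 + 10^(p - row$pka))      # protonated fraction, positive group
      } else {
        -1 / (1 + 10^(row$pka - p))     # deprotonated fraction, negative group
      }
      q <- q + counts[[g]] * frac
    }
    q
  }, numeric(1))
}

#' Isoelectric point
#'
#' The pH at which the peptide's net charge is zero, solved by bisection
#' on [0, 14] to a tolerance of 0.002 pH units. The net charge is a
#' strictly decreasing function of pH, so the root is unique; if it never
#' crosses zero inside the interval the clipped endpoint is returned.
#'
#' @param sequence Residue string.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence) {
  lo <- 0; hi <- 14
  q_lo <- peptide_charge(sequence, lo)
  q_hi <- peptide_charge(sequence, hi)
  if (q_lo <= 0) return(lo)
  if (q_hi >= 0) return(hi)
  while (hi - lo > 0.002) {
    mid <- (lo + hi) / 2
    if (peptide_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mean GES hydrophobicity
#'
#' Arithmetic mean of per-residue GES transfer free energies over the
#' standard residues; ambiguity letters are excluded.
#'
#' @param sequence Residue string with at least one standard residue.
#' @return Mean transfer free energy, kcal/mol.
#' @export
mean_ges_hydrophobicity <- function(sequence) {
  ch <- seq_chars(sequence)
  ch <- ch[ch %in% amino_acids()]
  if (length(ch) == 0) stop("sequence contains no standard residue")
  mean(ges_scale()[ch])
}

#' Molecular weight
#'
#' Sum of average residue masses plus one water. Ambiguity letters
#' contribute the mean of the 20 standard residue masses.
#'
#' @param sequence Residue string.
#' @return Mass in Daltons.
#' @export
molecular_weight <- function(sequence) {
  ch <- seq_chars(sequence)
  m <- residue_masses()
  mean_mass <- mean(m)
  sum(ifelse(ch %in% names(m), m[ch], mean_mass)) + water_mass()
}

#' Fraction of annotated residues
#'
#' @param mask Integer 0/1 vector (one element per residue).
#' @return Proportion of 1s, in [0, 1].
#' @export
annotation_fraction <- function(mask) {
  stopifnot(length(mask) >= 1, all(mask %in% c(0L, 1L)))
  mean(mask)
}

# mark residues inside any width-w window whose mean passes `test`;
# window means are computed directly (not by cumulative sums) so that
# identical windows give bitwise-identical means wherever they sit
window_flag <- function(values, w, test) {
  n <- length(values)
  flag <- logical(n)
  if (n < w) return(flag)
  for (s in 1:(n - w + 1)) {
    if (test(sum(values[s:(s + w - 1)]) / w)) flag[s:(s + w - 1)] <- TRUE
  }
  flag
}

# residues shorter than min_run in a run of TRUE are reset to FALSE
enforce_min_run <- function(flag, min_run) {
  r <- rle(flag)
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

#' Built-in heuristic annotators
#'
#' Deterministic stand-ins producing a per-residue 0/1 mask when no
#' external predictor output is supplied:
#' \describe{
#'   \item{transmembrane}{residues inside any 19-residue window whose mean
#'     GES hydrophobicity exceeds \code{tm_threshold} (default 1.6
#'     kcal/mol).}
#'   \item{helix, strand}{per-residue argmax of Chou-Fasman propensities
#'     (a residue is a candidate when its winning propensity exceeds 100),
#'     then runs shorter than 4 residues are erased.}
#'   \item{disorder}{residues inside any 21-residue window whose mean GES
#'     hydropathy is below \code{dis_hydro} (default -1.0 kcal/mol) and
#'     whose mean net-charge magnitude (K,R = +1; D,E = -1) exceeds
#'     \code{dis_charge} (default 0.15).}
#' }
#' These are second-class conveniences: supply masks from dedicated
#' predictors for real work.
#'
#' @param sequence Residue string.
#' @param kind One of \code{"helix"}, \code{"strand"}, \code{"disorder"},
#'   \code{"transmembrane"}.
#' @param tm_threshold,dis_hydro,dis_charge Tunable thresholds, see above.
#' @return Integer 0/1 vector of length \code{nchar(sequence)} with
#'   attribute \code{kind}.
#' @export
heuristic_annotate <- function(sequence, kind,
                               tm_threshold = 1.6,
                               dis_hydro = -1.0, dis_charge = 0.15) {
  kind <- match.arg(kind, c("helix", "strand", "disorder", "transmembrane"))
  ch <- seq_chars(sequence)
  n <- length(ch)
  ges <- ges_scale()
  ges_vals <- ifelse(ch %in% names(ges), ges[ch], 0)
  mask <- switch(kind,
    transmembrane = window_flag(ges_vals, 19L, function(m) m > tm_threshold),
    disorder = {
      charge <- ifelse(ch %in% c("K", "R"), 1, ifelse(ch %in% c("D", "E"), -1, 0))
      flag <- logical(n)
      if (n >= 21L) {
        for (s in 1:(n - 21L + 1L)) {
          idx <- s:(s + 20L)
          mean_h <- sum(ges_vals[idx]) / 21
          mean_q <- sum(charge[idx]) / 21
          # hydrophilic AND charged window marks all its residues
          if (mean_h < dis_hydro && abs(mean_q) > dis_charge)
            flag[s:(s + 20L)] <- TRUE
        }
      }
      flag
    },
    helix = ,
    strand = {
      cf <- chou_fasman()
      ph <- stats::setNames(cf$p_helix, cf$residue)
      ps <- stats::setNames(cf$p_strand, cf$residue)
      pa <- ifelse(ch %in% names(ph), ph[ch], 0)
      pb <- ifelse(ch %in% names(ps), ps[ch], 0)
      state <- if (kind == "helix") pa >= pb & pa > 100 else pb > pa & pb > 100
      enforce_min_run(state, 4L)
    })
  structure(as.integer(mask), kind = kind)
}

#' Default feature scaling specification
#'
#' Per-feature (lower, upper) bounds for min-max scaling to [0, 1]:
#' frequencies and annotation fractions use (0, 1) (identity); pI uses
#' (0, 14); mean GES uses the extreme values of the GES table; length
#' uses (0, 2000) and molecular weight (0, 250000) Da, both clipped.
#' The spec travels inside every model file so models trained with other
#' bounds remain portable.
#'
#' @return Data frame with columns \code{name}, \code{lower},
#'   \code{upper}, 428 rows, class \code{scaling_spec}.
#' @export
default_scaling <- function() {
  nm <- feature_names()
  lower <- stats::setNames(rep(0, length(nm)), nm)
  upper <- stats::setNames(rep(1, length(nm)), nm)
  ges <- ges_scale()
  lower["pI"] <- 0;            upper["pI"] <- 14
  lower["mean_ges"] <- min(ges); upper["mean_ges"] <- max(ges)
  lower["length"] <- 0;        upper["length"] <- 2000
  lower["mol_weight"] <- 0;    upper["mol_weight"] <- 250000
  structure(data.frame(name = nm, lower = unname(lower),
                       upper = unname(upper), stringsAsFactors = FALSE),
            class = c("scaling_spec", "data.frame"))
}

#' Assemble the 428-feature vector for one sequence
#'
#' Computes all feature blocks in the fixed registry order, then min-max
#' scales each value with \code{scaling} and clips to [0, 1].
#'
#' @param sequence Residue string.
#' @param tracks Named list with 0/1 masks \code{helix}, \code{strand},
#'   \code{disorder}, \code{transmembrane}, each of sequence length.
#'   \code{NULL} invokes [heuristic_annotate()] for all four kinds.
#' @param scaling A \code{scaling_spec}; default [default_scaling()].
#' @return Named numeric vector of length 428 with all values in [0, 1].
#' @export
assemble_features <- function(sequence, tracks = NULL,
                              scaling = default_scaling()) {
  n <- nchar(sequence)
  kinds <- c("helix", "strand", "disorder", "transmembrane")
  if (is.null(tracks))
    tracks <- stats::setNames(lapply(kinds, heuristic_annotate,
                                     sequence = sequence), kinds)
  for (k in kinds) {
    if (is.null(tracks[[k]]))
      stop("missing annotation track: ", k)
    if (length(tracks[[k]]) != n)
      stop("track '", k, "' length ", length(tracks[[k]]),
           " does not match sequence length ", n)
  }
  raw <- c(aa_frequencies(sequence),
           dipeptide_frequencies(sequence),
           pI = isoelectric_point(sequence),
           mean_ges = mean_ges_hydrophobicity(sequence),
           frac_helix = annotation_fraction(tracks$helix),
           frac_strand = annotation_fraction(tracks$strand),
           frac_disorder = annotation_fraction(tracks$disorder),
           length = n,
           frac_tm = annotation_fraction(tracks$transmembrane),
           mol_weight = molecular_weight(sequence))
  stopifnot(identical(names(raw), feature_names()))
  scaled <- (raw - scaling$lower) / (scaling$upper - scaling$lower)
  pmin(pmax(scaled, 0), 1)
}

#' Assemble a feature matrix for many sequences
#'
#' @param records Data frame from [read_fasta()].
#' @param tracks Named list (by annotation kind) of named lists (by id) of
#'   masks, as from [read_annotation_mask()]; missing entries fall back to
#'   [heuristic_annotate()].
#' @param scaling A \code{scaling_spec}.
#' @return Numeric matrix, one row per record (rownames = ids), 428
#'   columns.
#' @export
feature_matrix <- function(records, tracks = NULL,
                           scaling = default_scaling()) {
  kinds <- c("helix", "strand", "disorder", "transmembrane")
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    seq <- records$seq[i]
    tr <- stats::setNames(lapply(kinds, function(k) {
      m <- tracks[[k]][[id]]
      if (is.null(m)) heuristic_annotate(seq, k) else m
    }), kinds)
    assemble_features(seq, tr, scaling)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- records$id
  mat
}
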