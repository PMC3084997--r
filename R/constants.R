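# Physico-chemical constants shipped as plain-text tables under
# inst/extdata/constants (each file carries its source citation).

.crystalnn_cache <- new.env(parent = emptyenv())

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in alphabetical order, the
#' order used throughout the feature registry.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Ambiguity letters accepted in sequences
#'
#' Non-standard letters tolerated at parse time (X unknown, B Asx, Z Glx,
#' U selenocysteine, O pyrrolysine, J Leu/Ile). Their treatment in each
#' feature is documented on the feature functions.
#'
#' @return Character vector of length 6.
#' @export
ambiguity_letters <- function() c("X", "B", "Z", "U", "O", "J")

read_constant_table <- function(name) {
  key <- paste0("tab_", name)
  if (!is.null(.crystalnn_cache[[key]])) return(.crystalnn_cache[[key]])
  path <- system.file("extdata", "constants", paste0(name, ".tsv"),
                      package = "crystalnn", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  .crystalnn_cache[[key]] <- tab
  tab
}

named_constant <- function(name, column) {
  tab <- read_constant_table(name)
  stats::setNames(tab[[column]], tab[[1L]])[amino_acids()]
}

#' GES hydrophobicity scale
#'
#' Per-residue transfer free energies (kcal/mol) of the
#' Goldman-Engelman-Steitz scale; positive values are hydrophobic.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
ges_scale <- function() named_constant("ges_scale", "ges")

#' Average residue masses
#'
#' Average residue masses in Daltons (amino acid minus one water).
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
residue_masses <- function() named_constant("residue_masses", "mass")

# mass of one water molecule, Da
water_mass <- function() 18.01528

#' Ionizable-group pKa table
#'
#' The EMBOSS default pKa set for the free termini and the seven ionizable
#' side chains, with the sign of the charge each group carries.
#'
#' @return Data frame with columns \code{group}, \code{pka}, \code{charge}.
#' @export
pka_table <- function() read_constant_table("pka_table")

#' Chou-Fasman secondary-structure propensities
#'
#' @return Data frame with columns \code{residue}, \code{p_helix},
#'   \code{p_strand} (values x100).
#' @export
chou_fasman <- function() read_constant_table("chou_fasman")

#' Background amino-acid composition
#'
#' Swiss-Prot-style average composition used as the neutral sampling
#' distribution by the synthetic generator.
#'
#' @return Named numeric vector of frequencies summing to 1.
#' @export
background_frequencies <- function() {
  p <- named_constant("background_freqs", "percent")
  p / sum(p)
}

#' Disorder propensity scale
#'
#' TOP-IDP per-residue disorder propensities (higher = disorder-promoting).
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
disorder_propensity <- function() named_constant("disorder_propensity", "topidp")
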