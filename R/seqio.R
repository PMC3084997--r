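# Readers and writers for all external artifacts: FASTA, per-residue
# annotation masks, label tables and sliding-window score tracks.
# All file positions are 1-based; internal indices are 0/1-based R vectors.
# Parsers reject malformed input rather than repairing it.

valid_alphabet <- function() c(amino_acids(), ambiguity_letters())

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and '*' stop characters stripped. The id is
#' the first whitespace-delimited token of the header; the remainder is
#' kept as the description. Any character outside the 20 standard codes
#' plus the ambiguity letters (X, B, Z, U, O, J) is an error naming the
#' character and the record.
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns \code{id}, \code{desc}, \code{seq}, one
#'   row per record in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("FASTA file is empty: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE, whole.header = TRUE)
  if (length(recs) == 0) stop("no FASTA records in: ", path)
  headers <- names(recs)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  desc <- sub("^[^ \t]+[ \t]*", "", headers)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(gsub("[*[:space:]]", "", vapply(recs, as.character, "")))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0)
      stop("record '", ids[i], "' has an empty sequence")
    letters_i <- strsplit(seqs[i], "")[[1]]
    bad <- setdiff(unique(letters_i), valid_alphabet())
    if (length(bad) > 0)
      stop("illegal character(s) '", paste(bad, collapse = "', '"),
           "' in record '", ids[i], "'")
  }
  data.frame(id = ids, desc = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: writing then reading returns identical
#' records. Sequence lines are folded at 60 characters.
#'
#' @param records Data frame with columns \code{id}, \code{seq} and
#'   optionally \code{desc}.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    body <- gsub("(.{60})", "\\1\n", records$seq[i])
    body <- sub("\n$", "", body)
    writeLines(c(paste0(">", header), body), con)
  }
  invisible(path)
}

#' Read a per-residue annotation mask file
#'
#' One line per sequence: \code{id<TAB>mask}, where the mask is a string
#' over {0,1} with one character per residue (1 = residue carries the
#' annotation). This is the route for supplying output of external
#' secondary-structure, disorder or transmembrane predictors.
#'
#' @param path Path to the mask TSV.
#' @param kind One of \code{"helix"}, \code{"strand"}, \code{"disorder"},
#'   \code{"transmembrane"}.
#' @return Named list of integer 0/1 vectors with attribute \code{kind}.
#' @export
read_annotation_mask <- function(path, kind) {
  kind <- match.arg(kind, c("helix", "strand", "disorder", "transmembrane"))
  if (!file.exists(path)) stop("mask file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !nzchar(parts[1]) || !nzchar(parts[2]))
      stop("malformed mask line: '", ln, "'")
    if (grepl("[^01]", parts[2]))
      stop("mask for '", parts[1], "' contains characters outside {0,1}")
    if (parts[1] %in% names(out)) stop("duplicate mask id: ", parts[1])
    out[[parts[1]]] <- as.integer(strsplit(parts[2], "")[[1]])
  }
  structure(out, kind = kind)
}

#' Write a per-residue annotation mask file
#'
#' @param masks Named list of 0/1 integer vectors.
#' @param path Output path.
#' @export
write_annotation_mask <- function(masks, path) {
  lines <- vapply(names(masks), function(id) {
    paste0(id, "\t", paste(masks[[id]], collapse = ""))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled dataset table
#'
#' One \code{id<TAB>label} line per sequence, label 1 for
#' diffraction-quality crystals and 0 for work stopped.
#'
#' @param path Path to the label TSV.
#' @return Data frame with columns \code{id}, \code{label} in file order;
#'   empty file gives zero rows.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(id = character(0), label = integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) stop("malformed label line: '", lines[bad[1]], "'")
  ids <- vapply(parts, `[`, character(1), 1L)
  lab <- vapply(parts, `[`, character(1), 2L)
  if (!all(lab %in% c("0", "1")))
    stop("label outside {0,1} for id '", ids[which(!lab %in% c("0", "1"))[1]], "'")
  if (anyDuplicated(ids))
    stop("duplicate id in label table: ", ids[duplicated(ids)][1])
  data.frame(id = ids, label = as.integer(lab), stringsAsFactors = FALSE)
}

#' Write a label table
#'
#' @param labels Data frame with columns \code{id}, \code{label}.
#' @param path Output path.
#' @export
write_label_table <- function(labels, path) {
  writeLines(paste0(labels$id, "\t", labels$label), path)
  invisible(path)
}

#' Write a sliding-window score track
#'
#' Tab-separated with a header line, one row per window center: 1-based
#' center position and the score with six decimal places. Round-trips
#' through [read_score_track()] to within 1e-6.
#'
#' @param profile A \code{window_profile} (see [profile_sequence()]).
#' @param path Output path.
#' @export
write_score_track <- function(profile, path) {
  stopifnot(inherits(profile, "window_profile"), length(profile$scores) > 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("position\tscore", con)
  writeLines(sprintf("%d\t%.6f", profile$centers, profile$scores), con)
  invisible(path)
}

#' Read a sliding-window score track
#'
#' @param path Path written by [write_score_track()].
#' @return Data frame with columns \code{position}, \code{score}.
#' @export
read_score_track <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
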