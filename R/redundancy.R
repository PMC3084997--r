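# Single-linkage redundancy clustering over a user-supplied pairwise
# similarity table (e.g. alignment scores computed externally), and
# representative selection per cluster.

#' Read a pairwise similarity score table
#'
#' Three tab-separated columns: id_a, id_b, score. Self-pairs and
#' duplicate unordered pairs are rejected.
#'
#' @param path Path to the TSV (no header).
#' @return Data frame with columns \code{id_a}, \code{id_b},
#'   \code{score}.
#' @export
read_pair_scores <- function(path) {
  if (!file.exists(path)) stop("pair-score file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id_a", "id_b", "score"))
  validate_pair_scores(tab)
}

validate_pair_scores <- function(tab) {
  stopifnot(all(c("id_a", "id_b", "score") %in% names(tab)))
  if (!is.numeric(tab$score)) stop("pair scores must be numeric")
  if (any(tab$id_a == tab$id_b))
    stop("self-pair in score table: ", tab$id_a[tab$id_a == tab$id_b][1])
  key <- ifelse(tab$id_a < tab$id_b, paste(tab$id_a, tab$id_b),
                paste(tab$id_b, tab$id_a))
  if (anyDuplicated(key))
    stop("duplicate unordered pair: ", key[duplicated(key)][1])
  tab
}

#' Single-linkage clustering at a score threshold
#'
#' Two ids belong to the same cluster iff they are connected by a chain
#' of pairs with score >= threshold (union-find); ids in the universe
#' absent from all passing pairs are singletons. Clusters are numbered by
#' their lexicographically smallest member, so the result is invariant to
#' the order of pairs in the table.
#'
#' @param table Pair-score data frame (see [read_pair_scores()]).
#' @param universe Character vector of all ids to partition; defaults to
#'   the ids appearing in the table. Ids in the table but not in the
#'   universe are an error.
#' @param threshold Similarity threshold for linking.
#' @return A \code{cluster_set}: list with \code{membership} (named
#'   integer vector, id to cluster index), \code{clusters} (list of id
#'   vectors) and \code{representatives} (NULL until
#'   [pick_representatives()]).
#' @export
single_linkage <- function(table, threshold, universe = NULL) {
  table <- validate_pair_scores(table)
  stopifnot(is.finite(threshold))
  if (is.null(universe)) universe <- sort(unique(c(table$id_a, table$id_b)))
  unknown <- setdiff(unique(c(table$id_a, table$id_b)), universe)
  if (length(unknown) > 0)
    stop("id(s) in score table but not in universe: ",
         paste(unknown, collapse = ", "))
  parent <- seq_along(universe)
  names(parent) <- universe
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pass <- table[table$score >= threshold, , drop = FALSE]
  ia <- match(pass$id_a, universe); ib <- match(pass$id_b, universe)
  for (k in seq_len(nrow(pass))) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(universe), find, integer(1))
  # number clusters by lexicographically smallest member
  reps <- vapply(split(universe, root), min, character(1))
  ord <- order(reps)
  cluster_of_root <- stats::setNames(seq_along(ord), names(reps)[ord])
  membership <- cluster_of_root[as.character(root)]
  names(membership) <- universe
  clusters <- split(universe, membership)
  names(clusters) <- NULL
  structure(list(membership = membership, clusters = clusters,
                 representatives = NULL),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d ids in %d clusters\n",
              length(x$membership), length(x$clusters)))
  invisible(x)
}

#' Choose one representative per cluster
#'
#' @param clusters A \code{cluster_set} from [single_linkage()].
#' @param sequences Named character vector (or [read_fasta()] data frame)
#'   providing a sequence for every clustered id.
#' @param rule \code{"longest"} (ties by lexicographic id),
#'   \code{"first"} (lexicographically first id) or
#'   \code{"seeded-random"}.
#' @param seed Seed for \code{"seeded-random"}.
#' @return The \code{cluster_set} with \code{representatives} filled in
#'   (one id per cluster, in cluster order).
#' @export
pick_representatives <- function(clusters, sequences,
                                 rule = c("longest", "first", "seeded-random"),
                                 seed = 1L) {
  stopifnot(inherits(clusters, "cluster_set"))
  rule <- match.arg(rule)
  if (is.data.frame(sequences))
    sequences <- stats::setNames(sequences$seq, sequences$id)
  missing <- setdiff(names(clusters$membership), names(sequences))
  if (length(missing) > 0)
    stop("no sequence for id(s): ", paste(missing, collapse = ", "))
  pick_one <- function(ids, k) {
    ids <- sort(ids)  # lexicographic tie-break baked into the order
    switch(rule,
      first = ids[1],
      longest = ids[order(-nchar(sequences[ids]), ids)][1],
      `seeded-random` = with_seed(seed + k, ids[sample.int(length(ids), 1)]))
  }
  clusters$representatives <- vapply(seq_along(clusters$clusters),
                                     function(k) pick_one(clusters$clusters[[k]], k),
                                     character(1))
  clusters
}

#' Write a cluster table
#'
#' Tab-separated: cluster index, representative flag (1/0), id.
#'
#' @param clusters A \code{cluster_set} (representatives optional).
#' @param path Output path.
#' @export
write_clusters <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("cluster\trepresentative\tid", con)
  for (k in seq_along(clusters$clusters)) {
    for (id in clusters$clusters[[k]]) {
      rep_flag <- if (!is.null(clusters$representatives) &&
                      clusters$representatives[k] == id) 1L else 0L
      writeLines(sprintf("%d\t%d\t%s", k, rep_flag, id), con)
    }
  }
  invisible(path)
}
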