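#' Shared-peptide matrix between subfamilies
#'
#' Counts, for every pair of groups, the number of peptides present in both
#' peptide lists (exact set intersection). The diagonal is each group's list
#' size.
#'
#' @param groups List of at least two [peptide_group()] objects with unique
#'   ids.
#' @return Symmetric integer matrix with group ids as dimnames.
#' @export
shared_peptide_matrix <- function(groups) {
  stopifnot(length(groups) >= 2L)
  ids <- vapply(groups, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("group ids must be unique")
  peps <- lapply(groups, function(g) names(g$peptides))
  n <- length(groups)
  S <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    S[i, i] <- length(peps[[i]])
    if (i < n) for (j in seq.int(i + 1L, n)) {
      S[i, j] <- S[j, i] <- length(intersect(peps[[i]], peps[[j]]))
    }
  }
  S
}

#' Ward dendrogram of subfamilies from shared-peptide counts
#'
#' Converts shared-peptide counts to the dissimilarity
#' `d[i, j] = list_size - S[i, j]` (the simplest monotone inversion bounded
#' by the peptide-list size) and runs agglomerative Ward clustering.
#' Rows/columns are ordered lexicographically by group id first, so equal
#' dissimilarities resolve to the lexicographically smallest pair.
#'
#' @param S Symmetric shared-peptide count matrix with group-id dimnames
#'   (see [shared_peptide_matrix()]).
#' @param list_size The `L` in `d = L - S`; defaults to 70, the canonical
#'   peptides-per-group cap. Must be at least `max(S)`.
#' @return An [stats::hclust] tree with group ids as labels; serialize with
#'   [export_newick()].
#' @export
ward_dendrogram <- function(S, list_size = 70L) {
  if (!is.matrix(S) || nrow(S) < 2L || nrow(S) != ncol(S))
    stop("S must be a square matrix with at least 2 groups")
  if (is.null(rownames(S)) || !identical(rownames(S), colnames(S)))
    stop("S must carry identical row and column names")
  if (!isSymmetric(unname(S)))
    stop("shared-peptide matrix must be symmetric")
  if (list_size < max(S))
    stop("list_size must be at least the largest shared count")
  ord <- order(rownames(S))
  S <- S[ord, ord, drop = FALSE]
  d <- list_size - S
  diag(d) <- 0
  stats::hclust(stats::as.dist(d), method = "ward.D")
}

#' Export a dendrogram as Newick
#'
#' @param tree An [stats::hclust] tree (e.g. from [ward_dendrogram()]).
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
export_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Write / read a shared-peptide matrix as TSV
#'
#' @param S Matrix from [shared_peptide_matrix()].
#' @param path File path.
#' @return `write_shared_matrix()` returns `path` invisibly;
#'   `read_shared_matrix()` returns the integer matrix.
#' @export
write_shared_matrix <- function(S, path) {
  df <- data.frame(group_id = rownames(S), S, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shared_matrix
#' @export
read_shared_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  S <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(S) <- "integer"
  rownames(S) <- df[[1L]]
  S
}
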