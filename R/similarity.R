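#' Relaxed matching between two contact sets
#'
#' Counts the contacts two sets share when a pair of set A and a pair of
#' set B are considered the same contact whenever both residue indices
#' deviate by at most N (e.g. 3-15 and 3-16 match at N = 1). The count is
#' the size of a maximum-cardinality one-to-one matching on the
#' compatibility graph, which is deterministic and independent of input
#' order; at N = 0 it reduces to the size of the set intersection.
#'
#' @param A,B [contact_set]s (canonical, duplicate-free).
#' @param N neighborhood relaxation, 0, 1, 2 or 3.
#' @return Non-negative integer, at most \code{min(nrow(A), nrow(B))}.
#' @export
relaxed_match_count <- function(A, B, N = 0) {
  stopifnot(N %in% 0:3)
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0L || nB == 0L) return(0L)
  if (N == 0) {
    return(sum(pair_key(A$i, A$j) %in% pair_key(B$i, B$j)))
  }
  ## adjacency lists in deterministic (i, j) order
  oa <- order(A$i, A$j); ob <- order(B$i, B$j)
  Ai <- A$i[oa]; Aj <- A$j[oa]; Bi <- B$i[ob]; Bj <- B$j[ob]
  adj <- lapply(seq_len(nA), function(a)
    which(abs(Bi - Ai[a]) <= N & abs(Bj - Aj[a]) <= N))
  ## augmenting-path maximum bipartite matching
  match_b <- integer(nB)                 # 0 = unmatched
  try_augment <- function(a, seen) {
    for (b in adj[[a]]) {
      if (seen[b]) next
      seen[b] <- TRUE
      if (match_b[b] == 0L || Recall(match_b[b], seen)) {
        match_b[b] <<- a
        return(TRUE)
      }
    }
    FALSE
  }
  count <- 0L
  for (a in seq_len(nA))
    if (try_augment(a, logical(nB))) count <- count + 1L
  count
}

#' Jaccard similarity between two contact sets
#'
#' \eqn{J_{AB} = |A \cap B| / |A \cup B|}, with the intersection size M
#' given by [relaxed_match_count()] and the union size defined as
#' \eqn{|A| + |B| - M} so that \eqn{J \le 1} also holds under relaxation.
#' At N = 0 this is the ordinary set Jaccard.
#'
#' @inheritParams relaxed_match_count
#' @return J in \code{[0, 1]}; \code{NA} when both sets are empty.
#' @examples
#' A <- contact_set(3, 15, 1); B <- contact_set(3, 16, 1)
#' jaccard(A, B, N = 0)  # 0
#' jaccard(A, B, N = 1)  # 1
#' @export
jaccard <- function(A, B, N = 0) {
  if (nrow(A) == 0L && nrow(B) == 0L) return(NA_real_)
  M <- relaxed_match_count(A, B, N)
  M / (nrow(A) + nrow(B) - M)
}

#' Pairwise Jaccard similarity matrix
#'
#' All pairwise [jaccard()] values between two or more prediction sets,
#' optionally after truncating each set to its top-k contacts by
#' confidence.
#'
#' @param sets list of two or more [contact_set]s; names (or the sets'
#'   source labels) become row/column labels.
#' @param N neighborhood relaxation, 0..3.
#' @param top_k optional truncation applied to each set before comparison.
#' @return A symmetric matrix of class \code{contact_similarity} with unit
#'   diagonal and attribute \code{N}.
#' @export
similarity_matrix <- function(sets, N = 0, top_k = NULL) {
  if (length(sets) < 2L)
    stop("similarity requires at least two contact sets")
  labels <- names(sets)
  if (is.null(labels))
    labels <- vapply(sets, attr, "", "source")
  if (!is.null(top_k))
    sets <- lapply(sets, select_top, k = top_k)
  m <- length(sets)
  J <- diag(1, m)
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    J[a, b] <- J[b, a] <- jaccard(sets[[a]], sets[[b]], N)
  }
  dimnames(J) <- list(labels, labels)
  structure(J, N = N, class = c("contact_similarity", "matrix", "array"))
}

#' @export
print.contact_similarity <- function(x, ...) {
  cat(sprintf("Jaccard similarity matrix (N = %d):\n", attr(x, "N")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Hierarchical clustering order of a similarity matrix
#'
#' Agglomerative clustering (average linkage) on the dissimilarity
#' \code{1 - J}; ties merge in label order. Used to order the heatmap and
#' draw the dendrogram.
#'
#' @param matrix a \code{contact_similarity}.
#' @return List with \code{order} (leaf labels in plotting order),
#'   \code{merge}, \code{height}, and the underlying \code{hclust}
#'   object.
#' @export
cluster_order <- function(matrix) {
  h <- stats::hclust(stats::as.dist(1 - unclass(matrix)), method = "average")
  list(order = rownames(matrix)[h$order], merge = h$merge,
       height = h$height, hclust = h)
}

#' Write a similarity matrix as a labeled TSV table
#'
#' @param matrix a \code{contact_similarity}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_similarity <- function(matrix, path) {
  utils::write.table(round(unclass(matrix), 6), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
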