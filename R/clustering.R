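#' Complete-linkage hierarchical clustering of an expression matrix
#'
#' Agglomerative clustering with complete linkage on Euclidean distances,
#' over rows (transcripts) or columns (samples) of a z-scored expression
#' matrix. Deterministic given the input order (ties resolved by
#' \code{\link[stats]{hclust}}'s fixed merge rule, which takes the
#' lower-index pair first).
#'
#' @param object a \linkS4class{StageExpression} (typically measure
#'   \code{"zscore"}) or bare numeric matrix.
#' @param axis \code{"rows"} or \code{"columns"}.
#' @return An \code{\link[stats]{hclust}} tree.
#' @export
hierarchicalCluster <- function(object, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- if (is(object, "StageExpression")) exprValues(object) else as.matrix(object)
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2L) stop("need >= 2 items on the clustered axis")
  if (!all(is.finite(m))) stop("non-finite values in clustered matrix")
  stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
}

#' Cut a dendrogram into k clusters
#'
#' Cuts the merge tree at the height yielding exactly \code{k} clusters.
#' Cluster ids are reassigned 1..k by decreasing cluster size; ties by the
#' first member's position in the input order.
#'
#' @param tree an \code{\link[stats]{hclust}} tree.
#' @param k number of clusters, between 1 and the number of leaves.
#' @return Named integer vector mapping each item to its cluster id, plus the
#'   tree as attribute \code{"tree"}.
#' @export
cutToK <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  raw <- stats::cutree(tree, k = k)
  sizes <- table(raw)
  first <- vapply(names(sizes), function(cl) min(which(raw == as.integer(cl))),
                  numeric(1))
  ord <- order(-as.integer(sizes), first)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  out <- relabel[raw]
  names(out) <- names(raw)
  attr(out, "tree") <- tree
  out
}

#' Mean stage profiles per cluster
#'
#' For each cluster and each stage, the mean z-score over member transcripts
#' and the stage's replicate samples (the dark mean-accumulation lines of a
#' cluster-profile plot).
#'
#' @param assignment named cluster vector from \code{\link{cutToK}}.
#' @param object the clustered \linkS4class{StageExpression} (zscore).
#' @param sheet optional sample sheet; defaults to the object's colData.
#' @return Matrix clusters x stages of mean z-scores; attribute
#'   \code{"sizes"} carries cluster sizes.
#' @export
clusterProfiles <- function(assignment, object, sheet = NULL) {
  z <- exprValues(object)
  common <- intersect(names(assignment), rownames(z))
  if (length(common) == 0L) stop("assignment and matrix share no transcripts")
  st <- if (is.null(sheet)) as.character(stageOf(object))
        else as.character(sheet$stage[match(colnames(z), sheet$sample_id)])
  ks <- sort(unique(assignment))
  stages <- intersect(stageLevels(), unique(st))
  prof <- matrix(NA_real_, length(ks), length(stages),
                 dimnames = list(paste0("cluster", ks), stages))
  sizes <- integer(length(ks))
  for (i in seq_along(ks)) {
    members <- intersect(names(assignment)[assignment == ks[i]], common)
    sizes[i] <- length(members)
    if (length(members) == 0L) {
      warning("cluster ", ks[i], " has no members in the matrix; excluded")
      next
    }
    for (s in stages)
      prof[i, s] <- mean(z[members, st == s, drop = FALSE])
  }
  keep <- sizes > 0L
  prof <- prof[keep, , drop = FALSE]
  attr(prof, "sizes") <- sizes[keep]
  prof
}
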