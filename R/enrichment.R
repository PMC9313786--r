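#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' k annotated transcripts when n are selected from a universe of N of which
#' K are annotated. Exact, via \code{\link[stats]{phyper}}.
#'
#' @param k selected transcripts in the bin.
#' @param n selected transcripts.
#' @param K universe transcripts in the bin.
#' @param N universe size.
#' @return p-value in [0, 1].
#' @export
hypergeomUpper <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > min(n, K) || n > N || K > N)
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(n, K); ",
         "n, K <= N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# expand "15.5.30" to itself and its ancestors "15.5", "15"
.binAncestors <- function(bincode) {
  parts <- strsplit(bincode, ".", fixed = TRUE)[[1]]
  vapply(seq_along(parts), function(i) paste(parts[1:i], collapse = "."),
         character(1))
}

#' Functional-bin over-representation analysis
#'
#' One upper-tail hypergeometric test per functional bin with at least one
#' universe member, Benjamini-Hochberg adjustment across tested bins, and an
#' enrichment call at \code{FDR <= alpha}. By default a transcript annotated
#' to a leaf bin (dot-separated hierarchy, e.g. \code{"15.5.30"}) also counts
#' toward all ancestor bins (\code{"15.5"}, \code{"15"}), so top-level
#' category summaries are directly testable; set \code{ancestors = FALSE} for
#' leaf-only testing.
#'
#' @param selected character vector of selected transcript ids (must be a
#'   subset of \code{universe}).
#' @param universe character vector of background transcript ids (typically
#'   all transcripts passing the expression filter).
#' @param annot annotation data.frame (transcript_id, bincode, description),
#'   e.g. from \code{\link{readAnnotation}}.
#' @param alpha FDR threshold for the \code{enriched} call.
#' @param ancestors logical; count transcripts toward ancestor bins too.
#' @return data.frame: bincode, k, n, K, N, p_value, FDR, enriched; ordered
#'   by p-value.
#' @export
enrichBins <- function(selected, universe, annot, alpha = 0.05,
                       ancestors = TRUE) {
  selected <- unique(selected); universe <- unique(universe)
  if (length(setdiff(selected, universe)) > 0L)
    stop("selected set is not a subset of the universe")
  annot <- annot[annot$transcript_id %in% universe, , drop = FALSE]
  if (isTRUE(ancestors)) {
    expand <- lapply(seq_len(nrow(annot)), function(i)
      data.frame(transcript_id = annot$transcript_id[i],
                 bincode = .binAncestors(annot$bincode[i])))
    annot <- unique(do.call(rbind, expand))
  } else {
    annot <- unique(annot[, c("transcript_id", "bincode")])
  }
  N <- length(universe)
  n <- length(selected)
  bins <- split(annot$transcript_id, annot$bincode)
  res <- do.call(rbind, lapply(names(bins), function(b) {
    members <- unique(bins[[b]])
    K <- length(members)
    k <- length(intersect(members, selected))
    data.frame(bincode = b, k = k, n = n, K = K, N = N,
               p_value = hypergeomUpper(k, n, K, N))
  }))
  res$FDR <- bhAdjust(res$p_value)
  res$enriched <- res$FDR <= alpha
  res[order(res$p_value, res$bincode), ]
}
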