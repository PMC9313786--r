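#' Filter to expressed transcripts
#'
#' Keeps transcripts with (1) at least one read count in at least
#' \code{min_samples} samples and (2) a total (sum over samples) of at least
#' \code{min_total_cpm} counts per million. Both thresholds are inclusive.
#' \code{min_samples} defaults to 3, the smallest group size of the triplicate
#' design.
#'
#' @param object a \linkS4class{StageCounts}.
#' @param min_samples minimum number of samples with >= 1 count.
#' @param min_total_cpm minimum sum of per-sample CPM across all samples.
#' @return The filtered \linkS4class{StageCounts}.
#' @export
filterExpressed <- function(object, min_samples = 3L, min_total_cpm = 3) {
  cts <- counts(object)
  cpm <- exprValues(toCPM(object))
  keep <- rowSums(cts >= 1) >= min_samples & rowSums(cpm) >= min_total_cpm
  if (!any(keep))
    stop("expression filter removed all transcripts; review min_samples/",
         "min_total_cpm thresholds")
  object[keep, ]
}

# conditional NB log-likelihood of a group of equal-mean samples given their
# sum, as a function of size r = 1/phi (lgamma terms in y only are dropped)
.condLogLik <- function(y, r) {
  y <- as.matrix(y)
  n <- ncol(y)
  s <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(s + n * r)
}

#' Common qCML dispersion estimate
#'
#' Single negative-binomial dispersion maximizing the conditional
#' log-likelihood summed over transcripts and stage groups, after equalizing
#' library sizes: counts are scaled to the geometric-mean library size
#' (pseudo-counts), which makes the within-group equal-mean conditional
#' likelihood applicable. This is the common-dispersion core of the
#' quantile-adjusted conditional maximum likelihood approach; per-transcript
#' (tagwise) empirical-Bayes shrinkage is deliberately not performed.
#'
#' @param object a \linkS4class{StageCounts}.
#' @param interval search interval for phi, default [1e-6, 10].
#' @return List with \code{phi} (the estimate) and \code{method} tag.
#' @export
estimateCommonDispersion <- function(object, interval = c(1e-6, 10)) {
  cts <- counts(object)
  grp <- stageOf(object)
  tab <- table(grp)
  if (sum(tab >= 2L) < 1L || any(tab < 2L))
    stop("dispersion estimation needs >= 2 replicates in every group")
  lib <- colSums(cts)
  lstar <- exp(mean(log(lib)))
  pseudo <- sweep(cts, 2, lstar / lib, "*")
  groups <- split(seq_len(ncol(cts)), grp, drop = TRUE)
  negll <- function(phi) {
    r <- 1 / phi
    -sum(vapply(groups, function(j) {
      sum(.condLogLik(pseudo[, j, drop = FALSE], r))
    }, numeric(1)))
  }
  opt <- stats::optimize(negll, interval = interval, tol = 1e-6)
  phi <- opt$minimum
  width <- interval[2] - interval[1]
  if (phi - interval[1] < 1e-4 * width || interval[2] - phi < 1e-4 * width)
    warning("common dispersion estimate at search boundary: ", signif(phi, 3))
  list(phi = phi, method = "qCML-common")
}

#' Exact negative-binomial test for a two-group comparison
#'
#' Conditions on the total of the two group sums (after scaling both groups to
#' a common effective library size) and sums the probabilities of all splits
#' no more likely than the observed one. Group sums are negative-binomial with
#' size \code{n_group / phi}; with \code{phi = 0} the conditional distribution
#' is exactly binomial and the test reduces to the exact binomial split test.
#'
#' @param counts_A,counts_B non-negative count vectors (one entry per sample).
#' @param lib_A,lib_B effective library sizes of the samples in each group.
#' @param phi NB dispersion (0 for Poisson).
#' @return Two-sided p-value in [0, 1]; a degenerate total of 0 gives 1.
#' @export
nbExactTest <- function(counts_A, counts_B, lib_A, lib_B, phi = 0) {
  stopifnot(all(counts_A >= 0), all(counts_B >= 0),
            all(lib_A > 0), all(lib_B > 0),
            length(lib_A) == length(counts_A),
            length(lib_B) == length(counts_B))
  nA <- length(counts_A); nB <- length(counts_B)
  lstar <- exp(mean(log(c(lib_A, lib_B))))
  sA <- round(sum(counts_A * lstar / lib_A))
  sB <- round(sum(counts_B * lstar / lib_B))
  s <- sA + sB
  if (s == 0) return(1)
  pA <- nA / (nA + nB)
  y <- 0:s
  if (phi <= 0) {
    logp <- stats::dbinom(y, s, pA, log = TRUE)
  } else {
    muA <- s * pA; muB <- s * (1 - pA)
    logp <- stats::dnbinom(y, size = nA / phi, mu = muA, log = TRUE) +
      stats::dnbinom(s - y, size = nB / phi, mu = muB, log = TRUE)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  obs <- logp[sA + 1]
  min(1, sum(exp(logp[logp <= obs + 1e-10])))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper around
#' \code{\link[stats]{p.adjust}(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise differential-expression contrast
#'
#' TMM-scaled exact negative-binomial test of stage B versus stage A for every
#' transcript, with a common qCML dispersion estimated on the two groups,
#' Benjamini-Hochberg adjustment across tested transcripts, and direction
#' calls. log2 fold-changes are computed from effective-library CPM group
#' means with a 0.5-count prior. A transcript is called \code{up} or
#' \code{down} (by sign of log2FC, B relative to A) when \code{FDR <= alpha}
#' and \code{|log2FC| >= lfc}, both thresholds inclusive; otherwise \code{ns}.
#'
#' @param object a \linkS4class{StageCounts} (normally pre-filtered with
#'   \code{\link{filterExpressed}}).
#' @param stage_A,stage_B stage labels to compare (B vs A).
#' @param alpha FDR cut-off (default 0.05).
#' @param lfc minimum absolute log2 fold-change (default 1.5).
#' @param phi optional fixed dispersion; estimated from the two groups when
#'   missing.
#' @return data.frame (one row per transcript): \code{transcript_id},
#'   \code{log2FC}, \code{p_value}, \code{FDR}, \code{direction}; attributes
#'   \code{contrast} and \code{phi}.
#' @export
runContrast <- function(object, stage_A, stage_B, alpha = 0.05, lfc = 1.5,
                        phi = NULL) {
  .checkStage(c(stage_A, stage_B))
  st <- as.character(stageOf(object))
  if (!stage_A %in% st || !stage_B %in% st)
    stop("stage(s) absent from the sample sheet: ",
         paste(setdiff(c(stage_A, stage_B), st), collapse = ", "))
  sel <- st %in% c(stage_A, stage_B)
  sub <- object[, sel]
  cts <- counts(sub)
  grp <- as.character(stageOf(sub))
  f <- tmmFactors(sub)
  efflib <- colSums(cts) * f
  if (is.null(phi))
    phi <- estimateCommonDispersion(sub)$phi
  iA <- which(grp == stage_A); iB <- which(grp == stage_B)
  p <- vapply(seq_len(nrow(cts)), function(i) {
    nbExactTest(cts[i, iA], cts[i, iB], efflib[iA], efflib[iB], phi)
  }, numeric(1))
  cpm <- sweep(cts + 0.5, 2, efflib, "/") * 1e6
  log2FC <- log2(rowMeans(cpm[, iB, drop = FALSE])) -
    log2(rowMeans(cpm[, iA, drop = FALSE]))
  FDR <- bhAdjust(p)
  direction <- ifelse(FDR <= alpha & abs(log2FC) >= lfc,
                      ifelse(log2FC > 0, "up", "down"), "ns")
  res <- data.frame(transcript_id = rownames(cts), log2FC = log2FC,
                    p_value = p, FDR = FDR, direction = direction,
                    row.names = NULL)
  attr(res, "contrast") <- c(stage_A, stage_B)
  attr(res, "phi") <- phi
  res
}

#' All pairwise stage contrasts
#'
#' Runs \code{\link{runContrast}} for every unordered pair of stages present,
#' sharing a single common dispersion estimated on the full design.
#'
#' @inheritParams runContrast
#' @return Named list of contrast data.frames, names \code{"A_vs_B"} meaning
#'   B relative to A.
#' @export
allPairwiseContrasts <- function(object, alpha = 0.05, lfc = 1.5) {
  st <- levels(stageOf(object))
  phi <- estimateCommonDispersion(object)$phi
  out <- list()
  for (i in seq_along(st)) for (j in seq_along(st)) {
    if (j > i) {
      nm <- paste0(st[i], "_vs_", st[j])
      out[[nm]] <- runContrast(object, st[i], st[j], alpha, lfc, phi = phi)
    }
  }
  out
}

#' Venn regions of three significant sets relative to a reference stage
#'
#' Given the contrasts of SWE, ATT and PEN each against niS (or any three
#' contrasts sharing a transcript universe), returns the seven Venn regions of
#' the three significant sets plus per-contrast up/down counts.
#'
#' @param results named list of three contrast data.frames from
#'   \code{\link{runContrast}}.
#' @return List with \code{regions} (named list of 7 transcript-id vectors,
#'   names like \code{"A&B"}, \code{"A_only"}, \code{"A&B&C"}) and
#'   \code{counts} (data.frame of up/down/total per contrast).
#' @export
stageOverlapSets <- function(results) {
  stopifnot(length(results) == 3L)
  uni <- lapply(results, function(r) sort(r$transcript_id))
  if (!all(vapply(uni[-1], identical, logical(1), uni[[1]])))
    stop("contrasts do not share a transcript universe")
  sig <- lapply(results, function(r) r$transcript_id[r$direction != "ns"])
  nm <- names(results)
  if (is.null(nm)) nm <- c("A", "B", "C")
  A <- sig[[1]]; B <- sig[[2]]; C <- sig[[3]]
  regions <- list(
    setdiff(setdiff(A, B), C),
    setdiff(setdiff(B, A), C),
    setdiff(setdiff(C, A), B),
    setdiff(intersect(A, B), C),
    setdiff(intersect(A, C), B),
    setdiff(intersect(B, C), A),
    intersect(intersect(A, B), C))
  names(regions) <- c(paste0(nm, "_only"),
                      paste0(nm[1], "&", nm[2]), paste0(nm[1], "&", nm[3]),
                      paste0(nm[2], "&", nm[3]),
                      paste0(nm, collapse = "&"))
  cnt <- data.frame(
    contrast = nm,
    up = vapply(results, function(r) sum(r$direction == "up"), integer(1)),
    down = vapply(results, function(r) sum(r$direction == "down"), integer(1)),
    row.names = NULL)
  cnt$total <- cnt$up + cnt$down
  list(regions = regions, counts = cnt)
}
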