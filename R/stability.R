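#' geNorm expression stability
#'
#' For each candidate reference gene j, the stability value M is the mean
#' over all other candidates k of the standard deviation across samples of
#' log2(q_j / q_k), where q are relative quantities. The least stable
#' candidate (highest M) is excluded and M recomputed, iterating until two
#' candidates remain; those two share an identical final M (their mutual
#' log-ratio sd) and jointly occupy rank 1. The reported M of every other
#' candidate is its value at the step it was excluded. Pairwise variations
#' V(n/n+1) -- the sd across samples of the log2 ratio of normalization
#' factors (geometric means of the n vs n+1 most stable candidates) -- say
#' how many reference genes are needed (values below ~0.15 are
#' conventionally taken as "no benefit from adding one more").
#'
#' @param q numeric matrix of strictly positive relative quantities,
#'   candidates x samples.
#' @return List with \code{M} (named, reported per candidate), \code{rank}
#'   (competition ranks: final pair 1, 1, then 3, 4, ... by exclusion order),
#'   \code{stability_order} (most stable first), \code{exclusion_order} and
#'   \code{V} (named vector V2/3, V3/4, ...).
#' @export
geNorm <- function(q) {
  q <- as.matrix(q)
  if (nrow(q) < 3L) stop("geNorm needs >= 3 candidates")
  if (ncol(q) < 2L) stop("geNorm needs >= 2 samples")
  if (any(q <= 0) || any(!is.finite(q)))
    stop("relative quantities must be strictly positive and finite")
  if (is.null(rownames(q))) rownames(q) <- paste0("g", seq_len(nrow(q)))
  lq <- log2(q)
  mOf <- function(rows) {
    vapply(rows, function(j) {
      others <- setdiff(rows, j)
      mean(vapply(others, function(k) stats::sd(lq[j, ] - lq[k, ]),
                  numeric(1)))
    }, numeric(1))
  }
  current <- rownames(q)
  M_report <- stats::setNames(numeric(nrow(q)), rownames(q))
  excluded <- character(0)
  while (length(current) > 2L) {
    M <- mOf(current)
    names(M) <- current
    worst <- current[which.max(M)]
    M_report[worst] <- M[worst]
    excluded <- c(excluded, worst)
    current <- setdiff(current, worst)
  }
  Mfinal <- mOf(current)
  M_report[current] <- Mfinal
  stability_order <- c(current, rev(excluded))
  rk <- stats::setNames(integer(nrow(q)), rownames(q))
  rk[current] <- 1L
  if (length(excluded))
    rk[rev(excluded)] <- 2L + seq_along(excluded)
  # pairwise variations V(n/n+1) along the stability order
  k <- nrow(q)
  V <- numeric(0)
  if (k >= 3L) {
    nf <- function(n) colMeans(lq[stability_order[seq_len(n)], , drop = FALSE])
    V <- vapply(2:(k - 1), function(n) stats::sd(nf(n) - nf(n + 1)),
                numeric(1))
    names(V) <- paste0("V", 2:(k - 1), "/", 3:k)
  }
  list(M = M_report, rank = rk, stability_order = stability_order,
       exclusion_order = excluded, V = V)
}

#' NormFinder stability values
#'
#' Model-based stability on log-scale quantities. Within each sample group,
#' the gene-set average of each sample is subtracted, per-gene residual
#' variances are corrected for the induced dependence (a gene's own noise
#' enters the subtracted average), and per-gene group biases are taken as the
#' deviation of the gene's group mean residual from its average over groups.
#' The stability value combines the two sources,
#' \code{SV_i = mean_g(|bias_ig| + sd_ig / sqrt(n_g))}; lower is more
#' stable. With a single group (or none given) the corrected intra-group
#' standard deviation alone is returned, with a warning.
#'
#' @param x numeric matrix of log-scale quantities, candidates x samples.
#' @param groups factor/character of sample groups (length ncol(x)).
#' @return Named numeric vector of stability values (lower = more stable).
#' @export
normFinder <- function(x, groups = NULL) {
  x <- as.matrix(x)
  k <- nrow(x)
  if (k < 3L) stop("NormFinder needs >= 3 candidates")
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(k))
  if (is.null(groups) || length(unique(groups)) < 2L) {
    warning("single sample group: falling back to ungrouped variance-based ",
            "stability")
    d <- sweep(x, 2, colMeans(x))
    v <- .rowSds(d)^2
    sig2 <- pmax((v - sum(v) / (1 - 1 / k) / k^2) / (1 - 2 / k), 0)
    return(sqrt(sig2))
  }
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) stop("every group needs >= 2 samples")
  G <- nlevels(groups)
  gl <- levels(groups)
  sig2 <- matrix(0, k, G, dimnames = list(rownames(x), gl))
  dbar <- matrix(0, k, G, dimnames = list(rownames(x), gl))
  ng <- stats::setNames(as.integer(table(groups)[gl]), gl)
  for (g in gl) {
    z <- x[, groups == g, drop = FALSE]
    d <- sweep(z, 2, colMeans(z))
    v <- .rowSds(d)^2
    tot <- sum(v) / (1 - 1 / k)           # unbiased total of true variances
    sig2[, g] <- pmax((v - tot / k^2) / (1 - 2 / k), 0)
    dbar[, g] <- rowMeans(d)
  }
  bias <- dbar - rowMeans(dbar)
  sv <- rowMeans(abs(bias) + sqrt(sweep(sig2, 2, ng, "/")))
  stats::setNames(as.numeric(sv), rownames(x))
}

#' BestKeeper correlation with the reference index
#'
#' The BestKeeper index of a sample is the geometric mean of the candidate
#' quantities, i.e. the arithmetic mean of the candidates' Cq values. Each
#' candidate's r is the Pearson correlation of its Cq values with the index
#' across samples; higher r means more stable. A candidate with constant Cq
#' has undefined r and is flagged (\code{NA}, to be ranked last). The Cq
#' standard deviation is returned as a descriptive column.
#'
#' @param cq numeric matrix of (mean) Cq values, candidates x samples.
#' @return data.frame: candidate, r, sd_cq, constant.
#' @export
bestKeeper <- function(cq) {
  cq <- as.matrix(cq)
  if (nrow(cq) < 2L) stop("BestKeeper needs >= 2 candidates")
  if (is.null(rownames(cq))) rownames(cq) <- paste0("g", seq_len(nrow(cq)))
  index <- colMeans(cq)
  sds <- .rowSds(cq)
  r <- vapply(seq_len(nrow(cq)), function(j) {
    if (sds[j] == 0 || stats::sd(index) == 0) NA_real_
    else stats::cor(cq[j, ], index)
  }, numeric(1))
  data.frame(candidate = rownames(cq), r = r, sd_cq = sds,
             constant = sds == 0, row.names = NULL)
}

#' Integrate per-method stability ranks by geometric mean
#'
#' Competition ("min") ranks per method -- ascending geNorm M, ascending
#' NormFinder SV, descending BestKeeper r; tied candidates share the smaller
#' rank and the following rank is skipped -- integrated as the geometric mean
#' GM of the three ranks, reported to 2 decimals, final ordering by GM
#' ascending. geNorm ranks may be supplied directly (the stepwise-exclusion
#' ranks with the final pair tied at 1); otherwise they are computed from M.
#' An undefined BestKeeper r (constant candidate) is ranked last.
#'
#' @param M named numeric vector of geNorm M values.
#' @param SV NormFinder stability values (same candidates).
#' @param r BestKeeper correlation coefficients (same candidates).
#' @param rank_genorm optional explicit geNorm ranks.
#' @return A \linkS4class{StabilityRanking}.
#' @export
integrateRanks <- function(M, SV, r, rank_genorm = NULL) {
  n <- length(M)
  if (length(SV) != n || length(r) != n)
    stop("M, SV and r must cover the same candidates")
  cand <- names(M)
  if (is.null(cand)) cand <- paste0("g", seq_len(n))
  if (!is.null(names(SV))) SV <- SV[cand]
  if (!is.null(names(r))) r <- r[cand]
  rg <- if (is.null(rank_genorm)) rank(M, ties.method = "min")
        else as.integer(rank_genorm[cand])
  rn <- rank(SV, ties.method = "min")
  rneg <- -r
  rneg[is.na(rneg)] <- Inf
  rb <- rank(rneg, ties.method = "min")
  gm <- round((as.numeric(rg) * rn * rb)^(1 / 3), 2)
  tab <- data.frame(candidate = cand, M = as.numeric(M), SV = as.numeric(SV),
                    r = as.numeric(r), rank_genorm = as.integer(rg),
                    rank_normfinder = as.integer(rn),
                    rank_bestkeeper = as.integer(rb), GM = gm,
                    row.names = NULL)
  tab <- tab[order(tab$GM, tab$candidate), ]
  rownames(tab) <- NULL
  new("StabilityRanking", table = tab, pairwiseVariation = numeric(0),
      exclusionOrder = character(0))
}

#' Full reference-gene stability ranking from a Cq table
#'
#' Runs the three stability algorithms on their native scales -- geNorm on
#' relative quantities \code{efficiency^(Cq_min - Cq)}, NormFinder on log2
#' relative quantities, BestKeeper on the mean Cq values themselves -- and
#' integrates the rankings by geometric mean.
#'
#' @param cq a \linkS4class{CqTable} or a candidates x samples matrix of
#'   mean Cq values (no missing cells).
#' @param groups sample grouping for NormFinder (e.g. stages); optional.
#' @param candidates optional subset of gene ids to rank.
#' @param efficiency amplification efficiency (default 2).
#' @return A \linkS4class{StabilityRanking} with geNorm pairwise variations
#'   and exclusion order filled in.
#' @export
rankStability <- function(cq, groups = NULL, candidates = NULL,
                          efficiency = 2) {
  m <- if (is(cq, "CqTable")) cqMeans(cq) else as.matrix(cq)
  if (!is.null(candidates)) {
    miss <- setdiff(candidates, rownames(m))
    if (length(miss)) stop("candidate(s) absent from Cq table: ",
                           paste(miss, collapse = ", "))
    m <- m[candidates, , drop = FALSE]
  }
  if (any(is.na(m)))
    stop("stability ranking needs every candidate measured in every sample")
  rq <- efficiency^(apply(m, 1, min) - m)
  gn <- geNorm(rq)
  nf <- normFinder(log2(rq), groups = groups)
  bk <- bestKeeper(m)
  r <- stats::setNames(bk$r, bk$candidate)[rownames(m)]
  sr <- integrateRanks(gn$M[rownames(m)], nf[rownames(m)], r,
                       rank_genorm = gn$rank)
  sr@pairwiseVariation <- gn$V
  sr@exclusionOrder <- gn$exclusion_order
  sr
}
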