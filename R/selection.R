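.log2RpkmStats <- function(object) {
  rpkm <- exprValues(toRPKM(object))
  list(rpkm = rpkm)
}

#' Housekeeper candidate selection
#'
#' Multi-criteria filter for stable reference genes. A transcript qualifies
#' when it satisfies all of:
#' \enumerate{
#'   \item expression in all samples (RPKM > 0 everywhere);
#'   \item mean log2(RPKM) of at least \code{min_log2rpkm};
#'   \item low variance: coefficient of variation (CV) and median absolute
#'     deviation (MAD) of its log2(RPKM) row both within the lower
#'     \code{low_var_quantile} (default 10\%) of the population passing
#'     criteria 1-2;
#'   \item no significant fold change in any pairwise stage contrast
#'     (FDR > \code{alpha} or |log2FC| < \code{lfc} in every contrast).
#' }
#'
#' @param object a \linkS4class{StageCounts}.
#' @param de list of all pairwise contrasts from
#'   \code{\link{allPairwiseContrasts}} (all 6 stage pairs for a 4-stage
#'   design).
#' @param min_log2rpkm expression floor (default 5).
#' @param low_var_quantile CV/MAD quantile (default 0.10).
#' @param alpha,lfc significance thresholds defining "significant fold
#'   change" (defaults 0.05 and 1.5).
#' @return data.frame of selected candidates: transcript_id, mean_log2rpkm,
#'   se, CV, MAD, ordered by CV; attribute \code{"criteria"} records the
#'   thresholds and the realized CV/MAD cut-offs.
#' @export
selectHousekeepers <- function(object, de, min_log2rpkm = 5,
                               low_var_quantile = 0.10, alpha = 0.05,
                               lfc = 1.5) {
  n_pairs <- choose(length(unique(as.character(stageOf(object)))), 2)
  if (length(de) < n_pairs)
    stop("need all ", n_pairs, " pairwise contrasts; got ", length(de))
  rpkm <- exprValues(toRPKM(object))
  expressed <- rowSums(rpkm > 0) == ncol(rpkm)
  lr <- log2(rpkm[expressed, , drop = FALSE])
  mu <- rowMeans(lr)
  high <- mu >= min_log2rpkm
  lr <- lr[high, , drop = FALSE]
  mu <- mu[high]
  if (nrow(lr) == 0L) stop("no transcript passes the expression criteria")
  sds <- .rowSds(lr)
  cv <- sds / mu
  mad_ <- apply(lr, 1, stats::mad)
  cv_cut <- stats::quantile(cv, low_var_quantile, names = FALSE)
  mad_cut <- stats::quantile(mad_, low_var_quantile, names = FALSE)
  low_var <- cv <= cv_cut & mad_ <= mad_cut
  sig_any <- Reduce(`|`, lapply(de, function(d) {
    hit <- d$FDR <= alpha & abs(d$log2FC) >= lfc
    rownames(lr) %in% d$transcript_id[hit]
  }))
  sel <- low_var & !sig_any
  ids <- rownames(lr)[sel]
  out <- data.frame(transcript_id = ids,
                    mean_log2rpkm = mu[sel],
                    se = sds[sel] / sqrt(ncol(lr)),
                    CV = cv[sel],
                    MAD = mad_[sel],
                    row.names = NULL)
  out <- out[order(out$CV, out$MAD, out$transcript_id), ]
  attr(out, "criteria") <- list(min_log2rpkm = min_log2rpkm,
                                low_var_quantile = low_var_quantile,
                                cv_cut = cv_cut, mad_cut = mad_cut,
                                alpha = alpha, lfc = lfc,
                                population = nrow(lr))
  out
}

# TRUE where transcript is significantly higher in stage S than in `other`
.sigUpIn <- function(de, S, other, alpha, lfc) {
  ord <- match(c(S, other), stageLevels())
  a <- if (ord[1] < ord[2]) S else other
  b <- if (ord[1] < ord[2]) other else S
  d <- de[[paste0(a, "_vs_", b)]]
  if (is.null(d)) stop("missing contrast ", a, "_vs_", b)
  sign_needed <- if (b == S) 1 else -1
  hit <- d$FDR <= alpha & abs(d$log2FC) >= lfc & sign(d$log2FC) == sign_needed
  stats::setNames(hit, d$transcript_id)
}

#' Stage-marker candidate selection
#'
#' A transcript becomes a marker candidate of stage S when it
#' \enumerate{
#'   \item is differentially expressed, and higher in S, in all pairwise
#'     comparisons of S with the other stages (FDR <= \code{alpha},
#'     |log2FC| >= \code{lfc});
#'   \item shows a mean z-score of at least \code{z_min} over S's replicates
#'     (z-scores of log2(CPM + 1), matching the clustering measure);
#'   \item passes the gene-significance criteria for S
#'     (GS >= threshold and significant p.GS, from
#'     \code{\link{geneSignificance}}).
#' }
#' For a stage with too few strict candidates (the transitory ATT stage in
#' the original design), criterion 1 can be relaxed via \code{relax_stage}:
#' significance in at least \code{relax_min} of the 3 comparisons suffices
#' for that stage.
#'
#' @param object a \linkS4class{StageCounts}.
#' @param de list of all pairwise contrasts
#'   (\code{\link{allPairwiseContrasts}}).
#' @param gs gene-significance table from \code{\link{geneSignificance}}.
#' @param z_min minimum mean in-stage z-score (default 1).
#' @param relax_stage optional stage whose all-pairwise criterion is relaxed.
#' @param relax_min comparisons that must remain significant under
#'   relaxation (default 2 of 3).
#' @param alpha,lfc DE significance thresholds (defaults 0.05, 1.5).
#' @return data.frame: transcript_id, stage, mean_log2rpkm, se, max, min,
#'   zscore, GS, p.GS, relaxed; one row per candidate, each assigned to
#'   exactly one stage.
#' @export
selectMarkers <- function(object, de, gs, z_min = 1, relax_stage = NULL,
                          relax_min = 2L, alpha = 0.05, lfc = 1.5) {
  if (!is.null(relax_stage)) .checkStage(relax_stage)
  st <- as.character(stageOf(object))
  stages <- intersect(stageLevels(), unique(st))
  z <- exprValues(zscoreRows(log2p(toCPM(object))))
  lrpkm <- log2(exprValues(toRPKM(object)) + 1)
  out <- list()
  for (S in stages) {
    others <- setdiff(stages, S)
    ups <- lapply(others, function(o) .sigUpIn(de, S, o, alpha, lfc))
    ids <- Reduce(union, lapply(ups, names))
    n_up <- Reduce(`+`, lapply(ups, function(u) {
      v <- u[ids]; v[is.na(v)] <- FALSE; as.integer(v)
    }))
    need <- if (!is.null(relax_stage) && S == relax_stage) relax_min
            else length(others)
    cand <- ids[n_up >= need]
    cand <- intersect(cand, rownames(z))
    if (length(cand) == 0L) next
    zmean <- rowMeans(z[cand, st == S, drop = FALSE])
    cand <- cand[zmean >= z_min]
    gsS <- gs[gs$stage == S & gs$passes, ]
    cand <- intersect(cand, gsS$transcript_id)
    if (length(cand) == 0L) next
    gsrow <- gsS[match(cand, gsS$transcript_id), ]
    lr <- lrpkm[cand, , drop = FALSE]
    out[[S]] <- data.frame(
      transcript_id = cand, stage = S,
      mean_log2rpkm = rowMeans(lr),
      se = .rowSds(lr) / sqrt(ncol(lr)),
      max = apply(lr, 1, max), min = apply(lr, 1, min),
      zscore = rowMeans(z[cand, st == S, drop = FALSE]),
      GS = gsrow$GS, p.GS = gsrow$p.GS,
      relaxed = !is.null(relax_stage) && S == relax_stage,
      row.names = NULL)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(transcript_id = character(0), stage = character(0),
               mean_log2rpkm = numeric(0), se = numeric(0), max = numeric(0),
               min = numeric(0), zscore = numeric(0), GS = numeric(0),
               p.GS = numeric(0), relaxed = logical(0))
  dup <- res$transcript_id[duplicated(res$transcript_id)]
  if (length(dup) > 0L)
    stop("transcript(s) assigned to more than one stage (should be ",
         "impossible under the all-pairwise criterion): ",
         paste(unique(dup), collapse = ", "))
  res$stage <- factor(res$stage, levels = stageLevels())
  rownames(res) <- NULL
  res
}
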