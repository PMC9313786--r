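#' Binary stage-indicator pattern
#'
#' The idealized stage-specific expression pattern: 1 for the biological
#' samples of one stage, 0 for all others.
#'
#' @param sheet a sample sheet data.frame (sample_id, stage, ...) or a
#'   \linkS4class{StageCounts}/\linkS4class{StageExpression}.
#' @param stage target stage label.
#' @return Named 0/1 numeric vector over samples.
#' @export
stageIndicator <- function(sheet, stage) {
  if (is(sheet, "SummarizedExperiment")) sheet <- sampleSheet(sheet)
  .checkStage(stage)
  st <- as.character(sheet$stage)
  if (!stage %in% st) stop("stage absent from sample sheet: ", stage)
  ind <- as.numeric(st == stage)
  names(ind) <- sheet$sample_id
  ind
}

#' Gene significance: correlation with stage-indicator patterns
#'
#' For every transcript and every stage, the Pearson correlation GS between
#' the transcript's expression row and the binary stage indicator, with a
#' two-sided p-value from the exact t transform
#' \code{t = r * sqrt((n - 2) / (1 - r^2))} on n - 2 degrees of freedom
#' (n = number of samples). Low-abundance transcripts are discarded first by
#' a minimum mean RPKM across all samples. Expression is correlated on the
#' log2(RPKM + 1) scale. A transcript \code{passes} for a stage when
#' \code{GS >= gs_min} and \code{p.GS <= alpha} (both inclusive). Constant
#' expression rows have undefined GS and are flagged
#' (\code{constant = TRUE}, never passing) rather than returned as silent
#' NaN.
#'
#' @param object a \linkS4class{StageCounts}, or a
#'   \linkS4class{StageExpression} with measure \code{"RPKM"}.
#' @param min_mean_rpkm low-abundance cut-off (mean RPKM across samples).
#' @param gs_min minimum gene significance (default 0.7).
#' @param alpha p-value threshold (default 0.05).
#' @return Long data.frame: transcript_id, stage, GS, p.GS, passes, constant.
#' @export
geneSignificance <- function(object, min_mean_rpkm = 2, gs_min = 0.7,
                             alpha = 0.05) {
  rpkm <- if (is(object, "StageCounts")) toRPKM(object)
          else if (is(object, "StageExpression") && measure(object) == "RPKM")
            object
          else stop("geneSignificance needs StageCounts or an RPKM matrix")
  v <- exprValues(rpkm)
  n <- ncol(v)
  if (n < 3L) stop("gene significance needs >= 3 samples")
  keep <- rowMeans(v) >= min_mean_rpkm
  x <- log2(v[keep, , drop = FALSE] + 1)
  sheet <- sampleSheet(rpkm)
  stages <- intersect(stageLevels(), unique(as.character(sheet$stage)))
  sx <- .rowSds(x)
  const <- sx == 0
  xc <- x - rowMeans(x)
  out <- do.call(rbind, lapply(stages, function(s) {
    ind <- stageIndicator(sheet, s)[colnames(x)]
    ic <- ind - mean(ind)
    si <- stats::sd(ind)
    r <- as.numeric(xc %*% ic) / ((n - 1) * ifelse(const, 1, sx) * si)
    r[const] <- NA_real_
    r <- pmin(1, pmax(-1, r))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    data.frame(transcript_id = rownames(x), stage = s, GS = r, p.GS = p,
               passes = !const & !is.na(r) & r >= gs_min & p <= alpha,
               constant = const, row.names = NULL)
  }))
  out$stage <- factor(out$stage, levels = stageLevels())
  out
}

#' p-value of a gene-significance correlation
#'
#' The exact closed form behind \code{\link{geneSignificance}}: two-sided
#' p from \code{t = r * sqrt((n - 2) / (1 - r^2))} with n - 2 df.
#'
#' @param r Pearson correlation.
#' @param n number of samples.
#' @return Two-sided p-value.
#' @export
#' @examples
#' gsPValue(0.70, 12)  # 0.011 to 3 decimals
#' gsPValue(0.81, 12)  # 0.001 to 3 decimals
gsPValue <- function(r, n) {
  stopifnot(abs(r) <= 1, n > 2)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}
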