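#' Counts per million
#'
#' Scales each sample to library size one million:
#' \code{cpm = count / (library_size * factor) * 1e6}. Without scaling
#' factors each column sums to exactly 1e6. TMM factors from
#' \code{\link{tmmFactors}} can be supplied to obtain effective-library CPM as
#' used inside the differential-expression stage.
#'
#' @param object a \linkS4class{StageCounts}.
#' @param factors optional per-sample positive scaling factors (named or in
#'   column order); default none (all 1).
#' @return A \linkS4class{StageExpression} with measure \code{"CPM"}.
#' @export
toCPM <- function(object, factors = NULL) {
  cts <- counts(object)
  lib <- colSums(cts)
  if (any(lib == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(cts)[lib == 0], collapse = ", "))
  f <- rep(1, ncol(cts))
  if (!is.null(factors)) {
    if (!is.null(names(factors))) factors <- factors[colnames(cts)]
    stopifnot(length(factors) == ncol(cts), all(factors > 0))
    f <- as.numeric(factors)
  }
  vals <- sweep(cts, 2, lib * f, "/") * 1e6
  StageExpression(vals, "CPM", object)
}

#' Reads per kilobase per million mapped reads
#'
#' \code{rpkm = count / (length_kb * library_size_in_millions)}, using the raw
#' library size (column sum), i.e. the mapping-derived RPKM used for
#' expression-level reporting and housekeeper criteria.
#'
#' @param object a \linkS4class{StageCounts}.
#' @return A \linkS4class{StageExpression} with measure \code{"RPKM"}.
#' @export
toRPKM <- function(object) {
  cts <- counts(object)
  lib <- colSums(cts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(cts)[lib == 0], collapse = ", "))
  len_kb <- transcriptLengths(object) / 1000
  vals <- sweep(cts / len_kb, 2, lib / 1e6, "/")
  StageExpression(vals, "RPKM", object)
}

#' Offset log2 transform
#'
#' Elementwise \code{log2(value + offset)}. The measure tag gains a log2
#' prefix (CPM -> log2CPM, RPKM -> log2RPKM).
#'
#' @param object a \linkS4class{StageExpression} with measure CPM or RPKM.
#' @param offset non-negative pseudo-value, default 1.
#' @return A \linkS4class{StageExpression}.
#' @export
log2p <- function(object, offset = 1) {
  v <- exprValues(object)
  if (any(v + offset <= 0))
    stop("log2 of non-positive value; increase offset")
  meas <- switch(measure(object), CPM = "log2CPM", RPKM = "log2RPKM",
                 stop("log2p expects a CPM or RPKM matrix"))
  StageExpression(log2(v + offset), meas, object)
}

.rowSds <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (n - 1))
}

#' Per-transcript z-scores
#'
#' Centers and scales each row by its mean and sample (n-1) standard
#' deviation. A z-score is positive (negative) where a transcript's
#' accumulation in a sample is larger (smaller) than its mean accumulation.
#' Constant rows map to all-zero rows rather than NaN, so flat transcripts
#' remain clusterable.
#'
#' @param object a \linkS4class{StageExpression}.
#' @return A \linkS4class{StageExpression} with measure \code{"zscore"}.
#' @export
zscoreRows <- function(object) {
  v <- exprValues(object)
  if (ncol(v) < 2L) stop("z-scores need at least 2 samples")
  mu <- rowMeans(v)
  s <- .rowSds(v)
  z <- (v - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  StageExpression(z, "zscore", object)
}

#' TMM scaling factors
#'
#' Weighted trimmed mean of M-values between-sample normalization factors.
#' For each non-reference sample the log2 ratios M and mean log2 abundances A
#' of library-scaled proportions are computed over transcripts with nonzero
#' counts in both samples; the 30% M tails and 5% A tails are trimmed, and the
#' factor is 2 to the precision-weighted mean of the surviving M values
#' (weights are delta-method binomial variances). Factors are rescaled to have
#' geometric mean 1. The reference defaults to the sample whose 75th
#' percentile of scaled counts is closest to the mean of those percentiles.
#'
#' @param object a \linkS4class{StageCounts} (or bare count matrix).
#' @param ref_sample optional reference sample id.
#' @param trim_m,trim_a tail trim fractions for M and A (defaults 0.3, 0.05).
#' @return Named positive numeric vector of per-sample factors.
#' @export
tmmFactors <- function(object, ref_sample = NULL, trim_m = 0.3, trim_a = 0.05) {
  cts <- if (is(object, "SummarizedExperiment")) counts(object) else as.matrix(object)
  if (ncol(cts) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(cts)
  if (any(lib == 0)) stop("zero library size")
  if (is.null(ref_sample)) {
    q75 <- apply(sweep(cts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(q75 - mean(q75)))
  } else {
    ref <- match(ref_sample, colnames(cts))
    if (is.na(ref)) stop("unknown reference sample: ", ref_sample)
  }
  f <- vapply(seq_len(ncol(cts)), function(j) {
    .tmmPair(cts[, j], cts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(cts)
  f
}

# one pairwise TMM factor (obs vs ref); returns 1 when nothing survives
.tmmPair <- function(obs, ref, lib_obs, lib_ref, trim_m, trim_a) {
  keep0 <- obs > 0 & ref > 0
  if (!any(keep0)) {
    warning("no transcripts shared between sample and reference; factor 1")
    return(1)
  }
  obs <- obs[keep0]; ref <- ref[keep0]
  M <- log2((obs / lib_obs) / (ref / lib_ref))
  A <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) {
    warning("no transcripts survive TMM trimming; factor 1")
    return(1)
  }
  fval <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
  if (!is.finite(fval)) return(1)
  2^fval
}
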