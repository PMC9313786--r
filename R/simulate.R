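#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic staged expression
#' experiment. Defaults emulate the four-stage triplicate design (12 samples)
#' at desk scale: 2000 transcripts, 20 planted constant-expression
#' housekeepers, 5 planted markers per stage elevated by 3 log2 units in their
#' target stage, negative-binomial counts with dispersion 0.05
#' (variance = mu + phi * mu^2), and RT-qPCR tables derived from expression
#' with perfect doubling efficiency and 0.2-cycle noise.
#'
#' Two fields shape the non-planted background: \code{baseline_log2_sd}
#' spreads per-transcript baseline abundance, and \code{stage_effect_sd} gives
#' every background ("noise") transcript independent per-stage log2 effects,
#' emulating genuine biological stage-to-stage variation. Housekeepers carry
#' no stage effect and a fixed baseline; markers carry the planted effect only
#' in their target stage.
#'
#' @param n_transcripts total transcripts simulated.
#' @param n_housekeepers planted constant-expression housekeepers.
#' @param n_markers_per_stage named integer vector (niS, SWE, ATT, PEN).
#' @param baseline_log2_mean log2 expected count at average length/library.
#' @param baseline_log2_sd spread of background baselines (log2).
#' @param marker_effect_log2fc planted marker elevation (log2, >= 0).
#' @param stage_effect_sd per-stage biological effect sd for background
#'   transcripts (log2).
#' @param nb_dispersion NB dispersion phi >= 0 (0 = Poisson).
#' @param library_size_range,length_range_bp uniform sampling ranges.
#' @param replicates_per_stage biological replicates per stage.
#' @param seed integer seed governing all randomness of a run.
#' @param cq_intercept Cq of a (linear) expression of 1, i.e. log2 of 0.
#' @param cq_noise_sd technical Cq noise sd (cycles).
#' @param efficiency amplification efficiency in (1, 2]; 2 = perfect doubling.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_transcripts = 2000L,
                             n_housekeepers = 20L,
                             n_markers_per_stage = c(niS = 5L, SWE = 5L,
                                                     ATT = 5L, PEN = 5L),
                             baseline_log2_mean = 5,
                             baseline_log2_sd = 1.5,
                             marker_effect_log2fc = 3,
                             stage_effect_sd = 1.2,
                             nb_dispersion = 0.05,
                             library_size_range = c(8e5, 1.2e6),
                             length_range_bp = c(300L, 3000L),
                             replicates_per_stage = 3L,
                             seed = 1L,
                             cq_intercept = 30,
                             cq_noise_sd = 0.2,
                             efficiency = 2) {
  n_markers_per_stage <- unlist(n_markers_per_stage)
  if (is.null(names(n_markers_per_stage)))
    names(n_markers_per_stage) <- stageLevels()
  stopifnot(all(names(n_markers_per_stage) %in% stageLevels()))
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              n_housekeepers = as.integer(n_housekeepers),
              n_markers_per_stage = n_markers_per_stage,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              marker_effect_log2fc = marker_effect_log2fc,
              stage_effect_sd = stage_effect_sd,
              nb_dispersion = nb_dispersion,
              library_size_range = library_size_range,
              length_range_bp = length_range_bp,
              replicates_per_stage = as.integer(replicates_per_stage),
              seed = as.integer(seed),
              cq_intercept = cq_intercept,
              cq_noise_sd = cq_noise_sd,
              efficiency = efficiency)
  if (cfg$marker_effect_log2fc < 0) stop("marker effect must be >= 0")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$efficiency <= 1 || cfg$efficiency > 2)
    stop("efficiency must lie in (1, 2]")
  if (cfg$cq_noise_sd < 0 || cfg$stage_effect_sd < 0 || cfg$baseline_log2_sd < 0)
    stop("standard deviations must be >= 0")
  if (cfg$replicates_per_stage < 2L)
    stop("need >= 2 replicates per stage")
  if (cfg$n_housekeepers + sum(cfg$n_markers_per_stage) > cfg$n_transcripts)
    stop("infeasible config: planted housekeepers + markers exceed n_transcripts")
  class(cfg) <- "SimulationConfig"
  cfg
}

.rnb <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate a staged count matrix with planted ground truth
#'
#' Draws negative-binomial counts \code{NB(mean = mu, variance =
#' mu + phi mu^2)} for a 4-stage x r-replicate design. Expected counts are
#' \code{mu = 2^baseline * 2^effect * (length / mean length) * (library /
#' mean library)}: planted housekeepers have identical expected expression
#' rate in every sample (so they are constant on the RPKM scale, where the
#' housekeeper criteria operate), planted markers are elevated by
#' \code{marker_effect_log2fc} in their target stage only, and background
#' transcripts receive independent per-stage effects of sd
#' \code{stage_effect_sd}. A single seed governs the whole draw; the same
#' config yields identical output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return List with elements \code{counts} (a \linkS4class{StageCounts}) and
#'   \code{truth} (data.frame: transcript_id, role; role is
#'   \code{"housekeeper"}, \code{"marker:<stage>"} or \code{"noise"}).
#' @export
simulateCounts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nt <- config$n_transcripts
  r <- config$replicates_per_stage
  stages <- factor(rep(stageLevels(), each = r), levels = stageLevels())
  ns <- length(stages)
  sample_id <- paste0(stages, "_", rep(seq_len(r), times = 4))
  ids <- sprintf("Tx%05d", seq_len(nt))

  nm <- config$n_markers_per_stage
  roles <- rep("noise", nt)
  idx <- 1L
  if (config$n_housekeepers > 0L) {
    roles[idx:(idx + config$n_housekeepers - 1L)] <- "housekeeper"
    idx <- idx + config$n_housekeepers
  }
  for (st in stageLevels()) {
    k <- if (st %in% names(nm)) as.integer(nm[[st]]) else 0L
    if (k > 0L) {
      roles[idx:(idx + k - 1L)] <- paste0("marker:", st)
      idx <- idx + k
    }
  }

  len <- as.integer(round(stats::runif(nt, config$length_range_bp[1],
                                       config$length_range_bp[2])))
  lib <- stats::runif(ns, config$library_size_range[1],
                      config$library_size_range[2])

  base <- rep(config$baseline_log2_mean, nt)
  noise_i <- roles == "noise"
  base[noise_i] <- stats::rnorm(sum(noise_i), config$baseline_log2_mean,
                                config$baseline_log2_sd)
  # reference genes are well-expressed: plant them 3 log2 above baseline so
  # counting noise is negligible relative to the NB dispersion floor
  base[roles == "housekeeper"] <- config$baseline_log2_mean + 3
  # per-transcript x per-stage log2 effects
  eff <- matrix(0, nt, 4, dimnames = list(ids, stageLevels()))
  eff[noise_i, ] <- stats::rnorm(sum(noise_i) * 4, 0, config$stage_effect_sd)
  for (st in stageLevels()) {
    eff[roles == paste0("marker:", st), st] <- config$marker_effect_log2fc
  }

  len_scale <- len / mean(len)
  lib_scale <- lib / mean(lib)
  mu <- 2^(base + eff[, as.character(stages), drop = FALSE]) *
    len_scale %o% lib_scale
  cts <- matrix(.rnb(length(mu), mu, config$nb_dispersion), nt, ns,
                dimnames = list(ids, sample_id))
  sheet <- data.frame(sample_id = sample_id, stage = as.character(stages),
                      replicate = rep(seq_len(r), times = 4),
                      system = "host-free")
  list(counts = StageCounts(cts, len, sheet),
       truth = data.frame(transcript_id = ids, role = roles))
}

#' Simulate an RT-qPCR Cq table from log2 expression
#'
#' Inverts the relative-quantification model: a template amount of
#' \code{2^x} yields \code{Cq = cq_intercept - x * log(2)/log(efficiency) +
#' N(0, cq_noise_sd)}, with two independent technical replicates per gene x
#' sample cell. With efficiency 2 a doubling of expression (log2 + 1) lowers
#' Cq by exactly one cycle. Cq values are clipped into (0, 45], the validity
#' range of a \linkS4class{CqTable}.
#'
#' @param expr a \linkS4class{StageExpression} on a log2 scale
#'   (\code{log2CPM} or \code{log2RPKM}), strictly finite.
#' @param config a \code{\link{simulationConfig}} supplying
#'   \code{cq_intercept}, \code{cq_noise_sd}, \code{efficiency} and the seed.
#' @param n_technical technical replicates per cell (default 2).
#' @return A \linkS4class{CqTable}.
#' @export
simulateCq <- function(expr, config, n_technical = 2L) {
  stopifnot(inherits(config, "SimulationConfig"))
  x <- exprValues(expr)
  if (!all(is.finite(x))) stop("expression must be strictly finite")
  if (!measure(expr) %in% c("log2CPM", "log2RPKM"))
    stop("simulateCq expects a log2-scale expression matrix")
  set.seed(config$seed + 1L)
  noiseless <- config$cq_intercept - x * log(2) / log(config$efficiency)
  rows <- expand.grid(gene_id = rownames(x), sample_id = colnames(x),
                      rep = seq_len(n_technical), stringsAsFactors = FALSE)
  cq <- noiseless[cbind(rows$gene_id, rows$sample_id)] +
    stats::rnorm(nrow(rows), 0, config$cq_noise_sd)
  cq <- pmin(pmax(cq, 1e-3), 45)
  CqTable(data.frame(gene_id = rows$gene_id, sample_id = rows$sample_id,
                     cq = cq))
}
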