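# shared fixtures and independent oracles

# a small valid 4-stage x 2-replicate design
toySheet <- function(n_rep = 2) {
  data.frame(sample_id = paste0(rep(stageLevels(), each = n_rep), "_",
                                rep(seq_len(n_rep), 4)),
             stage = rep(stageLevels(), each = n_rep),
             replicate = rep(seq_len(n_rep), 4),
             system = "host-free")
}

toyCounts <- function(counts, lengths = NULL, n_rep = 2) {
  counts <- as.matrix(counts)
  sheet <- toySheet(n_rep)
  stopifnot(ncol(counts) == nrow(sheet))
  colnames(counts) <- sheet$sample_id
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("t%02d", seq_len(nrow(counts)))
  if (is.null(lengths)) lengths <- rep(1000L, nrow(counts))
  StageCounts(counts, lengths, sheet)
}

# exact conditional binomial split test by full enumeration (phi = 0 oracle)
binomSplitP <- function(a, b, pA = 0.5) {
  s <- a + b
  if (s == 0) return(1)
  pr <- dbinom(0:s, s, pA)
  sum(pr[pr <= pr[a + 1] * (1 + 1e-12)])
}

# hypergeometric upper tail by combinatorial enumeration
hyperEnumP <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# one shared default-scale recovery run, computed once per test session
.recoveryCache <- new.env(parent = emptyenv())
recoveryRun <- function(seed = 3L) {
  key <- paste0("s", seed)
  if (!is.null(.recoveryCache[[key]])) return(.recoveryCache[[key]])
  cfg <- simulationConfig(seed = seed)
  sim <- simulateCounts(cfg)
  fc <- filterExpressed(sim$counts)
  de <- allPairwiseContrasts(fc)
  gs <- geneSignificance(fc)
  hk <- selectHousekeepers(fc, de)
  mk <- selectMarkers(fc, de, gs, relax_stage = "ATT")
  run <- list(cfg = cfg, truth = sim$truth, fc = fc, de = de, gs = gs,
              hk = hk, mk = mk)
  .recoveryCache[[key]] <- run
  run
}
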