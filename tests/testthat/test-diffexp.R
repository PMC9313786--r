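test_that("the expression filter applies both criteria inclusively", {
  # 12 samples, library sizes fixed at 1e6 by a filler transcript
  n <- 12
  m <- rbind(
    zero    = rep(0L, n),
    border  = c(1L, 1L, 1L, rep(0L, 9)),      # 3 samples, sum CPM exactly 3
    few     = c(5L, rep(0L, 11)),             # 1 sample only
    plenty  = rep(10L, n))
  filler <- 1e6L - colSums(m)
  m <- rbind(m, filler = filler)
  sc <- toyCounts(m, n_rep = 3)
  kept <- rownames(filterExpressed(sc, min_samples = 3, min_total_cpm = 3))
  expect_true(all(c("border", "plenty", "filler") %in% kept))
  expect_false(any(c("zero", "few") %in% kept))
  sparse <- matrix(0L, 6, 12)
  for (i in 1:6) sparse[i, c(2 * i - 1, 2 * i)] <- 5L  # 2 samples each
  expect_error(filterExpressed(toyCounts(sparse, n_rep = 3)), "review")
})

test_that("a hand-computed CPM-sum example filters as evaluated manually", {
  m <- matrix(0L, 5, 12, dimnames = list(paste0("t", 1:5), NULL))
  m[1, ] <- 2L                    # 12 samples, high CPM
  m[2, 1:3] <- 1L                 # borderline samples, CPM depends on libs
  m[3, 1:2] <- 50L                # only 2 samples with counts
  m[4, ] <- 1L
  m[5, ] <- 100L
  sc <- toyCounts(m, n_rep = 3)
  lib <- colSums(counts(sc))
  cpm_sum <- rowSums(sweep(counts(sc), 2, lib, "/") * 1e6)
  manual <- rowSums(counts(sc) >= 1) >= 3 & cpm_sum >= 3
  expect_identical(rownames(filterExpressed(sc)),
                   rownames(m)[manual])
})

test_that("the exact NB test reduces to the binomial split test at phi 0", {
  expect_equal(nbExactTest(5, 5, 1e6, 1e6, phi = 0), 1)
  expect_equal(nbExactTest(0, 10, 1e6, 1e6, phi = 0), 2 * 0.5^10)
  expect_equal(nbExactTest(2, 8, 1e6, 1e6, phi = 0), 112 / 1024)
  for (s in c(1, 5, 12, 30)) {
    for (a in 0:s) {
      expect_equal(nbExactTest(a, s - a, 1e6, 1e6, phi = 0),
                   binomSplitP(a, s - a), tolerance = 1e-12)
    }
  }
})

test_that("widening the count gap at fixed total never raises the p-value", {
  for (s in c(6, 11, 20)) {
    p <- vapply(floor(s / 2):0, function(a)
      nbExactTest(a, s - a, 1e6, 1e6, phi = 0.1), numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.9, 0.001, 0.04, 0.2)
  expect_equal(max(bhAdjust(p)), max(p))
  ord <- sample(length(p))
  expect_equal(bhAdjust(p[ord]), bhAdjust(p)[ord])
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("common dispersion is recovered from simulated data", {
  cfg <- simulationConfig(n_transcripts = 500, n_housekeepers = 0,
                          n_markers_per_stage = c(niS = 0L, SWE = 0L,
                                                  ATT = 0L, PEN = 0L),
                          stage_effect_sd = 0, baseline_log2_sd = 1,
                          nb_dispersion = 0, seed = 21)
  expect_warning(
    poisson_fit <- estimateCommonDispersion(simulateCounts(cfg)$counts),
    "boundary")  # true phi = 0 sits at the search floor
  expect_lt(poisson_fit$phi, 0.05)

  cfg2 <- simulationConfig(n_transcripts = 500, n_housekeepers = 0,
                           n_markers_per_stage = c(niS = 0L, SWE = 0L,
                                                   ATT = 0L, PEN = 0L),
                           stage_effect_sd = 0, baseline_log2_sd = 1,
                           nb_dispersion = 0.2, seed = 22)
  nb_fit <- estimateCommonDispersion(simulateCounts(cfg2)$counts)
  expect_gt(nb_fit$phi, 0.1)
  expect_lt(nb_fit$phi, 0.3)

  sheet <- data.frame(sample_id = c("niS_1", "niS_2"),
                      stage = "niS", replicate = 1:2)
  one_rep <- StageCounts(matrix(1:2, 1, 2, dimnames = list("t1", sheet$sample_id)),
                         500L, sheet)
  expect_error(estimateCommonDispersion(one_rep[, 1]), "replicates")
})

test_that("dispersion agrees with the reference qCML implementation", {
  skip_if_not_installed("edgeR")
  cfg <- simulationConfig(n_transcripts = 400, n_housekeepers = 0,
                          n_markers_per_stage = c(niS = 0L, SWE = 0L,
                                                  ATT = 0L, PEN = 0L),
                          stage_effect_sd = 0, baseline_log2_sd = 1,
                          library_size_range = c(1e6, 1e6),
                          nb_dispersion = 0.1, seed = 31)
  sc <- simulateCounts(cfg)$counts
  ours <- estimateCommonDispersion(sc)$phi
  d <- edgeR::DGEList(counts = counts(sc),
                      group = as.character(stageOf(sc)))
  theirs <- edgeR::estimateCommonDisp(d)$common.dispersion
  expect_equal(ours, theirs, tolerance = 0.15)
})

test_that("contrasts are antisymmetric and respect inclusive thresholds", {
  run <- recoveryRun()
  sub <- run$fc[1:200, ]
  ab <- runContrast(sub, "niS", "SWE", phi = 0.05)
  ba <- runContrast(sub, "SWE", "niS", phi = 0.05)
  expect_equal(ab$log2FC, -ba$log2FC, tolerance = 1e-9)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-9)
  sig <- ab$direction != "ns"
  expect_true(all(ab$FDR[sig] <= 0.05 & abs(ab$log2FC[sig]) >= 1.5))
  expect_true(all(ab$FDR[!sig] > 0.05 | abs(ab$log2FC[!sig]) < 1.5))
  expect_error(runContrast(sub, "niS", "MAT"), "unknown stage")
})

test_that("null simulations keep the FDR-call fraction near nominal", {
  frac <- vapply(1:3, function(seed) {
    cfg <- simulationConfig(n_transcripts = 300, n_housekeepers = 0,
                            n_markers_per_stage = c(niS = 0L, SWE = 0L,
                                                    ATT = 0L, PEN = 0L),
                            stage_effect_sd = 0, baseline_log2_sd = 1,
                            nb_dispersion = 0.05, seed = 40 + seed)
    sc <- simulateCounts(cfg)$counts
    d <- runContrast(sc, "niS", "SWE")
    mean(d$FDR <= 0.05)
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / 300)
  expect_lt(mean(frac), 0.05 + 3 * se)
})

test_that("planted eightfold markers are flagged up with high power", {
  run <- recoveryRun()
  d <- run$de[["niS_vs_SWE"]]
  swe <- run$truth$transcript_id[run$truth$role == "marker:SWE"]
  expect_gte(mean(d$direction[d$transcript_id %in% swe] == "up"), 0.9)
})

test_that("Venn regions match set algebra on identical, disjoint and hand cases", {
  mk <- function(ids, sig) {
    d <- data.frame(transcript_id = ids, log2FC = ifelse(ids %in% sig, 2, 0),
                    p_value = 0.5, FDR = ifelse(ids %in% sig, 0.01, 0.9),
                    direction = ifelse(ids %in% sig, "up", "ns"))
    d
  }
  uni <- paste0("t", 1:10)
  same <- list(A = mk(uni, uni[1:4]), B = mk(uni, uni[1:4]),
               C = mk(uni, uni[1:4]))
  r <- stageOverlapSets(same)
  expect_setequal(r$regions[["A&B&C"]], uni[1:4])
  expect_true(all(lengths(r$regions[names(r$regions) != "A&B&C"]) == 0))

  disj <- list(A = mk(uni, uni[1:2]), B = mk(uni, uni[3:4]),
               C = mk(uni, uni[5:6]))
  r2 <- stageOverlapSets(disj)
  expect_setequal(r2$regions[["A_only"]], uni[1:2])
  expect_setequal(r2$regions[["C_only"]], uni[5:6])

  hand <- list(A = mk(uni, uni[c(1, 2, 3, 7)]), B = mk(uni, uni[c(2, 3, 8)]),
               C = mk(uni, uni[c(3, 7, 9)]))
  r3 <- stageOverlapSets(hand)
  expect_setequal(r3$regions[["A&B&C"]], "t3")
  expect_setequal(r3$regions[["A&B"]], "t2")
  expect_setequal(r3$regions[["A&C"]], "t7")
  expect_setequal(r3$regions[["B&C"]], character(0))
  expect_setequal(r3$regions[["A_only"]], "t1")
  expect_equal(r3$counts$total, c(4, 3, 3))

  bad <- list(A = mk(uni, uni[1]), B = mk(uni[1:9], uni[2]),
              C = mk(uni, uni[3]))
  expect_error(stageOverlapSets(bad), "universe")
})
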