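test_that("CPM matches its closed form and sums to one million", {
  m <- matrix(c(5L, 5L, 2L, 8L), 2, 2,
              dimnames = list(c("a", "b"), c("niS_1", "niS_2")))
  sheet <- data.frame(sample_id = c("niS_1", "niS_2"), stage = "niS",
                      replicate = 1:2)
  sc <- StageCounts(m, c(1000L, 1000L), sheet)
  cpm <- exprValues(toCPM(sc))
  expect_equal(unname(cpm[, 1]), c(500000, 500000))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  halved <- exprValues(toCPM(sc, factors = c(niS_1 = 2, niS_2 = 1)))
  expect_equal(halved[, 1], cpm[, 1] / 2)
  expect_equal(halved[, 2], cpm[, 2])
})

test_that("RPKM matches its closed form, halves with doubled length, zero stays zero", {
  m <- matrix(c(10L, 0L, 10L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("niS_1", "niS_2")))
  m[2, ] <- c(999990L, 999990L)  # fill libraries to 1e6
  sheet <- data.frame(sample_id = c("niS_1", "niS_2"), stage = "niS",
                      replicate = 1:2)
  sc <- StageCounts(m, c(1000L, 1000L), sheet)
  expect_equal(unname(exprValues(toRPKM(sc))["a", ]), c(10, 10))
  sc2 <- StageCounts(m, c(2000L, 1000L), sheet)
  expect_equal(unname(exprValues(toRPKM(sc2))["a", ]), c(5, 5))
  m0 <- m; m0[1, ] <- 0L
  expect_equal(unname(exprValues(toRPKM(StageCounts(m0, c(1000L, 1000L),
                                                    sheet)))["a", ]), c(0, 0))
})

test_that("log2 transform applies the offset and preserves ordering", {
  e <- StageExpression(matrix(c(3, 0, 7, 1), 2, 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))),
                       "CPM")
  lv <- exprValues(log2p(e, offset = 1))
  expect_equal(lv["a", 1], 2)
  expect_equal(lv["b", 1], 0)
  expect_true(all(order(exprValues(e)) == order(lv)))
  expect_identical(measure(log2p(e)), "log2CPM")
  expect_error(log2p(StageExpression(matrix(-2, 1, 2), "CPM"), offset = 1),
               "non-positive")
})

test_that("row z-scores use the n-1 sd, zero constant rows, and are idempotent", {
  e <- StageExpression(matrix(c(1, 2, 3, 7, 7, 7), 2, 3, byrow = TRUE,
                              dimnames = list(c("a", "b"), paste0("s", 1:3))),
                       "CPM")
  z <- exprValues(zscoreRows(e))
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_true(all(abs(rowSums(z)) < 1e-9))
  z2 <- exprValues(zscoreRows(StageExpression(z, "zscore")))
  expect_equal(z2, z, tolerance = 1e-12)
})

test_that("TMM factors are 1 for identical and globally scaled libraries", {
  m <- matrix(rpois(40, 60) + 1L, 20, 2,
              dimnames = list(sprintf("t%02d", 1:20), c("niS_1", "niS_2")))
  m[, 2] <- m[, 1]
  sheet <- data.frame(sample_id = colnames(m), stage = "niS", replicate = 1:2)
  f <- tmmFactors(StageCounts(m, rep(1000L, 20), sheet))
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  m[, 2] <- m[, 1] * 2L
  f2 <- tmmFactors(StageCounts(m, rep(1000L, 20), sheet))
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches an independent evaluation of the published formula", {
  set.seed(42)
  m <- matrix(rpois(40, 200) + 1L, 20, 2)
  m[1:2, 2] <- m[1:2, 2] * 25L  # two transcripts dominate sample B
  dimnames(m) <- list(sprintf("t%02d", 1:20), c("A", "B"))
  libs <- colSums(m)
  # direct formula evaluation, no shortcuts: M/A over shared transcripts,
  # 30%/5% rank trims, inverse-variance weights, factors with geomean 1
  obs <- m[, 2]; ref <- m[, 1]
  M <- log2((obs / libs[2]) / (ref / libs[1]))
  A <- 0.5 * log2((obs / libs[2]) * (ref / libs[1]))
  w <- (libs[2] - obs) / (libs[2] * obs) + (libs[1] - ref) / (libs[1] * ref)
  n <- length(M)
  keep <- rank(M) >= floor(0.3 * n) + 1 & rank(M) <= n - floor(0.3 * n) &
    rank(A) >= floor(0.05 * n) + 1 & rank(A) <= n - floor(0.05 * n)
  fB <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  expected <- c(1 / sqrt(fB), fB / sqrt(fB))
  got <- tmmFactors(m, ref_sample = "A")
  expect_equal(unname(got), unname(expected), tolerance = 1e-6)
  expect_equal(exp(mean(log(got))), 1, tolerance = 1e-9)
})

test_that("TMM agrees with the reference Bioconductor implementation", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  m <- matrix(rnbinom(300, mu = 150, size = 10) + 1L, 50, 6)
  m[1:5, 4] <- m[1:5, 4] * 12L
  dimnames(m) <- list(sprintf("t%02d", 1:50), paste0("s", 1:6))
  ours <- tmmFactors(m, ref_sample = "s1")
  theirs <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})
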