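test_that("geNorm gives the constant-ratio pair M = 0 and shared rank 1", {
  q <- rbind(a = c(1, 2, 4, 8),
             b = 3 * c(1, 2, 4, 8),          # constant ratio to a
             c = c(5, 1, 7, 2),
             d = c(2, 9, 1, 6))
  g <- geNorm(q)
  expect_equal(unname(g$M[c("a", "b")]), c(0, 0))
  expect_equal(unname(g$rank[c("a", "b")]), c(1L, 1L))
  expect_setequal(g$stability_order[1:2], c("a", "b"))
  expect_equal(sort(unname(g$rank)), c(1L, 1L, 3L, 4L))
  expect_error(geNorm(q * -1), "positive")
})

test_that("geNorm M matches a hand-evaluated pairwise-sd computation", {
  q <- rbind(g1 = c(1.0, 1.2, 0.9, 1.1),
             g2 = c(0.8, 1.1, 1.0, 0.7),
             g3 = c(2.0, 0.5, 1.5, 1.0))
  lq <- log2(q)
  manual <- vapply(1:3, function(j) {
    mean(vapply(setdiff(1:3, j), function(k) sd(lq[j, ] - lq[k, ]),
                numeric(1)))
  }, numeric(1))
  g <- geNorm(q)
  # with 3 candidates, one exclusion happens; the worst keeps its full-set M
  worst <- which.max(manual)
  expect_equal(unname(g$M[worst]), manual[worst])
  # the surviving pair share the sd of their mutual log ratio
  pair <- setdiff(1:3, worst)
  expect_equal(unname(g$M[pair]),
               rep(sd(lq[pair[1], ] - lq[pair[2], ]), 2))
})

test_that("an erratic candidate inflates every other candidate's initial M", {
  set.seed(1)
  q <- matrix(2^rnorm(24, 0, 0.1), 4, 6,
              dimnames = list(paste0("g", 1:4), NULL))
  base <- geNorm(q)
  noisy <- rbind(q, bad = 2^rnorm(6, 0, 3))
  # recompute full-set M directly for comparability
  fullM <- function(qq) {
    lq <- log2(qq)
    vapply(seq_len(nrow(qq)), function(j)
      mean(vapply(setdiff(seq_len(nrow(qq)), j), function(k)
        sd(lq[j, ] - lq[k, ]), numeric(1))), numeric(1))
  }
  expect_true(all(fullM(noisy)[1:4] > fullM(q)))
})

test_that("geNorm pairwise variations are the sds of normalization-factor ratios", {
  set.seed(3)
  q <- matrix(2^rnorm(30, 0, 0.3), 5, 6,
              dimnames = list(paste0("g", 1:5), NULL))
  g <- geNorm(q)
  expect_named(g$V, c("V2/3", "V3/4", "V4/5"))
  ord <- g$stability_order
  lq <- log2(q)
  v23 <- sd(colMeans(lq[ord[1:2], ]) - colMeans(lq[ord[1:3], ]))
  expect_equal(unname(g$V["V2/3"]), v23)
})

test_that("NormFinder prefers constant candidates and ignores global shifts", {
  groups <- rep(c("A", "B", "C"), each = 3)
  set.seed(4)
  x <- matrix(rnorm(45, 10, 0.3), 5, 9,
              dimnames = list(paste0("g", 1:5), NULL))
  x["g1", ] <- 10                      # perfectly constant
  sv <- normFinder(x, groups)
  expect_equal(names(which.min(sv)), "g1")
  # location invariance: adding a constant to one candidate changes nothing
  x2 <- x; x2["g3", ] <- x2["g3", ] + 5
  sv2 <- normFinder(x2, groups)
  expect_equal(sv, sv2, tolerance = 1e-12)
})

test_that("a group-shifted candidate is ranked least stable by NormFinder", {
  groups <- rep(c("A", "B", "C"), each = 4)
  set.seed(5)
  x <- matrix(rnorm(72, 10, 0.2), 6, 12,
              dimnames = list(paste0("g", 1:6), NULL))
  x["g4", groups == "B"] <- x["g4", groups == "B"] + 2  # group-level bias
  sv <- normFinder(x, groups)
  expect_equal(names(which.max(sv)), "g4")
})

test_that("NormFinder matches an independent coding of the model equations", {
  groups <- rep(c("A", "B"), each = 4)
  set.seed(6)
  x <- matrix(rnorm(40, 8, 0.4), 5, 8,
              dimnames = list(paste0("g", 1:5), NULL))
  k <- nrow(x)
  oracle <- {
    gl <- unique(groups)
    sig2 <- dbar <- matrix(0, k, length(gl))
    ng <- integer(length(gl))
    for (gi in seq_along(gl)) {
      z <- x[, groups == gl[gi], drop = FALSE]
      ng[gi] <- ncol(z)
      d <- z - matrix(colMeans(z), k, ncol(z), byrow = TRUE)
      v <- apply(d, 1, var)
      tot <- sum(v) / (1 - 1 / k)
      sig2[, gi] <- pmax((v - tot / k^2) / (1 - 2 / k), 0)
      dbar[, gi] <- rowMeans(d)
    }
    b <- dbar - rowMeans(dbar)
    rowMeans(abs(b) + sqrt(sig2 / matrix(ng, k, length(gl), byrow = TRUE)))
  }
  expect_equal(unname(normFinder(x, groups)), unname(oracle),
               tolerance = 1e-12)
})

test_that("BestKeeper correlates candidates against the per-sample index", {
  copies <- rbind(g1 = c(20, 21, 22, 23, 24, 25),
                  g2 = c(20, 21, 22, 23, 24, 25))
  expect_equal(bestKeeper(copies)$r, c(1, 1))  # index collinearity
  cqm <- rbind(copies, g3 = c(25, 24, 23, 25, 24, 23))
  bk <- bestKeeper(cqm)
  idx <- colMeans(cqm)
  expect_equal(bk$r[bk$candidate == "g3"], cor(cqm["g3", ], idx))
  expect_equal(bk$r[bk$candidate == "g1"], cor(cqm["g1", ], idx))
  const <- rbind(cqm, g4 = rep(20, 6))
  bk2 <- bestKeeper(const)
  expect_true(is.na(bk2$r[bk2$candidate == "g4"]))
  expect_true(bk2$constant[bk2$candidate == "g4"])
})

test_that("rank integration reproduces the published two-panel GM columns", {
  # per-method scores as printed for the five reference candidates,
  # host-free system
  hf_M <- c(Cc006757.t1 = 0.48, Cc028808.t1 = 0.48, Cc036327.t1 = 0.58,
            Cc028378.t1 = 0.78, Cc002986.t1 = 0.87)
  hf_SV <- c(Cc028808.t1 = 0.32, Cc028378.t1 = 0.43, Cc036327.t1 = 0.49,
             Cc006757.t1 = 0.51, Cc002986.t1 = 0.52)
  hf_r <- c(Cc006757.t1 = 0.95, Cc028808.t1 = 0.95, Cc036327.t1 = 0.91,
            Cc028378.t1 = 0.74, Cc002986.t1 = 0.27)
  hf <- stabilityTable(integrateRanks(hf_M, hf_SV[names(hf_M)],
                                      hf_r[names(hf_M)]))
  expect_equal(hf$GM[match(c("Cc028808.t1", "Cc006757.t1", "Cc036327.t1",
                             "Cc028378.t1", "Cc002986.t1"), hf$candidate)],
               c(1.00, 1.59, 3.00, 3.17, 5.00))

  hi_M <- c(Cc002986.t1 = 0.29, Cc028378.t1 = 0.29, Cc006757.t1 = 0.36,
            Cc028808.t1 = 0.39, Cc036327.t1 = 0.51)
  hi_SV <- c(Cc028378.t1 = 0.19, Cc006757.t1 = 0.27, Cc002986.t1 = 0.27,
             Cc028808.t1 = 0.29, Cc036327.t1 = 0.42)
  hi_r <- c(Cc028378.t1 = 0.95, Cc006757.t1 = 0.94, Cc028808.t1 = 0.88,
            Cc002986.t1 = 0.88, Cc036327.t1 = 0.52)
  hi <- stabilityTable(integrateRanks(hi_M, hi_SV[names(hi_M)],
                                      hi_r[names(hi_M)]))
  expect_equal(hi$GM[match(c("Cc028378.t1", "Cc002986.t1", "Cc006757.t1",
                             "Cc028808.t1", "Cc036327.t1"), hi$candidate)],
               c(1.00, 1.82, 2.29, 3.63, 5.00))
  # competition ranking: ties share the smaller rank, next rank skipped
  expect_equal(sort(hi$rank_bestkeeper), c(1L, 2L, 3L, 3L, 5L))
})

test_that("rank integration is exact on closed-form rank triples", {
  sr <- integrateRanks(M = c(a = 1, b = 2, c = 3),
                       SV = c(a = 1, b = 2, c = 3),
                       r = c(a = 3, b = 2, c = 1))
  tab <- stabilityTable(sr)
  expect_equal(tab$GM, c(1, 2, 3))  # strict consensus keeps the ranks
  gm <- function(x) round(prod(x)^(1 / 3), 2)
  expect_equal(gm(c(3, 3, 3)), 3.00)
  expect_equal(gm(c(1, 4, 1)), 1.59)
  expect_equal(gm(c(4, 2, 4)), 3.17)
})

test_that("stability scoring is invariant to candidate order", {
  set.seed(8)
  cqm <- matrix(runif(30, 18, 26), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  groups <- rep(c("A", "B"), each = 3)
  full <- rankStability(cqm, groups = groups)
  perm <- sample(5)
  shuffled <- rankStability(cqm[perm, ], groups = groups)
  a <- stabilityTable(full); b <- stabilityTable(shuffled)
  expect_equal(a[order(a$candidate), ], b[order(b$candidate), ],
               ignore_attr = TRUE)
  # the geNorm final pair tie propagates into the integrated table
  expect_equal(sort(a$rank_genorm)[1:2], c(1L, 1L))
})
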