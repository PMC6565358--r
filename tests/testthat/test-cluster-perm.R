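test_that("comparison grids reproduce the printed point counts", {
  lay <- electrodeLayout62()
  whole <- buildComparisonGrid(lay$name, c(0, 600))
  expect_equal(whole$nComparisons, 18600L)

  roi <- c("CP1", "CPz", "CP2", "P1", "Pz", "P2", "F1", "Fz", "F2")
  expect_true(all(roi %in% lay$name))
  expect_equal(buildComparisonGrid(roi, c(300, 600))$nComparisons, 1350L)

  expect_equal(buildComparisonGrid("Cz", c(100, 102))$nComparisons, 1L)
  ## an inclusive endpoint over 300-500 ms gives 101 samples per channel
  expect_equal(buildComparisonGrid(lay$name, c(300, 500),
                                   endpoint = "inclusive")$nComparisons,
               62L * 101L)
  expect_error(buildComparisonGrid(character(0), c(0, 600)), "empty")
})

test_that("paired t maps match the closed-form statistic", {
  d <- array(0, dim = c(4, 1, 3))
  d[, 1, 1] <- c(1, 2, 3, 4)
  d[, 1, 2] <- c(-1, 1, -1, 1)
  tm <- pairedTMap(d)
  expect_equal(tm$df, 3L)
  expect_equal(tm$t[1, 1], mean(1:4) / (sd(1:4) / 2))
  expect_equal(tm$t[1, 2], 0)
  expect_equal(tm$t[1, 3], 0)                 # zero mean, zero variance

  dConst <- array(rep(2, 4 * 1 * 2), dim = c(4, 1, 2))
  expect_warning(tmc <- pairedTMap(dConst), "zero-variance")
  expect_true(all(is.infinite(tmc$t)))
})

test_that("cluster formation joins by time, adjacency and sign", {
  lay <- lineLayout(2)
  adj <- channelAdjacency(lay)
  mk <- function(v) matrix(v, nrow = 2, byrow = TRUE,
                           dimnames = list(lay$name, NULL))
  ## single channel active: runs at times 4-6 and 10
  t1 <- mk(c(0, 0, 0, 5, 5, 5, 0, 0, 0, 5, 0, 0,
             rep(0, 12)))
  cl <- formClusters(t1, df = 10, adjacency = adj)
  expect_length(cl, 2L)
  expect_equal(sort(vapply(cl, function(c) nrow(c$members), integer(1))),
               c(1L, 3L))
  expect_equal(sort(vapply(cl, `[[`, numeric(1), "mass")), c(5, 15))

  ## two adjacent channels, same time, same sign: one cluster
  t2 <- mk(c(0, 5, 0, 0, 0, 5, 0, 0))
  cl2 <- formClusters(t2, df = 10, adjacency = adj)
  expect_length(cl2, 1L)
  expect_equal(cl2[[1]]$mass, 10)

  ## opposite signs never join
  t3 <- mk(c(0, 5, 0, 0, 0, -5, 0, 0))
  cl3 <- formClusters(t3, df = 10, adjacency = adj)
  expect_length(cl3, 2L)

  ## sub-threshold maps yield nothing
  expect_length(formClusters(mk(rep(0.5, 8)), df = 10, adjacency = adj), 0L)

  ## one-sided with positive direction ignores negative excursions
  cl4 <- formClusters(t3, df = 10, sidedness = "one", adjacency = adj,
                      signDir = 1)
  expect_length(cl4, 1L)
  expect_equal(cl4[[1]]$sign, 1)
})

test_that("the permutation test agrees with exhaustive sign-flip enumeration", {
  D <- rbind(c(1, 2, 3, 0, 0),
             c(2, 1, 2, 0, 0),
             c(1, 3, 1, 0, 0),
             c(2, 2, 2, 0, 0))
  chan <- data.frame(name = "Cz", x = 0, y = 0)
  adj <- list(Cz = character(0))
  expect_message(
    res <- clusterMassTest(diffs = array(D, dim = c(4, 1, 5)),
                           channels = chan, adjacency = adj,
                           nPermutations = 5000, seed = 1),
    "enumerating")
  expect_equal(res@mode, "enumeration")

  ## independent brute-force oracle over all 16 assignments
  tcrit <- qt(0.975, 3)
  maxmass <- function(d) {
    m <- colMeans(d)
    s <- apply(d, 2, sd)
    t <- ifelse(s == 0, ifelse(m == 0, 0, Inf * sign(m)), m / (s / 2))
    cap <- max(abs(t[is.finite(t)]), 1)
    t[is.infinite(t)] <- sign(t[is.infinite(t)]) * cap
    supra <- abs(t) >= tcrit
    best <- 0; i <- 1
    while (i <= length(t)) {
      if (supra[i]) {
        j <- i; sgn <- sign(t[i]); mass <- 0
        while (j <= length(t) && supra[j] && sign(t[j]) == sgn) {
          mass <- mass + t[j]; j <- j + 1
        }
        best <- max(best, abs(mass)); i <- j
      } else i <- i + 1
    }
    best
  }
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), 4)))
  null <- apply(signs, 1, function(s) maxmass(s * D))
  pOracle <- sum(null >= maxmass(D) - 1e-12) / 16
  expect_equal(clusters(res)$pCorrected[1], pOracle)
})

test_that("null data give no clusters and p-values are never zero", {
  lay <- lineLayout(3)
  res <- suppressMessages(
    clusterMassTest(diffs = array(0, dim = c(5, 3, 10)), channels = lay,
                    nPermutations = 100, seed = 2))
  expect_equal(nrow(clusters(res)), 0L)

  set.seed(3)
  d <- array(rnorm(6 * 3 * 20), dim = c(6, 3, 20))
  d[, 2, 8:14] <- d[, 2, 8:14] + 3
  res2 <- suppressMessages(
    clusterMassTest(diffs = d, channels = lay, nPermutations = 200,
                    seed = 4))
  p <- clusters(res2)$pCorrected
  expect_true(all(p >= 1 / length(res2@nullMaxMasses)))
  expect_true(all(p <= 1))
})

test_that("stronger effects never raise the cluster p-value", {
  set.seed(8)
  lay <- lineLayout(4)
  d <- array(rnorm(8 * 4 * 25), dim = c(8, 4, 25))
  d[, 2:3, 10:18] <- d[, 2:3, 10:18] + 1
  p1 <- min(clusters(clusterMassTest(diffs = d, channels = lay,
                                     nPermutations = 300,
                                     seed = 5))$pCorrected)
  p2 <- min(clusters(clusterMassTest(diffs = 2 * d, channels = lay,
                                     nPermutations = 300,
                                     seed = 5))$pCorrected)
  expect_lte(p2, p1)
})

test_that("sampled permutations converge to the enumerated p-value", {
  set.seed(12)
  lay <- lineLayout(2)
  d <- array(rnorm(8 * 2 * 15), dim = c(8, 2, 15))
  d[, , 5:9] <- d[, , 5:9] + 1
  exact <- suppressMessages(
    clusterMassTest(diffs = d, channels = lay, nPermutations = 256,
                    seed = 1))
  expect_equal(exact@mode, "enumeration")
  sampled <- clusterMassTest(diffs = d, channels = lay, nPermutations = 200,
                             seed = 6)
  expect_equal(sampled@mode, "sampled")
  pE <- clusters(exact)$pCorrected[1]
  pS <- clusters(sampled)$pCorrected[1]
  mcsd <- sqrt(pE * (1 - pE) / 200)
  expect_lt(abs(pS - pE), 3 * mcsd + 1e-3)
})

test_that("permutation results are reproducible under a fixed seed", {
  set.seed(21)
  lay <- lineLayout(3)
  d <- array(rnorm(14 * 3 * 12), dim = c(14, 3, 12))
  r1 <- clusterMassTest(diffs = d, channels = lay, nPermutations = 150,
                        seed = 9)
  r2 <- clusterMassTest(diffs = d, channels = lay, nPermutations = 150,
                        seed = 9)
  expect_identical(r1@nullMaxMasses, r2@nullMaxMasses)
  expect_identical(clusters(r1), clusters(r2))
})
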