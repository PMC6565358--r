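test_that("global field power is the spatial standard deviation", {
  expect_equal(gfp(rep(3, 10)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  v <- rnorm(16)
  expect_equal(gfp(5 * v), 5 * gfp(v))
  expect_equal(gfp(-v), gfp(v))
  m <- cbind(c(1, -1), c(2, -2))
  expect_equal(gfp(m), c(1, 2))
})

test_that("AAHC recovers orthogonal generators and saturates at K = n", {
  set.seed(4)
  u1 <- c(1, -1, 0, 0) / sqrt(2)
  u2 <- c(0, 0, 1, -1) / sqrt(2)
  X <- cbind(3 * u1, 2 * u2, 4 * u1, 5 * u2, 2.5 * u1, 3 * u2)
  fit <- aahc(X, kRange = c(2, ncol(X)))
  expect_equal(explainedVariance(fit, 2), 1, tolerance = 1e-12)
  expect_equal(explainedVariance(fit, ncol(X)), 1, tolerance = 1e-12)
  tm <- templateMaps(fit, 2)
  match1 <- max(abs(crossprod(tm, u1)))
  match2 <- max(abs(crossprod(tm, u2)))
  expect_equal(match1, 1, tolerance = 1e-9)   # up to sign
  expect_equal(match2, 1, tolerance = 1e-9)
  expect_equal(colSums(tm^2), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(aahc(X, kRange = 2:10), "exceed")
})

test_that("AAHC explains at least as much variance as random partitions", {
  set.seed(11)
  X <- matrix(rnorm(4 * 8), nrow = 4)
  X <- sweep(X, 2, colMeans(X))
  fit <- aahc(X, kRange = 2)
  evA <- explainedVariance(fit, 2)

  ## brute-force oracle: every 2-partition of the 8 maps, centroids as
  ## polarity-aligned normalized means, same explained-variance measure
  evPartition <- function(groups) {
    expl <- 0
    for (g in unique(groups)) {
      mem <- which(groups == g)
      ref <- X[, mem[1]]
      cen <- rowSums(sapply(mem, function(j)
        sign(sum(X[, j] * ref) + (sum(X[, j] * ref) == 0)) * X[, j]))
      cen <- cen / sqrt(sum(cen^2))
      expl <- expl + sum((t(X[, mem, drop = FALSE]) %*% cen)^2)
    }
    expl / sum(X^2)
  }
  all2 <- vapply(1:(2^7 - 1), function(code)  # every non-empty bipartition
    evPartition(c(0, as.integer(intToBits(code))[1:7])), numeric(1))
  expect_gte(evA, median(all2))               # greedy beats typical partitions
  expect_gte(evA, 0.95 * max(all2))           # and comes close to the optimum
  expect_gte(evA, mean(replicate(50, evPartition(sample(c(0, 1), 8,
                                                        TRUE)))))
})

test_that("explained variance grows with the number of templates", {
  sim <- simulateMicrostateErps(nMaps = 6, nChannels = 20, nConditions = 2,
                                nTimes = 120, seed = 7)
  fit <- aahc(sim$erps, kRange = 2:12)
  ev <- explainedVariance(fit)
  expect_true(all(diff(ev[order(as.integer(names(ev)))]) >= -1e-9))
})

test_that("segmentation is invariant to consistent channel permutation", {
  sim <- simulateMicrostateErps(nMaps = 3, nChannels = 12, nConditions = 1,
                                nTimes = 60, seed = 9)
  erp <- sim$erps[[1]]
  set.seed(1)
  perm <- sample(nrow(erp))
  s1 <- backfit(sim$templates, erp)
  s2 <- backfit(sim$templates[perm, ], erp[perm, ])
  expect_identical(segmentLabels(s1), segmentLabels(s2))
})

test_that("map-count selection recovers the generating pool size", {
  sim <- simulateMicrostateErps(nMaps = 12, seed = 2)
  fit <- aahc(sim$erps, kRange = 2:20)
  expect_equal(selectNMaps(fit, "cv"), 12L)
  expect_equal(selectNMaps(fit, "meta"), 12L)

  ## a single generating map
  sim1 <- simulateMicrostateErps(nMaps = 1, nChannels = 15, nConditions = 1,
                                 nTimes = 60, seed = 3)
  fit1 <- aahc(sim1$erps, kRange = 1:6)
  expect_equal(selectNMaps(fit1, "cv"), 1L)

  ## selection is invariant to global rescaling
  fitScaled <- aahc(lapply(sim$erps, function(m) 3.7 * m), kRange = 2:20)
  expect_equal(selectNMaps(fitScaled, "cv"), selectNMaps(fit, "cv"))
})

test_that("back-fitting labels samples by spatial correlation", {
  sim <- simulateMicrostateErps(nMaps = 4, nChannels = 16, nConditions = 1,
                                nTimes = 120, noiseSd = 0, seed = 5)
  erp <- sim$erps[[1]]
  seg <- backfit(sim$templates, erp, polarity = "respect")
  expect_identical(segmentLabels(seg), as.integer(sim$labels[[1]]))
  expect_equal(explainedVariance(seg), 1, tolerance = 1e-9)

  ## polarity-ignoring labels survive a sign flip of the whole ERP
  segI <- backfit(sim$templates, erp, polarity = "ignore")
  segIflip <- backfit(sim$templates, -erp, polarity = "ignore")
  expect_identical(segmentLabels(segI), segmentLabels(segIflip))

  ## a template orthogonal to the data is never assigned under respect mode
  ortho <- qr.Q(qr(cbind(sim$templates, rnorm(16))))[, 5]
  ortho <- ortho - mean(ortho)
  seg2 <- backfit(cbind(sim$templates, ortho), erp, polarity = "respect")
  expect_false(any(segmentLabels(seg2) == 5, na.rm = TRUE))
})

test_that("segment statistics report visits in temporal order", {
  lab <- c(rep(1L, 25), rep(2L, 10), rep(1L, 5))
  times <- seq(100, by = 2, length.out = 40)
  seg <- new("Segmentation", labels = lab, times = times,
             gfp = rep(c(2, 4, 6), c(25, 10, 5)),
             explainedVariance = 0.9, condition = "PE",
             polarity = "respect")
  st <- segmentStats(seg)
  expect_equal(st$template, c(1, 1, 2))
  expect_equal(st$visit, c(1, 2, 1))
  expect_equal(st$onset, c(100, 170, 150))
  expect_equal(st$duration, c(50, 10, 20))
  expect_equal(st$meanGfp, c(2, 6, 4))
})

test_that("Welch comparisons have unequal-variance degrees of freedom", {
  a <- c(230, 250, 260, 270)
  b <- c(300, 380, 420, 500, 260)
  res <- compareConditions(a, b)
  o <- t.test(a, b)
  expect_equal(res$t, unname(o$statistic))
  expect_equal(res$df, unname(o$parameter))
  expect_lt(res$df, 7)                        # Satterthwaite, not pooled

  eq <- compareConditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
})
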