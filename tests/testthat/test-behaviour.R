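test_that("responses are classified into hits, misses and false alarms", {
  s <- buildSession(smallTaskConfig(randomGapRange = c(6L, 9L)), seed = 4)
  sq <- sequences(s)
  td <- s@config@trialDuration
  n <- nrow(sq)

  ## perfect performance
  resp <- perfectResponses(s)
  cls <- classifyResponses(s, resp)
  expect_equal(cls$hits, n)
  expect_equal(cls$misses, 0L)
  expect_equal(cls$falseAlarms, 0L)
  expect_equal(cls$PR, 1)

  ## two misses and two stray presses (after the grace window, before the
  ## next sequence's window opens)
  missed <- c(3L, 7L)
  resp2 <- perfectResponses(s, setdiff(seq_len(n), missed))
  ends <- (sq$startIndex[missed] + sq$realizedLength[missed]) * td
  stray <- data.frame(press = ends + 2050, release = ends + 2250)
  cls2 <- classifyResponses(s, rbind(resp2, stray))
  expect_equal(cls2$hits, n - 2L)
  expect_equal(cls2$misses, 2L)
  expect_equal(cls2$falseAlarms, 2L)
  expect_equal(cls2$hits + cls2$misses, n)
  expect_equal(cls2$PR,
               (n - 2) / n - 2 / cls2$nFaOpportunities)

  ## no presses at all
  cls3 <- classifyResponses(s, data.frame(press = numeric(),
                                          release = numeric()))
  expect_equal(cls3$hits, 0L)
  expect_equal(cls3$misses, n)
  expect_equal(cls3$PR, 0)

  expect_error(classifyResponses(s, data.frame(press = c(100, 200),
                                               release = c(300, 400))),
               "overlapping")
})

test_that("onset and offset latencies use the prescribed reference points", {
  expect_equal(onsetLatency(500, 500), 0)
  expect_equal(onsetLatency(1288, 500), 788)
  expect_lt(onsetLatency(300, 500), 0)        # press during cue retained

  off <- offsetLatency(3000, 3000)
  expect_equal(off$latency, 0)
  expect_false(off$excluded)
  expect_true(offsetLatency(5100, 3000)$excluded)        # 2100 ms late
  off2 <- offsetLatency(2700, 3000)                      # -300 ms
  expect_equal(off2$latency, -300)
  expect_false(off2$excluded)
  expect_true(offsetLatency(2400, 3000)$excluded)        # < -500 ms
})

test_that("latency tables line up presses with sequence metadata", {
  s <- buildSession(smallTaskConfig(), seed = 9)
  sur <- scoreSession(s)
  resp <- perfectResponses(s)
  lat <- latencyTable(s, resp, sur, participant = "p7")
  expect_equal(nrow(lat), nrow(sequences(s)))
  expect_true(all(lat$onsetLatency == 300))
  expect_true(all(lat$offsetLatency == 400))
  expect_false(any(lat$excluded))
  expect_equal(lat$I, sur$I[match(lat$seqId, sur$seqId)])
})

test_that("the within-subject ANOVA matches textbook sums of squares", {
  set.seed(42)
  grid <- expand.grid(participant = paste0("s", 1:5),
                      uncertainty = c("low", "high"),
                      compliance = c("terminated", "regular", "extended"),
                      stringsAsFactors = FALSE)
  grid$offsetLatency <- 500 +
    ifelse(grid$compliance == "terminated", 80,
           ifelse(grid$compliance == "extended", -120, 0)) +
    rnorm(nrow(grid), 0, 40)
  res <- rmAnova2x3(grid)

  ## independent oracle: explicit two-way within-subject decomposition
  y <- array(0, dim = c(5, 2, 3))
  for (r in seq_len(nrow(grid))) {
    i <- match(grid$participant[r], paste0("s", 1:5))
    a <- match(grid$uncertainty[r], c("high", "low"))  # factor order
    b <- match(grid$compliance[r], c("extended", "regular", "terminated"))
    y[i, a, b] <- grid$offsetLatency[r]
  }
  GM <- mean(y)
  mi <- apply(y, 1, mean); ma <- apply(y, 2, mean); mb <- apply(y, 3, mean)
  mia <- apply(y, c(1, 2), mean); mib <- apply(y, c(1, 3), mean)
  mab <- apply(y, c(2, 3), mean)
  ssA <- 5 * 3 * sum((ma - GM)^2)
  ssAS <- 3 * sum((mia - outer(mi, rep(1, 2)) - outer(rep(1, 5), ma) + GM)^2)
  ssB <- 2 * 5 * sum((mb - GM)^2)
  ssBS <- 2 * sum((mib - outer(mi, rep(1, 3)) - outer(rep(1, 5), mb) + GM)^2)
  ssAB <- 5 * sum((mab - outer(ma, rep(1, 3)) - outer(rep(1, 2), mb) + GM)^2)
  resid <- array(0, dim = dim(y))
  for (i in 1:5) for (a in 1:2) for (b in 1:3)
    resid[i, a, b] <- y[i, a, b] - mia[i, a] - mib[i, b] - mab[a, b] +
      mi[i] + ma[a] + mb[b] - GM
  ssABS <- sum(resid^2)
  fA <- (ssA / 1) / (ssAS / 4)
  fB <- (ssB / 2) / (ssBS / 8)
  fAB <- (ssAB / 2) / (ssABS / 8)

  expect_equal(res$F[res$effect == "uncertainty"], fA, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "compliance"], fB, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "uncertainty:compliance"], fAB,
               tolerance = 1e-8)
  expect_equal(res$df1, c(1, 2, 2))
  expect_equal(res$df2, c(4, 8, 8))
})

test_that("ANOVA p-values are calibrated under a permuted null", {
  set.seed(7)
  grid <- expand.grid(participant = paste0("s", 1:8),
                      uncertainty = c("low", "high"),
                      compliance = c("terminated", "regular", "extended"),
                      stringsAsFactors = FALSE)
  ps <- replicate(60, {
    grid$offsetLatency <- rnorm(nrow(grid))
    rmAnova2x3(grid)$p[2]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Benjamini-Hochberg adjustment is exact and monotone", {
  expect_equal(fdrBH(0.03), 0.03)
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrBH(rep(1, 5)), rep(1, 5))
  set.seed(1)
  p <- runif(20)
  q <- fdrBH(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p & q <= 1))
  ## vectors whose adjusted values are all tied are fixed points
  expect_equal(fdrBH(fdrBH(c(0.01, 0.02, 0.03, 0.04))),
               fdrBH(c(0.01, 0.02, 0.03, 0.04)))
  expect_error(fdrBH(c(0.1, 1.2)), "0, 1")
})

test_that("the cue-learning median split balances groups", {
  mk <- function(gains) {
    n <- length(gains)
    data.frame(participant = rep(sprintf("p%02d", seq_len(n)), each = 2),
               cuedColour = rep(c("learned", "new"), n),
               onsetLatency = as.vector(rbind(rep(800, n), 800 + gains)))
  }
  sp <- medianSplitGain(mk(c(-50, 0, 100, 200)))
  expect_equal(sp$median, 50)
  expect_equal(sp$assignment$group, c("no_gain", "no_gain", "gain", "gain"))
  expect_equal(sp$assignment$gainScore, c(-50, 0, 100, 200))

  ## all-equal scores: deterministic split by participant order
  sp2 <- medianSplitGain(mk(rep(25, 4)))
  expect_equal(sum(sp2$assignment$group == "gain"), 2L)
  expect_equal(sp2$assignment$group[1:2], c("gain", "gain"))

  ## 30 participants split into two groups of 15
  set.seed(3)
  sp3 <- medianSplitGain(mk(rnorm(30, 60, 100)))
  expect_equal(as.numeric(table(sp3$assignment$group)), c(15, 15))
})

test_that("surprise-latency correlations and their comparison behave", {
  d <- data.frame(compliance = "extended", excluded = FALSE,
                  I = seq(0.1, 2, length.out = 20),
                  offsetLatency = 1000 - 150 * seq(0.1, 2, length.out = 20))
  res <- correlateSurpriseLatency(d)
  expect_equal(res$r, -1)
  expect_equal(res$df, 18L)

  z <- compareCorrelations(-0.29, 74, 0.06, 74)
  expect_equal(abs(z$Z), 2.1368, tolerance = 1e-3)
  expect_lt(abs(abs(z$Z) - 2.11), 0.05)       # matches the reported contrast
  expect_equal(z$p, pnorm(z$Z), tolerance = 1e-12)
  expect_lt(abs(z$p - 0.016), 0.005)

  expect_equal(compareCorrelations(0.4, 50, 0.4, 60)$Z, 0)
  dd <- d; dd$offsetLatency <- 5
  expect_error(correlateSurpriseLatency(dd), "zero variance")
})

test_that("windowed release counts bin half-open intervals", {
  w <- windowReleaseCounts(numeric(0), c(-1000, 500))
  expect_equal(w$total, 0)
  expect_true(all(w$bins$count == 0))
  expect_equal(nrow(w$bins), 15L)

  w2 <- windowReleaseCounts(c(-950, -50, 499), c(-1000, 500))
  expect_equal(w2$total, 3)
  expect_equal(w2$bins$count[w2$bins$lo == -1000], 1)
  expect_equal(w2$bins$count[w2$bins$lo == -100], 1)
  expect_equal(w2$bins$count[w2$bins$lo == 400], 1)

  ## regular-sequence analysis window
  w3 <- windowReleaseCounts(c(-500, 499, 500), c(-500, 500))
  expect_equal(w3$total, 2)                   # 500 is outside [lo, hi)
  expect_error(windowReleaseCounts(1, c(-1050, 500)), "multiples")
})
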