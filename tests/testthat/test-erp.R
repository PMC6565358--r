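test_that("the band-pass filter keeps the passband and kills the stopband", {
  fs <- 500
  tt <- seq(0, 4, by = 1 / fs)
  mid <- floor(length(tt) * 0.25):floor(length(tt) * 0.75)

  y10 <- bandpassFilter(matrix(sin(2 * pi * 10 * tt), 1), 0.1, 30, fs)
  expect_lt(abs(max(abs(y10[mid])) - 1), 0.05)

  y50 <- bandpassFilter(matrix(sin(2 * pi * 50 * tt), 1), 0.1, 30, fs)
  expect_lt(max(abs(y50[mid])), 0.1)          # > 90 % attenuation

  yDC <- bandpassFilter(matrix(rep(7, length(tt)), 1), 0.1, 30, fs)
  expect_lt(max(abs(yDC)), 1e-9)

  expect_error(bandpassFilter(matrix(0, 1, 100), 30, 0.1, fs), "invalid band")
  expect_error(bandpassFilter(matrix(0, 1, 100), 0.1, 300, fs),
               "invalid band")
})

test_that("epoching cuts half-open windows and subtracts the baseline", {
  fs <- 500
  times <- seq(0, 9998, by = 2)
  chans <- lineLayout(3)
  flat <- matrix(5, nrow = 3, ncol = length(times))
  ep <- epochData(flat, times, eventOnsets = c(1000, 3000), chans,
                  labels = c("a", "b"))
  expect_equal(dim(epochsArray(ep)), c(2L, 3L, 350L))
  expect_equal(max(abs(epochsArray(ep))), 0)  # flat minus baseline
  expect_equal(epochLabels(ep), c("a", "b"))
  expect_equal(range(epochTimes(ep)), c(-100, 598))

  expect_warning(
    ep2 <- epochData(flat, times, eventOnsets = c(50, 3000), chans),
    "edge")
  expect_equal(nEpochs(ep2), 1L)
})

test_that("artifact rejection applies amplitude and step rules", {
  chans <- lineLayout(2)
  mk <- function(vals) {
    d <- array(0, dim = c(length(vals), 2, 20))
    for (i in seq_along(vals)) d[i, 1, 10] <- vals[i]
    new("EpochSet", data = d, times = seq(0, 38, by = 2), channels = chans,
        labels = rep("x", length(vals)), participant = "p", log = list())
  }
  clean <- rejectArtifacts(mk(rep(0, 10)))
  expect_equal(nEpochs(clean), 10L)
  expect_equal(nrow(clean@log$rejections), 0L)

  one <- rejectArtifacts(mk(c(rep(0, 10), 250)))
  expect_equal(nEpochs(one), 10L)
  expect_equal(one@log$rejections$reason, "amplitude")

  ## a 60 uV jump between consecutive samples trips the step rule
  d <- array(0, dim = c(1, 2, 20))
  d[1, 1, 11:20] <- 60
  ep <- new("EpochSet", data = d, times = seq(0, 38, by = 2),
            channels = chans, labels = "x", participant = "p", log = list())
  expect_equal(nEpochs(rejectArtifacts(ep)), 0L)

  ## monotonicity: a stricter amplitude bound never rejects fewer epochs
  set.seed(2)
  d2 <- array(rnorm(30 * 2 * 20, sd = 80), dim = c(30, 2, 20))
  ep2 <- new("EpochSet", data = d2, times = seq(0, 38, by = 2),
             channels = chans, labels = rep("x", 30), participant = "p",
             log = list())
  kept <- vapply(c(300, 200, 150, 100), function(th)
    nEpochs(rejectArtifacts(ep2, maxAbs = th, maxStep = 1e6)), integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("kurtosis outlier channels are replaced by their neighbour mean", {
  ## the z > 6 criterion needs a dense array: with C channels the population
  ## z-score is bounded by about (C-1)/sqrt(C), so use the full 62-channel
  ## layout as in practice
  set.seed(5)
  chans <- electrodeLayout62()
  nCh <- nrow(chans)
  d <- array(rnorm(10 * nCh * 50), dim = c(10, nCh, 50))
  ep <- new("EpochSet", data = d, times = seq(0, 98, by = 2),
            channels = chans, labels = rep("x", 10), participant = "p",
            log = list())
  none <- interpolateChannels(ep)
  expect_equal(nrow(none@log$interpolations), 0L)

  ## heavy-tailed spikes on Cz only
  bad <- match("Cz", chans$name)
  dBad <- d
  spikes <- sample(50, 4)
  dBad[, bad, spikes] <- dBad[, bad, spikes] + 60
  epB <- new("EpochSet", data = dBad, times = seq(0, 98, by = 2),
             channels = chans, labels = rep("x", 10), participant = "p",
             log = list())
  fixed <- interpolateChannels(epB)
  expect_equal(fixed@log$interpolations$channel, "Cz")
  nbNames <- channelAdjacency(chans)[["Cz"]]
  nb <- apply(dBad[, match(nbNames, chans$name), , drop = FALSE],
              c(1, 3), mean)
  expect_equal(epochsArray(fixed)[, bad, ], nb, tolerance = 1e-12)
  expect_error(interpolateChannels(epB, adjacency = setNames(
    rep(list(character(0)), nCh), chans$name)), "no clean neighbours")
})

test_that("average reference zeroes the channel sum at every sample", {
  set.seed(6)
  d <- array(rnorm(4 * 5 * 30) + 3, dim = c(4, 5, 30))
  ep <- new("EpochSet", data = d, times = seq(0, 58, by = 2),
            channels = lineLayout(5), labels = rep("x", 4),
            participant = "p", log = list())
  rr <- rereferenceAverage(ep)
  expect_lt(max(abs(apply(epochsArray(rr), c(1, 3), sum))), 1e-9)
  ## already zero-mean data is unchanged
  rr2 <- rereferenceAverage(rr)
  expect_equal(epochsArray(rr2), epochsArray(rr), tolerance = 1e-12)
})

test_that("condition averaging and grand averaging are arithmetic means", {
  chans <- lineLayout(2)
  d <- array(0, dim = c(3, 2, 4))
  d[1, , ] <- 1; d[2, , ] <- -1; d[3, , ] <- 5
  ep <- new("EpochSet", data = d, times = seq(0, 6, by = 2),
            channels = chans, labels = c("a", "a", "b"), participant = "p",
            log = list())
  er <- averageErp(ep)
  expect_equal(max(abs(erps(er)$a)), 0)              # 1 and -1 cancel
  expect_equal(erps(er)$b, matrix(5, 2, 4), ignore_attr = TRUE)
  expect_equal(unname(nEpochs(er)[c("a", "b")]), c(2L, 1L))
  expect_warning(averageErp(ep, conditions = c("a", "zz")), "zz")

  mk <- function(v) new("ERPSet", erps = list(a = matrix(v, 2, 4)),
                        nEpochs = c(a = 1L), times = seq(0, 6, by = 2),
                        channels = chans, level = "participant",
                        participant = "p")
  ga <- grandAverage(list(mk(1), mk(2), mk(6)))
  expect_equal(ga@erps$a, matrix(3, 2, 4), ignore_attr = TRUE)
  expect_equal(ga@level, "grand")

  ## average reference commutes with averaging
  set.seed(9)
  d2 <- array(rnorm(6 * 5 * 10), dim = c(6, 5, 10))
  ep2 <- new("EpochSet", data = d2, times = seq(0, 18, by = 2),
             channels = lineLayout(5), labels = rep("a", 6),
             participant = "p", log = list())
  a <- erps(averageErp(rereferenceAverage(ep2)))$a
  b <- erps(averageErp(ep2))$a
  b <- sweep(b, 2, colMeans(b))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("epoch sets survive a TSV round trip", {
  set.seed(10)
  ep <- new("EpochSet",
            data = array(rnorm(3 * 4 * 25), dim = c(3, 4, 25)),
            times = seq(-100, -100 + 24 * 2, by = 2),
            channels = lineLayout(4), labels = c("PE", "STD", "PE"),
            participant = "p1", log = list())
  f <- tempfile(fileext = ".tsv")
  writeEpochsTsv(ep, f)
  back <- readEpochsTsv(f)
  expect_equal(epochsArray(back), epochsArray(ep), tolerance = 1e-6)
  expect_equal(epochLabels(back), epochLabels(ep))
  expect_equal(channelInfo(back)$name, channelInfo(ep)$name)
})
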