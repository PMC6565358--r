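#' Zero-phase band-pass filter
#'
#' Butterworth band-pass (default 0.1-30 Hz) applied forward and backward
#' (zero phase); the DC component is removed. Accepts a channels-by-time
#' matrix or an [EpochSet-class] (filtered per epoch and channel).
#'
#' @param x matrix (channels x time) or [EpochSet-class].
#' @param low,high band edges in Hz; \code{0 < low < high < fs/2}.
#' @param fs sampling rate in Hz (taken from the time grid for an
#'   [EpochSet-class]).
#' @param order Butterworth section order (default 3, i.e. 6th-order
#'   band-pass).
#' @return object of the same shape, filtered.
#' @export
bandpassFilter <- function(x, low = 0.1, high = 30, fs = 500, order = 3L) {
  if (is(x, "EpochSet")) {
    fs <- 1000 / diff(x@times[1:2])
    d <- x@data
    for (e in seq_len(dim(d)[1]))
      d[e, , ] <- bandpassFilter(d[e, , , drop = TRUE], low, high, fs, order)
    x@data <- d
    return(x)
  }
  if (!(low > 0 && high > low && high < fs / 2))
    stop("invalid band: need 0 < low < high < fs/2")
  x <- as.matrix(x)
  x <- x - rowMeans(x)                      # remove DC before filtering
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  t(apply(x, 1, function(v) signal::filtfilt(bf, v)))
}

#' Cut epochs around events and baseline-correct
#'
#' One epoch per event onset over a half-open window (default [-100, 600) ms);
#' the mean over the baseline interval (default [-100, 0) ms) is subtracted
#' per channel. Events too close to the recording edges are dropped with a
#' warning.
#'
#' @param continuous channels x time matrix of the continuous recording.
#' @param sampleTimes time (ms) of each column of \code{continuous}.
#' @param eventOnsets event onsets in ms.
#' @param channels channel metadata data.frame.
#' @param labels condition label per event.
#' @param window epoch window (ms, half-open).
#' @param baseline baseline interval (ms, half-open); NULL disables.
#' @param participant participant id.
#' @return an [EpochSet-class].
#' @export
epochData <- function(continuous, sampleTimes, eventOnsets, channels,
                      labels = rep("event", length(eventOnsets)),
                      window = c(-100, 600), baseline = c(-100, 0),
                      participant = "p1") {
  dt <- diff(sampleTimes[1:2])
  rel <- seq(window[1], window[2] - dt, by = dt)
  nT <- length(rel)
  iStart <- round((eventOnsets + window[1] - sampleTimes[1]) / dt) + 1L
  ok <- iStart >= 1L & (iStart + nT - 1L) <= length(sampleTimes)
  if (any(!ok))
    warning(sprintf("%d event(s) too close to the recording edge dropped",
                    sum(!ok)))
  iStart <- iStart[ok]; labels <- labels[ok]
  dat <- array(0, dim = c(length(iStart), nrow(channels), nT))
  for (e in seq_along(iStart))
    dat[e, , ] <- continuous[, iStart[e]:(iStart[e] + nT - 1L)]
  eset <- new("EpochSet", data = dat, times = rel, channels = channels,
              labels = as.character(labels), participant = participant,
              log = list())
  if (!is.null(baseline)) baselineCorrect(eset, baseline) else eset
}

#' Subtract the per-channel baseline mean
#'
#' @param epochs an [EpochSet-class].
#' @param baseline ms interval, half-open.
#' @return baseline-corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, baseline = c(-100, 0)) {
  sel <- epochs@times >= baseline[1] & epochs@times < baseline[2]
  if (!any(sel)) stop("baseline interval contains no samples")
  d <- epochs@data
  base <- apply(d[, , sel, drop = FALSE], c(1, 2), mean)
  epochs@data <- d - as.vector(base)        # recycles over time (3rd dim)
  epochs
}

#' Reject epochs by amplitude and step thresholds
#'
#' An epoch is rejected when any channel sample exceeds \code{maxAbs}
#' microvolt in magnitude or any consecutive-sample difference exceeds
#' \code{maxStep} microvolt. The rejection log is appended to the epoch set's
#' log (and returned as attribute for inspection / manual override lists).
#'
#' @param epochs an [EpochSet-class].
#' @param maxAbs amplitude threshold (microvolt).
#' @param maxStep step threshold (microvolt per sample).
#' @return the [EpochSet-class] without rejected epochs; the log is in
#'   \code{slot log, element "rejections"}.
#' @export
rejectArtifacts <- function(epochs, maxAbs = 200, maxStep = 50) {
  if (maxAbs <= 0 || maxStep <= 0) stop("thresholds must be positive")
  d <- epochs@data
  nE <- dim(d)[1]
  reasons <- character(nE)
  for (e in seq_len(nE)) {
    m <- d[e, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(d)[2])
    if (any(abs(m) > maxAbs)) reasons[e] <- "amplitude"
    else if (ncol(m) > 1 && any(abs(m[, -1] - m[, -ncol(m)]) > maxStep))
      reasons[e] <- "step"
  }
  bad <- which(reasons != "")
  log <- data.frame(epoch = bad, reason = reasons[bad],
                    label = epochs@labels[bad], stringsAsFactors = FALSE)
  if (length(bad)) {
    epochs@data <- epochs@data[-bad, , , drop = FALSE]
    epochs@labels <- epochs@labels[-bad]
  }
  epochs@log$rejections <- log
  epochs
}

## population-sd z-scores
zScorePop <- function(v) {
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

#' Interpolate outlier channels by neighbour means
#'
#' Excess kurtosis of each channel (over all epochs and samples) is z-scored
#' across channels with the population standard deviation; channels with
#' z above the threshold are replaced, at every sample, by the unweighted mean
#' of their adjacent channels.
#'
#' @param epochs an [EpochSet-class].
#' @param kurtosisZ z threshold (default 6).
#' @param adjacency neighbour list (default from [channelAdjacency()]).
#' @return the [EpochSet-class] with offenders replaced; log in
#'   \code{slot log, element "interpolations"}.
#' @export
interpolateChannels <- function(epochs, kurtosisZ = 6, adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- channelAdjacency(epochs@channels)
  d <- epochs@data
  nCh <- dim(d)[2]
  k <- vapply(seq_len(nCh), function(c)
    e1071::kurtosis(as.vector(d[, c, ]), type = 1), numeric(1))
  z <- zScorePop(k)
  bad <- which(z > kurtosisZ)
  nms <- epochs@channels$name
  for (c in bad) {
    nb <- match(setdiff(adjacency[[nms[c]]], nms[bad]), nms)
    nb <- nb[!is.na(nb)]
    if (!length(nb)) stop("channel ", nms[c], " has no clean neighbours")
    d[, c, ] <- apply(d[, nb, , drop = FALSE], c(1, 3), mean)
  }
  epochs@data <- d
  epochs@log$interpolations <- data.frame(channel = nms[bad],
                                          kurtosisZ = z[bad],
                                          stringsAsFactors = FALSE)
  epochs
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample of every epoch, the mean over channels; channel
#' sums are zero afterwards.
#'
#' @param epochs an [EpochSet-class].
#' @return re-referenced [EpochSet-class].
#' @export
rereferenceAverage <- function(epochs) {
  if (dim(epochs@data)[2] < 2) stop("need at least 2 channels")
  d <- epochs@data
  m <- apply(d, c(1, 3), mean)              # epoch x time means
  for (c in seq_len(dim(d)[2])) d[, c, ] <- d[, c, ] - m
  epochs@data <- d
  epochs
}

#' Average epochs into per-condition ERPs
#'
#' Arithmetic mean over the (non-rejected) epochs of each condition; empty
#' conditions are omitted with a warning.
#'
#' @param epochs an [EpochSet-class].
#' @param conditions conditions to average (default: all present).
#' @return an [ERPSet-class] at participant level.
#' @export
averageErp <- function(epochs, conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(epochs@labels)
  empty <- setdiff(conditions, epochs@labels)
  if (length(empty)) {
    warning("no epochs for condition(s): ", paste(empty, collapse = ", "))
    conditions <- setdiff(conditions, empty)
  }
  erpsList <- lapply(conditions, function(cn) {
    sel <- which(epochs@labels == cn)
    apply(epochs@data[sel, , , drop = FALSE], c(2, 3), mean)
  })
  names(erpsList) <- conditions
  n <- vapply(conditions, function(cn) sum(epochs@labels == cn), integer(1))
  new("ERPSet", erps = erpsList, nEpochs = n, times = epochs@times,
      channels = epochs@channels, level = "participant",
      participant = epochs@participant)
}

#' Grand average across participants
#'
#' Unweighted mean of participant ERPs, per condition shared by all
#' participants.
#'
#' @param erpSets list of participant-level [ERPSet-class] objects.
#' @return an [ERPSet-class] at grand level.
#' @export
grandAverage <- function(erpSets) {
  stopifnot(length(erpSets) >= 1)
  conds <- Reduce(intersect, lapply(erpSets, function(e) names(e@erps)))
  if (!length(conds)) stop("no condition shared by all participants")
  out <- lapply(conds, function(cn)
    Reduce(`+`, lapply(erpSets, function(e) e@erps[[cn]])) / length(erpSets))
  names(out) <- conds
  new("ERPSet", erps = out,
      nEpochs = setNames(rep(length(erpSets), length(conds)), conds),
      times = erpSets[[1]]@times, channels = erpSets[[1]]@channels,
      level = "grand", participant = "")
}

#' Write / read an epoch set as tab-separated text
#'
#' Long-format text serialization of an [EpochSet-class] (one row per epoch,
#' channel and sample), with channel coordinates and labels restored on
#' reading.
#'
#' @param epochs an [EpochSet-class].
#' @param file path of the TSV file.
#' @param meta optional named character vector of `# key: value` header lines.
#' @return \code{writeEpochsTsv}: the path, invisibly; \code{readEpochsTsv}:
#'   an [EpochSet-class].
#' @export
writeEpochsTsv <- function(epochs, file, meta = NULL) {
  d <- epochs@data
  nE <- dim(d)[1]; nC <- dim(d)[2]; nT <- dim(d)[3]
  long <- data.frame(
    epoch = rep(seq_len(nE), times = nC * nT),
    channel = rep(rep(epochs@channels$name, each = nE), times = nT),
    x = rep(rep(epochs@channels$x, each = nE), times = nT),
    y = rep(rep(epochs@channels$y, each = nE), times = nT),
    time = rep(epochs@times, each = nE * nC),
    label = rep(epochs@labels, times = nC * nT),
    value = as.vector(d))
  writeTaggedTsv(long, file, c(meta, participant = epochs@participant))
  invisible(file)
}

#' @rdname writeEpochsTsv
#' @export
readEpochsTsv <- function(file) {
  long <- read.delim(file, comment.char = "#")
  nE <- max(long$epoch)
  chans <- unique(long[long$epoch == 1 & long$time == long$time[1],
                       c("channel", "x", "y")])
  names(chans)[1] <- "name"
  rownames(chans) <- NULL
  times <- sort(unique(long$time))
  d <- array(long$value, dim = c(nE, nrow(chans), length(times)))
  labels <- long$label[seq_len(nE)]
  new("EpochSet", data = d, times = times, channels = chans,
      labels = as.character(labels), participant = "p1", log = list())
}
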