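## reference time points of a sequence (ms from stream start)
seqTimes <- function(session, sq = session@sequences) {
  td <- session@config@trialDuration
  cueOnset <- sq$startIndex * td
  list(cueOnset = cueOnset,
       secondTrialOnset = cueOnset + td,
       endOnset = cueOnset + sq$realizedLength * td)   # first random trial
}

## attribute each press to the first sequence whose span (cue onset to end +
## grace) it overlaps; NA = stray press
attributePresses <- function(session, responses, grace = 2000) {
  st <- seqTimes(session)
  lo <- st$cueOnset - 500               # presses before cue - 500 ms excluded
  hi <- st$endOnset + grace
  vapply(seq_len(nrow(responses)), function(i) {
    p <- responses$press[i]
    j <- which(p >= lo & p < hi)
    if (length(j)) session@sequences$seqId[j[1]] else NA_integer_
  }, integer(1))
}

#' Classify responses into hits, misses and false alarms
#'
#' A sequence with at least one press overlapping its span (cue onset to
#' sequence end plus a 2000 ms grace window) counts as a hit; a sequence with
#' none is a miss; presses attributable to no sequence are false alarms.
#' The discrimination index is \eqn{PR = hits/(hits+misses) - FA/n_{FA}},
#' where the number of false-alarm opportunities is the number of
#' inter-sequence runs of random trials.
#'
#' @param session a [Session-class].
#' @param responses data.frame with \code{press} and \code{release} times (ms);
#'   presses of one participant must not overlap.
#' @param grace grace window after sequence end (ms).
#' @return list with \code{hits}, \code{misses}, \code{falseAlarms},
#'   \code{nFaOpportunities}, \code{PR} and the per-press attribution.
#' @export
classifyResponses <- function(session, responses, grace = 2000) {
  responses <- responses[order(responses$press), , drop = FALSE]
  if (any(responses$release <= responses$press))
    stop("release must follow press")
  if (nrow(responses) > 1 &&
      any(responses$press[-1] < responses$release[-nrow(responses)]))
    stop("overlapping presses from one participant")
  attrib <- attributePresses(session, responses, grace)
  nSeq <- nrow(session@sequences)
  hits <- length(unique(attrib[!is.na(attrib)]))
  misses <- nSeq - hits
  fa <- sum(is.na(attrib))
  gapRuns <- rle(session@trials$role == "random")
  nGaps <- sum(gapRuns$values)
  pr <- (if (nSeq > 0) hits / nSeq else 0) - (if (nGaps > 0) fa / nGaps else 0)
  list(hits = hits, misses = misses, falseAlarms = fa,
       nFaOpportunities = nGaps, PR = pr, attribution = attrib)
}

#' Onset latency of a press
#'
#' Reaction time of the button press relative to the onset of the second trial
#' of the sequence -- the earliest point at which a sequential pattern is
#' detectable. Negative values (press during the cue trial) are retained.
#'
#' @param pressTime press time (ms from stream start).
#' @param secondTrialOnset onset of the sequence's second trial (ms).
#' @return latency in ms.
#' @export
onsetLatency <- function(pressTime, secondTrialOnset) {
  pressTime - secondTrialOnset
}

#' Offset latency of a release, with exclusion flag
#'
#' Reaction time of the button release relative to the onset of the first
#' random trial after the sequence. Latencies earlier than -500 ms (before
#' the last sequential digit's predecessor boundary) or later than 2000 ms are
#' flagged excluded.
#'
#' @param releaseTime release time (ms from stream start).
#' @param endOnset onset of the first random trial after the sequence (ms).
#' @param bounds exclusion bounds (ms).
#' @return list with \code{latency} (ms) and \code{excluded} flag.
#' @export
offsetLatency <- function(releaseTime, endOnset, bounds = c(-500, 2000)) {
  lat <- releaseTime - endOnset
  list(latency = lat, excluded = lat < bounds[1] | lat > bounds[2])
}

#' Per-sequence latency table
#'
#' Combines response attribution, onset/offset latencies with exclusion flags,
#' sequence metadata and (optionally) ideal-observer surprise into one tidy
#' table, the substrate of all behavioural statistics.
#'
#' @param session a [Session-class].
#' @param responses press/release data.frame (see [classifyResponses()]).
#' @param surpriseTable optional output of [scoreSession()].
#' @param participant participant id recorded in the table.
#' @return data.frame with one row per hit sequence: \code{participant},
#'   \code{seqId}, \code{onsetLatency}, \code{offsetLatency}, \code{excluded},
#'   \code{compliance}, \code{cueType}, \code{uncertainty}, \code{cuedColour},
#'   \code{block}, \code{I}.
#' @export
latencyTable <- function(session, responses, surpriseTable = NULL,
                         participant = "p1") {
  cls <- classifyResponses(session, responses)
  sq <- session@sequences
  st <- seqTimes(session)
  rows <- lapply(seq_len(nrow(sq)), function(i) {
    hit <- which(cls$attribution == sq$seqId[i])
    if (!length(hit)) return(NULL)
    j <- hit[1]                       # first press attributed to the sequence
    off <- offsetLatency(responses$release[j], st$endOnset[i])
    data.frame(participant = participant, seqId = sq$seqId[i],
               onsetLatency = onsetLatency(responses$press[j],
                                           st$secondTrialOnset[i]),
               offsetLatency = off$latency, excluded = off$excluded,
               compliance = sq$compliance[i], cueType = sq$cueType[i],
               uncertainty = sq$uncertainty[i], cuedColour = sq$cuedColour[i],
               block = sq$block[i], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(tab)
  if (!is.null(surpriseTable))
    tab$I <- surpriseTable$I[match(tab$seqId, surpriseTable$seqId)]
  else tab$I <- NA_real_
  rownames(tab) <- NULL
  tab
}

#' Two-way repeated-measures ANOVA (uncertainty x compliance)
#'
#' Classical within-subject ANOVA on per-participant cell means: each effect's
#' F-ratio is tested against its participant-by-effect interaction stratum,
#' with degrees of freedom \eqn{(a-1, (a-1)(n-1))} for a factor with a levels
#' and n participants. Participants with empty cells are dropped.
#'
#' @param data data.frame with columns \code{participant}, \code{uncertainty},
#'   \code{compliance} and a response column.
#' @param response name of the response column (default
#'   \code{"offsetLatency"}).
#' @return data.frame with \code{effect}, \code{df1}, \code{df2}, \code{F},
#'   \code{p}.
#' @export
rmAnova2x3 <- function(data, response = "offsetLatency") {
  cells <- aggregate(data[[response]],
                     by = list(participant = data$participant,
                               uncertainty = data$uncertainty,
                               compliance = data$compliance),
                     FUN = mean)
  names(cells)[4] <- "y"
  nCells <- length(unique(cells$uncertainty)) *
    length(unique(cells$compliance))
  counts <- table(cells$participant)
  keep <- names(counts)[counts == nCells]
  if (length(keep) < length(counts))
    warning(sprintf("dropping %d participant(s) with empty cells",
                    length(counts) - length(keep)))
  cells <- cells[cells$participant %in% keep, ]
  if (length(keep) < 2) stop("need at least 2 complete participants")
  cells$participant <- factor(cells$participant)
  cells$uncertainty <- factor(cells$uncertainty)
  cells$compliance <- factor(cells$compliance)
  fit <- aov(y ~ uncertainty * compliance +
               Error(participant / (uncertainty * compliance)), data = cells)
  out <- lapply(summary(fit), function(s) {
    tab <- s[[1]]
    eff <- trimws(rownames(tab))
    isRes <- eff == "Residuals"
    if (all(isRes)) return(NULL)
    data.frame(effect = eff[!isRes],
               df1 = tab$Df[!isRes], df2 = tab$Df[isRes],
               F = tab$`F value`[!isRes], p = tab$`Pr(>F)`[!isRes],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1).
#'
#' @param p numeric vector of p-values in \code{[0, 1]}.
#' @return adjusted p-values.
#' @export
fdrBH <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Median split on cue-learning gain
#'
#' Computes each participant's gain score (mean onset latency to new minus
#' learned cue colours during the post session: positive = faster after
#' learned cues) and splits the sample at the median: strictly above the
#' median is the gain group. Ties at the median are resolved in stable
#' participant-id order so group sizes differ by at most one.
#'
#' @param postLatencies latency table (see [latencyTable()]) of the post
#'   session, pooled over participants; must contain \code{participant},
#'   \code{cuedColour} and \code{onsetLatency}.
#' @return list with \code{assignment} (data.frame: \code{participant},
#'   \code{gainScore}, \code{group}) and \code{median}.
#' @export
medianSplitGain <- function(postLatencies) {
  means <- aggregate(onsetLatency ~ participant + cuedColour,
                     data = postLatencies, FUN = mean)
  wide <- merge(means[means$cuedColour == "learned", c("participant", "onsetLatency")],
                means[means$cuedColour == "new", c("participant", "onsetLatency")],
                by = "participant", suffixes = c(".learned", ".new"),
                all = TRUE)
  bad <- is.na(wide$onsetLatency.learned) | is.na(wide$onsetLatency.new)
  if (any(bad)) {
    warning(sprintf("dropping %d participant(s) missing a condition mean",
                    sum(bad)))
    wide <- wide[!bad, ]
  }
  wide <- wide[order(wide$participant), ]
  gain <- wide$onsetLatency.new - wide$onsetLatency.learned
  med <- median(gain)
  group <- ifelse(gain > med, "gain", "no_gain")
  ## balance ties at the median by participant order
  n <- length(gain)
  target <- floor(n / 2)
  tied <- which(gain == med & group == "no_gain")
  i <- 1L
  while (sum(group == "gain") < target && i <= length(tied)) {
    group[tied[i]] <- "gain"; i <- i + 1L
  }
  list(assignment = data.frame(participant = wide$participant,
                               gainScore = gain, group = group,
                               stringsAsFactors = FALSE),
       median = med)
}

#' Correlation of surprise and offset latency
#'
#' Pearson correlation over (surprise, offset latency) pairs of extended
#' sequences, pooled across participants within a group.
#'
#' @param latencies latency table with \code{I} and \code{offsetLatency};
#'   excluded rows and rows with missing surprise are dropped.
#' @param compliance which compliance level to pool (default
#'   \code{"extended"}).
#' @return list with \code{r}, \code{n}, \code{df} (n - 2) and two-sided
#'   \code{p}.
#' @export
correlateSurpriseLatency <- function(latencies, compliance = "extended") {
  d <- latencies[latencies$compliance == compliance & !latencies$excluded &
                   !is.na(latencies$I), ]
  if (nrow(d) < 4) stop("need at least 4 pairs")
  if (sd(d$I) == 0 || sd(d$offsetLatency) == 0)
    stop("undefined correlation: zero variance")
  r <- cor(d$I, d$offsetLatency)
  n <- nrow(d)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, df = n - 2L, p = 2 * pt(-abs(tstat), n - 2))
}

#' Compare two independent correlations (Fisher z)
#'
#' \eqn{Z = (\mathrm{atanh}\, r_1 - \mathrm{atanh}\, r_2) /
#' \sqrt{1/(n_1-3) + 1/(n_2-3)}} with a normal reference distribution.
#'
#' @param r1,n1,r2,n2 correlations and pair counts.
#' @param alternative "less" (r1 < r2), "greater" or "two.sided"; one-tailed
#'   by default in the direction \code{r1 < r2}.
#' @return list with \code{Z} and \code{p}.
#' @examples
#' compareCorrelations(-0.29, 74, 0.06, 74)$Z # about -2.14
#' @export
compareCorrelations <- function(r1, n1, r2, n2,
                                alternative = c("less", "greater",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- switch(alternative,
              less = pnorm(z),
              greater = pnorm(z, lower.tail = FALSE),
              two.sided = 2 * pnorm(-abs(z)))
  list(Z = z, p = p)
}

#' Windowed release counts
#'
#' Counts button releases whose offset latency falls in a half-open window
#' \code{[lo, hi)}, overall and per consecutive bin (incremental releases per
#' bin).
#'
#' @param offsetLatencies numeric vector of offset latencies (ms).
#' @param window two-element ms interval; endpoints must be multiples of
#'   \code{bin}.
#' @param bin bin width in ms (default 100).
#' @return list with \code{total} and \code{bins} (data.frame \code{lo},
#'   \code{hi}, \code{count}).
#' @export
windowReleaseCounts <- function(offsetLatencies, window = c(-1000, 500),
                                bin = 100) {
  if (any(window %% bin != 0))
    stop("window endpoints must be multiples of bin")
  edges <- seq(window[1], window[2], by = bin)
  counts <- vapply(seq_len(length(edges) - 1L), function(i)
    sum(offsetLatencies >= edges[i] & offsetLatencies < edges[i + 1L]),
    numeric(1))
  list(total = sum(counts),
       bins = data.frame(lo = edges[-length(edges)], hi = edges[-1],
                         count = counts))
}
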