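#' Channel-by-time comparison grid
#'
#' Cartesian product of selected channels and the time samples inside the
#' analysis window. Windows are half-open \code{[lo, hi)} on the sampling
#' grid by default (62 channels x [0, 600) ms at 2 ms = 18600 points; 9 ROI
#' channels x [300, 600) ms = 1350); an inclusive-endpoint convention is
#' selectable.
#'
#' @param channels character vector of channel names.
#' @param window ms interval.
#' @param samplingRate Hz (default 500).
#' @param endpoint "half_open" or "inclusive".
#' @return list with \code{channels}, \code{times} and \code{nComparisons}.
#' @export
buildComparisonGrid <- function(channels, window, samplingRate = 500,
                                endpoint = c("half_open", "inclusive")) {
  endpoint <- match.arg(endpoint)
  if (!length(channels)) stop("empty channel selection")
  dt <- 1000 / samplingRate
  hi <- if (endpoint == "half_open") window[2] - dt else window[2]
  times <- seq(window[1], hi, by = dt)
  if (!length(times)) stop("empty time selection")
  list(channels = channels, times = times,
       nComparisons = length(channels) * length(times))
}

#' Paired t-score map
#'
#' Per channel-time point, the paired t statistic of the participant
#' condition differences, with df = n - 1. Zero-variance points with a
#' non-zero mean are set to +/-Inf with a warning (they are capped at the
#' largest finite magnitude during cluster formation).
#'
#' @param diffs array \code{[participant, channel, time]} of condition
#'   differences.
#' @return list with \code{t} (channels x time matrix) and \code{df}.
#' @export
pairedTMap <- function(diffs) {
  n <- dim(diffs)[1]
  if (n < 2) stop("need at least 2 participants")
  m <- apply(diffs, c(2, 3), mean)
  s <- apply(diffs, c(2, 3), sd)
  t <- m / (s / sqrt(n))
  zv <- s == 0 & m != 0
  if (any(zv)) {
    warning(sprintf("%d zero-variance point(s) set to +/-Inf", sum(zv)))
    t[zv] <- sign(m[zv]) * Inf
  }
  t[s == 0 & m == 0] <- 0
  list(t = t, df = n - 1L)
}

## cap infinite t-scores at the largest finite magnitude in the map
capInfinite <- function(t) {
  if (!any(is.infinite(t))) return(t)
  finite <- abs(t[is.finite(t)])
  cap <- if (length(finite) && max(finite) > 0) max(finite) else 1
  t[is.infinite(t)] <- sign(t[is.infinite(t)]) * cap
  t
}

#' Form clusters of supra-threshold t-scores
#'
#' Points whose uncorrected p-value is at or below \code{clusterAlpha} are
#' joined into clusters when they share the sign of t and are temporally
#' adjacent on the same channel or simultaneous on adjacent channels. A
#' cluster's mass is the sum of its t-scores.
#'
#' @param t channels x time t-score matrix (rownames = channel names).
#' @param df t degrees of freedom.
#' @param clusterAlpha uncorrected cluster-forming p (default .05).
#' @param sidedness "two" (threshold |t|) or "one" (hypothesized sign only).
#' @param adjacency neighbour list (see [channelAdjacency()]).
#' @param channelNames channel names for the rows of \code{t}.
#' @param signDir hypothesized sign for one-sided tests (+1 or -1).
#' @return list of clusters, each with \code{members} (data.frame channel,
#'   timeIndex), \code{mass} and \code{sign}.
#' @export
formClusters <- function(t, df, clusterAlpha = 0.05,
                         sidedness = c("two", "one"), adjacency,
                         channelNames = rownames(t), signDir = 1) {
  sidedness <- match.arg(sidedness)
  t <- capInfinite(t)
  tCrit <- if (sidedness == "two") qt(1 - clusterAlpha / 2, df) else
    qt(1 - clusterAlpha, df)
  nCh <- nrow(t); nT <- ncol(t)
  supra <- if (sidedness == "two") abs(t) >= tCrit else signDir * t >= tCrit
  if (!any(supra)) return(list())
  adjIdx <- adjacencyIndices(adjacency, channelNames)
  lab <- matrix(0L, nCh, nT)
  clustersOut <- list()
  cid <- 0L
  for (c0 in seq_len(nCh)) for (t0 in seq_len(nT)) {
    if (!supra[c0, t0] || lab[c0, t0] != 0L) next
    cid <- cid + 1L
    queue <- matrix(c(c0, t0), ncol = 2)
    lab[c0, t0] <- cid
    members <- queue
    sgn <- unname(sign(t[c0, t0]))
    while (nrow(queue)) {
      cc <- queue[1, 1]; tt <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      neigh <- NULL
      if (tt > 1L) neigh <- rbind(neigh, c(cc, tt - 1L))
      if (tt < nT) neigh <- rbind(neigh, c(cc, tt + 1L))
      if (length(adjIdx[[cc]]))
        neigh <- rbind(neigh, cbind(adjIdx[[cc]] + 1L, tt))
      for (k in seq_len(NROW(neigh))) {
        nc <- neigh[k, 1]; nt <- neigh[k, 2]
        if (supra[nc, nt] && lab[nc, nt] == 0L && sign(t[nc, nt]) == sgn) {
          lab[nc, nt] <- cid
          queue <- rbind(queue, c(nc, nt))
          members <- rbind(members, c(nc, nt))
        }
      }
    }
    clustersOut[[cid]] <- list(
      members = data.frame(channel = channelNames[members[, 1]],
                           timeIndex = members[, 2],
                           stringsAsFactors = FALSE),
      mass = sum(t[members]), sign = sgn)
  }
  clustersOut
}

#' Repeated-measures cluster-mass permutation test
#'
#' Paired t-tests at every channel-time point of the grid; supra-threshold
#' points are clustered (see [formClusters()]); the null distribution of the
#' most extreme cluster mass is built by within-participant condition
#' exchange, i.e. random sign flips of the participant difference maps, with
#' the observed data counted as one permutation set. Two-sided tests use the
#' maximum absolute mass, one-sided tests the maximum mass of the
#' hypothesized sign. For cohorts with \code{2^n} no larger than the
#' requested number of permutations, all sign assignments are enumerated
#' instead of sampled (exact test). Corrected p-values are the rank of the
#' observed mass in the null and can never be 0.
#'
#' @param erpA,erpB lists (one element per participant) of channels x time
#'   matrices for the two conditions; or pass \code{diffs} directly.
#' @param diffs optional array \code{[participant, channel, time]} of
#'   differences (overrides erpA/erpB).
#' @param channels channel layout data.frame for the rows.
#' @param adjacency neighbour list; computed from \code{channels} if NULL.
#' @param clusterAlpha cluster-forming uncorrected p (default .05).
#' @param nPermutations random permutations (default 5000).
#' @param familywiseAlpha significance level (default .05).
#' @param sidedness "two" or "one".
#' @param signDir hypothesized sign for one-sided tests.
#' @param seed integer seed for the permutation draws.
#' @return a [ClusterResult-class].
#' @export
clusterMassTest <- function(erpA = NULL, erpB = NULL, diffs = NULL,
                            channels, adjacency = NULL,
                            clusterAlpha = 0.05, nPermutations = 5000L,
                            familywiseAlpha = 0.05,
                            sidedness = c("two", "one"), signDir = 1,
                            seed = 1L) {
  sidedness <- match.arg(sidedness)
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  if (is.null(diffs)) {
    stopifnot(length(erpA) == length(erpB), length(erpA) >= 2)
    diffs <- array(0, dim = c(length(erpA), nrow(erpA[[1]]),
                              ncol(erpA[[1]])))
    for (i in seq_along(erpA)) diffs[i, , ] <- erpA[[i]] - erpB[[i]]
  }
  n <- dim(diffs)[1]; nCh <- dim(diffs)[2]; nT <- dim(diffs)[3]
  if (is.null(adjacency)) adjacency <- channelAdjacency(channels)
  channelNames <- channels$name
  adjIdx <- adjacencyIndices(adjacency, channelNames)

  tm <- suppressWarnings(pairedTMap(diffs))
  tObs <- capInfinite(tm$t)
  rownames(tObs) <- channelNames
  tCrit <- if (sidedness == "two") qt(1 - clusterAlpha / 2, tm$df) else
    qt(1 - clusterAlpha, tm$df)
  obsClusters <- formClusters(tObs, tm$df, clusterAlpha, sidedness,
                              adjacency, channelNames, signDir)

  ## participant x point matrix for the permutation engine
  D <- matrix(aperm(diffs, c(1, 2, 3)), nrow = n)   # column = (channel, time)
  enumerate <- 2^n <= nPermutations
  if (enumerate) {
    signsM <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    mode <- "enumeration"
    message(sprintf("enumerating all %d sign assignments", nrow(signsM)))
  } else {
    set.seed(as.integer(seed))
    signsM <- matrix(sample(c(-1, 1), n * nPermutations, replace = TRUE),
                     nrow = nPermutations)
    mode <- "sampled"
  }
  nullMax <- permNullMaxMass(D, signsM, tCrit, adjIdx, nCh, nT,
                             sidedness == "two", as.integer(signDir))
  obsMax <- if (length(obsClusters)) {
    if (sidedness == "two") max(abs(vapply(obsClusters, `[[`, numeric(1),
                                           "mass")))
    else max(signDir * vapply(obsClusters, `[[`, numeric(1), "mass"))
  } else 0
  nullFull <- if (enumerate) nullMax else c(obsMax, nullMax)

  stat <- function(mass) if (sidedness == "two") abs(mass) else signDir * mass
  pvals <- vapply(obsClusters, function(cl)
    sum(nullFull >= stat(cl$mass) - 1e-12) / length(nullFull), numeric(1))

  clDf <- if (length(obsClusters)) {
    data.frame(id = seq_along(obsClusters),
               sign = vapply(obsClusters, `[[`, numeric(1), "sign"),
               mass = vapply(obsClusters, `[[`, numeric(1), "mass"),
               nMembers = vapply(obsClusters, function(cl)
                 nrow(cl$members), integer(1)),
               pCorrected = pvals)
  } else data.frame(id = integer(), sign = numeric(), mass = numeric(),
                    nMembers = integer(), pCorrected = numeric())
  ord <- order(-abs(clDf$mass))
  new("ClusterResult",
      clusters = clDf[ord, , drop = FALSE],
      members = lapply(obsClusters[ord], `[[`, "members"),
      tMap = tObs, df = tm$df, nullMaxMasses = as.numeric(nullFull),
      nComparisons = as.integer(nCh * nT), mode = mode,
      spec = list(clusterAlpha = clusterAlpha,
                  nPermutations = if (enumerate) nrow(signsM) else
                    as.integer(nPermutations),
                  familywiseAlpha = familywiseAlpha, sidedness = sidedness,
                  signDir = signDir, seed = as.integer(seed)))
}
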