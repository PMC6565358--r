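modelDefaults <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "model-defaults.yaml",
                          package = "surpriseERP")
      cache <<- yaml::read_yaml(path)
    }
    cache
  }
})

#' Construct a behavioural response model
#'
#' Defaults are read from the package's versioned calibration file
#' (\code{inst/extdata/model-defaults.yaml}): trial-level offset latency
#' means/SDs per compliance level (terminated 619.48/96.55, regular
#' 532.81/99.74, extended 346.68/219.35 ms), onset latency means/SDs for
#' learned vs new cues, a per-participant cue-learning gain distribution, a
#' surprise-latency slope, premature-release rates and miss/false-alarm rates.
#' Any argument overrides its default.
#'
#' @param ... named overrides of the slots in [BehaviourModel-class].
#' @return a validated [BehaviourModel-class].
#' @export
behaviourModel <- function(...) {
  d <- modelDefaults()$behaviour
  args <- list(
    offsetMean = unlist(d$offsetMean), offsetSd = unlist(d$offsetSd),
    onsetMean = unlist(d$onsetMean), onsetSd = unlist(d$onsetSd),
    gainEffectMean = unlist(d$gainEffectMean),
    gainEffectSd = unlist(d$gainEffectSd),
    surpriseSlope = unlist(d$surpriseSlope),
    prematureReleaseRate = unlist(d$prematureReleaseRate),
    missRate = d$missRate, faRate = d$faRate)
  over <- list(...)
  args[names(over)] <- over
  do.call(new, c(list(Class = "BehaviourModel"), args))
}

#' Construct an ERP forward model
#'
#' Defaults (from the calibration file) place four components on the
#' 62-channel layout: a parieto-central P3b (positive, peaking 388 ms for
#' prediction errors and ~420 ms for checkpoints, absent for standards), a
#' centro-parietal N400 (negative, prediction errors only, peak 418 ms), a
#' right-parietal P600 (peak 500/554 ms) and an early frontal map around
#' 300 ms that is strongest for standards. Sensor noise is spatially smoothed
#' Gaussian noise.
#'
#' @param channels channel layout (default [electrodeLayout62()]).
#' @param ... named overrides of [ERPModel-class] slots
#'   (\code{samplingRate}, \code{window}, \code{components}, \code{noiseSd},
#'   \code{noiseSmoothing}).
#' @return a validated [ERPModel-class].
#' @export
erpModel <- function(channels = electrodeLayout62(), ...) {
  d <- modelDefaults()$erp
  comps <- lapply(d$components, function(comp) {
    comp$peak <- unlist(comp$peak); comp$weight <- unlist(comp$weight); comp
  })
  args <- list(channels = channels, samplingRate = d$samplingRate,
               window = as.numeric(unlist(d$window)), components = comps,
               noiseSd = d$noiseSd, noiseSmoothing = d$noiseSmoothing)
  over <- list(...)
  args[names(over)] <- over
  do.call(new, c(list(Class = "ERPModel"), args))
}

#' Simulate button press/release responses for one participant
#'
#' For every non-missed sequence the press occurs at the onset of the second
#' trial plus Gaussian onset latency (learned or new cue parameters; an
#' explicit participant \code{gainScore} shifts new-cue presses relative to
#' the learned-cue mean). The release occurs at the first random trial after
#' the sequence plus Gaussian offset latency for the compliance level, plus
#' the group's surprise slope times the condition-centred surprise (so trial
#' surprise modulates latency without shifting condition means; the Gaussian
#' component is shrunk so the total trial-level spread stays at the
#' configured sd). With the
#' group's premature-release probability, releases after extended sequences
#' are instead placed near the would-be end (offset latency uniform in
#' [-1000, -500] ms). False alarms are injected per inter-sequence gap.
#'
#' @param session a [Session-class].
#' @param model a [BehaviourModel-class].
#' @param group "gain" or "no_gain" (selects slope and premature rate).
#' @param gainScore participant cue-learning gain in ms, or NULL to use the
#'   marginal new-cue onset parameters.
#' @param surpriseTable output of [scoreSession()]; computed if NULL.
#' @param seed integer seed.
#' @return data.frame with \code{press} and \code{release} (ms), sorted.
#' @export
simulateResponses <- function(session, model = behaviourModel(),
                              group = c("gain", "no_gain"), gainScore = NULL,
                              surpriseTable = NULL, seed = 1L) {
  group <- match.arg(group)
  validObject(model)
  set.seed(as.integer(seed))
  if (is.null(surpriseTable)) surpriseTable <- scoreSession(session)
  sq <- session@sequences
  st <- seqTimes(session)
  I <- surpriseTable$I[match(sq$seqId, surpriseTable$seqId)]
  Ic <- stats::ave(I, sq$compliance, FUN = function(v) v - mean(v))
  slope <- model@surpriseSlope[[group]]
  premRate <- model@prematureReleaseRate[[group]]
  ## shrink the Gaussian part so the total trial-level spread per compliance
  ## stays at the configured sd despite the surprise coupling
  IcVar <- vapply(COMPLIANCE_LEVELS, function(cc) {
    v <- Ic[sq$compliance == cc]
    if (length(v) > 1) var(v) else 0
  }, numeric(1))
  offsetSdAdj <- vapply(COMPLIANCE_LEVELS, function(cc)
    sqrt(max(model@offsetSd[[cc]]^2 - slope^2 * IcVar[[cc]],
             (0.25 * model@offsetSd[[cc]])^2)), numeric(1))

  press <- release <- rep(NA_real_, nrow(sq))
  hit <- runif(nrow(sq)) >= model@missRate
  for (i in which(hit)) {
    if (sq$cuedColour[i] == "new") {
      mu <- if (is.null(gainScore)) model@onsetMean[["new"]] else
        model@onsetMean[["learned"]] + gainScore
      onsLat <- rnorm(1, mu, model@onsetSd[["new"]])
    } else {
      onsLat <- rnorm(1, model@onsetMean[["learned"]],
                      model@onsetSd[["learned"]])
    }
    press[i] <- st$secondTrialOnset[i] + onsLat
    comp <- sq$compliance[i]
    offLat <- rnorm(1, model@offsetMean[[comp]], offsetSdAdj[[comp]]) +
      slope * Ic[i]
    if (comp == "extended" && runif(1) < premRate)
      offLat <- runif(1, -1000, -500)
    release[i] <- st$endOnset[i] + offLat
    if (release[i] <= press[i]) release[i] <- press[i] + 50
  }
  resp <- data.frame(press = press[hit], release = release[hit])

  ## false alarms inside inter-sequence gaps
  runs <- rle(session@trials$role == "random")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  td <- session@config@trialDuration
  for (g in which(runs$values)) {
    if (runif(1) < model@faRate && runs$lengths[g] >= 3L) {
      t0 <- session@trials$onset[starts[g]]
      t1 <- session@trials$onset[ends[g]] + td
      p <- runif(1, t0, t1 - 400)
      resp <- rbind(resp, data.frame(press = p,
                                     release = p + runif(1, 200, 400)))
    }
  }
  resp <- resp[order(resp$press), , drop = FALSE]
  ## drop any overlapping holds (a press while still holding is impossible)
  keep <- rep(TRUE, nrow(resp))
  lastRelease <- -Inf
  for (i in seq_len(nrow(resp))) {
    if (resp$press[i] < lastRelease) keep[i] <- FALSE
    else lastRelease <- resp$release[i]
  }
  resp <- resp[keep, , drop = FALSE]
  rownames(resp) <- NULL
  resp
}

#' Simulate a cohort of synthetic participants
#'
#' Builds, per participant, a main session (and optionally a post session with
#' half new-colour cues), draws the participant's group (balanced gain /
#' no-gain split) and cue-learning gain score, simulates responses, and scores
#' latencies plus surprise. Bit-reproducible from \code{seed}.
#'
#' @param nParticipants cohort size (default 30).
#' @param config main-session [TaskConfig-class].
#' @param model a [BehaviourModel-class].
#' @param includePost also simulate a post session per participant.
#' @param postConfig post-session configuration (default: one low-uncertainty
#'   block of the same composition, sessionKind "post").
#' @param seed master seed; participant seeds are derived from it.
#' @return list with \code{participants} (each: \code{id}, \code{group},
#'   \code{gainScore}, \code{session}, \code{responses}, \code{latencies},
#'   \code{surprise}, and post-session counterparts when requested) and
#'   \code{groups} (data.frame).
#' @export
simulateCohort <- function(nParticipants = 30L, config = taskConfig(),
                           model = behaviourModel(), includePost = TRUE,
                           postConfig = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  pSeeds <- sample.int(.Machine$integer.max %/% 4L, nParticipants * 3L)
  groups <- sample(rep_len(c("gain", "no_gain"), nParticipants))
  gainScores <- rnorm(nParticipants,
                      model@gainEffectMean[groups],
                      model@gainEffectSd[groups])
  if (is.null(postConfig))
    postConfig <- taskConfig(nBlocksLow = 1L, nBlocksHigh = 0L,
                             compositionLow = config@compositionLow,
                             sequencesPerBlock = config@sequencesPerBlock,
                             sessionKind = "post")
  participants <- vector("list", nParticipants)
  for (i in seq_len(nParticipants)) {
    id <- sprintf("p%02d", i)
    ses <- buildSession(config, seed = pSeeds[i])
    sur <- scoreSession(ses)
    resp <- simulateResponses(ses, model, group = groups[i],
                              gainScore = gainScores[i],
                              surpriseTable = sur,
                              seed = pSeeds[nParticipants + i])
    lat <- latencyTable(ses, resp, surpriseTable = sur, participant = id)
    entry <- list(id = id, group = groups[i], gainScore = gainScores[i],
                  session = ses, responses = resp, latencies = lat,
                  surprise = sur)
    if (includePost) {
      pses <- buildSession(postConfig, seed = pSeeds[2L * nParticipants + i])
      psur <- scoreSession(pses)
      presp <- simulateResponses(pses, model, group = groups[i],
                                 gainScore = gainScores[i],
                                 surpriseTable = psur,
                                 seed = pSeeds[2L * nParticipants + i] + 1L)
      entry$postSession <- pses
      entry$postResponses <- presp
      entry$postLatencies <- latencyTable(pses, presp, surpriseTable = psur,
                                          participant = id)
    }
    participants[[i]] <- entry
  }
  list(participants = participants,
       groups = data.frame(participant = sprintf("p%02d",
                                                 seq_len(nParticipants)),
                           group = groups, gainScore = gainScores,
                           stringsAsFactors = FALSE))
}

## average-referenced, unit-norm Gaussian topography centred on a channel
componentTopography <- function(channels, centre, spread) {
  xy <- as.matrix(channels[, c("x", "y")])
  c0 <- xy[match(centre, channels$name), ]
  d2 <- rowSums(sweep(xy, 2, c0)^2)
  topo <- exp(-d2 / (2 * spread^2))
  topo <- topo - mean(topo)
  topo / sqrt(sum(topo^2))
}

## spatial smoothing matrix with unit-L2 rows (preserves per-sensor noise sd)
noiseSmoother <- function(channels, h) {
  if (h <= 0) return(diag(nrow(channels)))
  xy <- as.matrix(channels[, c("x", "y")])
  d2 <- as.matrix(dist(xy))^2
  W <- exp(-d2 / (2 * h^2))
  W / sqrt(rowSums(W^2))
}

#' Simulate multichannel ERP epochs for labelled events
#'
#' Forward model: each epoch is the sum over components of (condition weight x
#' amplitude x topography x Gaussian temporal kernel) plus spatially smoothed
#' Gaussian sensor noise. Event classes are collapsed to conditions:
#' \code{PE_termination}/\code{PE_extension} to \code{"PE"},
#' \code{CP_term_check}/\code{CP_ext_check} to \code{"CP"}, \code{STD} stays.
#'
#' @param events events data.frame (see [labelEvents()]) or a character
#'   vector of condition labels.
#' @param model an [ERPModel-class].
#' @param nPerCondition maximum epochs per condition (default 30; Inf for
#'   all).
#' @param participant participant id.
#' @param seed integer seed.
#' @return an [EpochSet-class].
#' @export
simulateEpochs <- function(events, model = erpModel(), nPerCondition = 30L,
                           participant = "p1", seed = 1L) {
  validObject(model)
  set.seed(as.integer(seed))
  if (is.data.frame(events)) {
    klass <- events$klass
    cond <- ifelse(grepl("^PE_", klass), "PE",
                   ifelse(grepl("^CP_", klass), "CP", klass))
  } else cond <- as.character(events)
  known <- unique(unlist(lapply(model@components, function(cc)
    names(cc$weight))))
  if (!all(cond %in% known))
    stop("unknown condition label(s): ",
         paste(setdiff(unique(cond), known), collapse = ", "))
  keep <- unlist(lapply(split(seq_along(cond), cond), function(ix)
    head(ix, nPerCondition)), use.names = FALSE)
  cond <- cond[sort(keep)]

  fs <- model@samplingRate
  times <- seq(model@window[1], model@window[2] - 1000 / fs, by = 1000 / fs)
  nCh <- nrow(model@channels)
  nT <- length(times)

  condSignal <- list()
  for (cn in unique(cond)) {
    sig <- matrix(0, nCh, nT)
    for (comp in model@components) {
      w <- comp$weight[[cn]]
      if (is.null(w) || w == 0) next
      topo <- componentTopography(model@channels, comp$centre, comp$spread)
      kern <- exp(-(times - comp$peak[[cn]])^2 / (2 * comp$width^2))
      sig <- sig + w * comp$amplitude * outer(topo, kern)
    }
    condSignal[[cn]] <- sig
  }
  S <- noiseSmoother(model@channels, model@noiseSmoothing)
  dat <- array(0, dim = c(length(cond), nCh, nT))
  for (e in seq_along(cond)) {
    noise <- model@noiseSd * (S %*% matrix(rnorm(nCh * nT), nCh, nT))
    dat[e, , ] <- condSignal[[cond[e]]] + noise
  }
  new("EpochSet", data = dat, times = times, channels = model@channels,
      labels = cond, participant = participant, log = list())
}

#' Simulate group ERPs from a pool of template topographies
#'
#' Builds one channels-by-time ERP per condition as a piecewise sequence of
#' maps drawn from a shared pool of \code{nMaps} orthonormal, average-
#' referenced topographies, scaled by a global-field-power profile, plus
#' i.i.d. sensor noise. Conditions draw their own segment sequences from the
#' common pool (sharing and omitting maps), and every map is used by at least
#' one condition.
#'
#' @param nMaps size of the topography pool.
#' @param nChannels number of channels (default 62).
#' @param nConditions number of conditions (default 4).
#' @param nTimes samples per condition (default 350).
#' @param minSegment minimum segment length in samples.
#' @param gfpProfile function of sample index giving the field-power envelope
#'   (microvolt); default a smooth positive curve.
#' @param noiseSd sensor noise sd (microvolt); NULL = 5 percent of the mean
#'   clean GFP.
#' @param seed integer seed.
#' @return list with \code{erps} (list of channels x time matrices),
#'   \code{templates} (channels x nMaps), \code{labels} (true map per sample
#'   per condition), \code{noiseSd}.
#' @export
simulateMicrostateErps <- function(nMaps = 12L, nChannels = 62L,
                                   nConditions = 4L, nTimes = 350L,
                                   minSegment = 15L, gfpProfile = NULL,
                                   noiseSd = NULL, seed = 1L) {
  stopifnot(nMaps >= 1L, nChannels > nMaps + 1L)
  set.seed(as.integer(seed))
  M <- matrix(rnorm(nChannels * nMaps), nChannels, nMaps)
  M <- sweep(M, 2, colMeans(M))              # average-referenced
  M <- qr.Q(qr(M))[, seq_len(nMaps), drop = FALSE]
  M <- sweep(M, 2, colMeans(M))              # re-centre (numerically tiny)
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")

  if (is.null(gfpProfile))
    gfpProfile <- function(i) 2 + 1.5 * sin(pi * i / nTimes)^2

  segmentsFor <- function() {
    bounds <- c(0L, sort(sample(seq.int(minSegment, nTimes - minSegment),
                                size = max(1L, nTimes %/% (2L * minSegment)))),
                nTimes)
    len <- diff(bounds)
    ## merge too-short segments into predecessors
    out <- integer(0)
    for (l in len) {
      if (l < minSegment && length(out)) out[length(out)] <- out[length(out)] + l
      else out <- c(out, l)
    }
    out
  }
  labels <- vector("list", nConditions)
  for (cn in seq_len(nConditions)) {
    len <- segmentsFor()
    maps <- integer(length(len))
    for (s in seq_along(len)) {
      cand <- if (s == 1L || nMaps == 1L) seq_len(nMaps) else
        setdiff(seq_len(nMaps), maps[s - 1L])
      maps[s] <- cand[sample.int(length(cand), 1L)]
    }
    labels[[cn]] <- rep(maps, len)
  }
  ## ensure full pool coverage: overwrite a run of a map that occurs in more
  ## than one run (so no other map loses its sole appearance); when every map
  ## has a single run, split the longest run to make room
  repeat {
    missing <- setdiff(seq_len(nMaps), unique(unlist(labels)))
    if (!length(missing)) break
    m <- missing[1]
    runsBy <- lapply(labels, rle)
    runCounts <- table(unlist(lapply(runsBy, `[[`, "values")))
    cand <- do.call(rbind, lapply(seq_len(nConditions), function(cn) {
      hit <- which(runCounts[as.character(runsBy[[cn]]$values)] > 1)
      if (length(hit)) cbind(cn, unname(hit)) else NULL
    }))
    if (!is.null(cand) && nrow(cand)) {
      pick <- cand[sample.int(nrow(cand), 1L), ]
      runs <- runsBy[[pick[1]]]
      runs$values[pick[2]] <- m
      labels[[pick[1]]] <- inverse.rle(runs)
    } else {
      lens <- do.call(rbind, lapply(seq_len(nConditions), function(cn)
        cbind(cn, seq_along(runsBy[[cn]]$lengths), runsBy[[cn]]$lengths)))
      pick <- lens[which.max(lens[, 3]), ]
      if (pick[3] < 2L * minSegment)
        stop("epoch too short to place all ", nMaps, " maps")
      runs <- runsBy[[pick[1]]]
      half <- runs$lengths[pick[2]] %/% 2L
      runs$lengths[pick[2]] <- runs$lengths[pick[2]] - half
      runs$values <- append(runs$values, m, after = pick[2])
      runs$lengths <- append(runs$lengths, half, after = pick[2])
      labels[[pick[1]]] <- inverse.rle(runs)
    }
  }

  env <- gfpProfile(seq_len(nTimes))
  clean <- lapply(labels, function(lab)
    M[, lab, drop = FALSE] * rep(env, each = nChannels))
  if (is.null(noiseSd)) {
    meanGfp <- mean(vapply(clean, function(x) mean(gfp(x)), numeric(1)))
    noiseSd <- 0.05 * meanGfp
  }
  erpsOut <- lapply(clean, function(x)
    x + matrix(rnorm(length(x), sd = noiseSd), nrow(x), ncol(x)))
  names(erpsOut) <- paste0("cond", seq_len(nConditions))
  list(erps = erpsOut, templates = M, labels = labels, noiseSd = noiseSd)
}
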