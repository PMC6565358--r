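#' Construct a task configuration
#'
#' Defaults describe the main experimental session: 8 blocks (4 low + 4 high
#' uncertainty) of 20 cued sequences each, with block compositions
#' (terminated, regular, extended) of (.05, .90, .05) under low and
#' (.15, .70, .15) under high uncertainty, so the session-wide cue validity
#' (fraction of regular sequences) is exactly .80. Short/long cues announce
#' regular lengths of 5 and 7 digits; terminations/extensions remove/add 2
#' items; digits are shown for 500 ms.
#'
#' @param nBlocksLow,nBlocksHigh number of low/high-uncertainty blocks.
#' @param sequencesPerBlock sequences per block.
#' @param compositionLow,compositionHigh named proportions over
#'   terminated/regular/extended; counts must be integral.
#' @param regularLengthShort,regularLengthLong cued regular lengths (digits).
#' @param deltaItems shortening/prolongation in items.
#' @param cueColours learned cue colour ids (short, long).
#' @param nFillerColours number of filler colours.
#' @param trialDuration stimulus duration (ms).
#' @param randomGapRange min/max random trials between sequences.
#' @param sessionKind "training", "main" or "post".
#' @param postNewCueFraction fraction of new-colour cues in a post session.
#' @return a validated [TaskConfig-class].
#' @examples
#' cfg <- taskConfig()
#' cfg <- taskConfig(sessionKind = "post", nBlocksLow = 1L, nBlocksHigh = 0L)
#' @export
taskConfig <- function(nBlocksLow = 4L, nBlocksHigh = 4L,
                       sequencesPerBlock = 20L,
                       compositionLow = c(terminated = 0.05, regular = 0.90,
                                          extended = 0.05),
                       compositionHigh = c(terminated = 0.15, regular = 0.70,
                                           extended = 0.15),
                       regularLengthShort = 5L, regularLengthLong = 7L,
                       deltaItems = 2L,
                       cueColours = c("cyan", "orange"),
                       nFillerColours = 6L,
                       trialDuration = 500,
                       randomGapRange = c(4L, 9L),
                       sessionKind = "main",
                       postNewCueFraction = 0.5) {
  new("TaskConfig",
      nBlocksLow = as.integer(nBlocksLow), nBlocksHigh = as.integer(nBlocksHigh),
      sequencesPerBlock = as.integer(sequencesPerBlock),
      compositionLow = compositionLow, compositionHigh = compositionHigh,
      regularLengthShort = as.integer(regularLengthShort),
      regularLengthLong = as.integer(regularLengthLong),
      deltaItems = as.integer(deltaItems),
      cueColours = cueColours, nFillerColours = as.integer(nFillerColours),
      trialDuration = trialDuration,
      randomGapRange = as.integer(randomGapRange),
      sessionKind = sessionKind, postNewCueFraction = postNewCueFraction)
}

#' Ascending digit sequence with wrap-around
#'
#' Each digit increases its predecessor by one, continuing circularly after 9
#' (8-9-0-1-2).
#'
#' @param startDigit first digit, 0-9.
#' @param length number of digits (>= 1).
#' @return integer vector of digits.
#' @examples
#' makeSequence(8, 5) # 8 9 0 1 2
#' @export
makeSequence <- function(startDigit, length) {
  if (length < 1) stop("length must be >= 1")
  if (startDigit < 0 || startDigit > 9) stop("startDigit must be in 0..9")
  (as.integer(startDigit) + 0:(as.integer(length) - 1L)) %% 10L
}

#' Realized length of a cued sequence
#'
#' Regular sequences have the cued length; terminated sequences are
#' \code{deltaItems} shorter, extended sequences \code{deltaItems} longer.
#' The cue digit counts towards the length.
#'
#' @param cueType "short" or "long".
#' @param compliance "terminated", "regular" or "extended".
#' @param config a [TaskConfig-class].
#' @return integer number of sequential digits (cue included).
#' @examples
#' realizedLength("long", "terminated", taskConfig()) # 5
#' @export
realizedLength <- function(cueType, compliance, config = taskConfig()) {
  cueType <- match.arg(cueType, c("short", "long"))
  compliance <- match.arg(compliance, COMPLIANCE_LEVELS)
  base <- if (cueType == "short") config@regularLengthShort else
    config@regularLengthLong
  base + switch(compliance, terminated = -config@deltaItems, regular = 0L,
                extended = config@deltaItems)
}

#' Build a full session of the serial-pattern task
#'
#' Deterministically generates the trial stream for one session: block order is
#' shuffled, per-block outcome composition is realized by exact counts (not
#' sampled), sequences are separated by random-trial gaps drawn uniformly from
#' \code{randomGapRange}, digit and colour assignments use reshuffled
#' round-robin pools so presentation frequencies stay balanced up to rounding,
#' and random-trial digits never continue the preceding digit by +1 (so only
#' genuine sequences ascend). For post sessions, \code{postNewCueFraction} of
#' the sequences start with fixed non-learned colours. Events are labelled via
#' [labelEvents()].
#'
#' @param config a validated [TaskConfig-class].
#' @param seed integer seed; identical seeds give identical sessions.
#' @return a [Session-class].
#' @examples
#' s <- buildSession(taskConfig(), seed = 1)
#' mean(sequences(s)$compliance == "regular") # 0.80
#' @export
buildSession <- function(config, seed = 1L) {
  validObject(config)
  set.seed(as.integer(seed))

  nBlocks <- config@nBlocksLow + config@nBlocksHigh
  unc <- sample(rep(c("low", "high"),
                    c(config@nBlocksLow, config@nBlocksHigh)))
  blocksDf <- data.frame(block = seq_len(nBlocks), uncertainty = unc,
                         stringsAsFactors = FALSE)

  nSeqTotal <- nBlocks * config@sequencesPerBlock
  ## balanced start digits across the whole session
  startPool <- sample(rep(0:9, length.out = nSeqTotal))
  fillerCols <- paste0("filler", seq_len(config@nFillerColours))
  newCueCols <- c(short = "newShort", long = "newLong")

  trialsList <- vector("list", nBlocks)
  seqList <- vector("list", nBlocks)
  idx <- 0L          # 0-based stream index
  seqId <- 0L
  poolPtr <- 0L

  for (b in seq_len(nBlocks)) {
    comp <- if (unc[b] == "low") config@compositionLow else
      config@compositionHigh
    counts <- round(comp[COMPLIANCE_LEVELS] * config@sequencesPerBlock)
    compliance <- sample(rep(COMPLIANCE_LEVELS, counts))
    cueType <- sample(rep_len(c("short", "long"), config@sequencesPerBlock))
    cued <- rep("learned", config@sequencesPerBlock)
    if (config@sessionKind == "post") {
      nNew <- round(config@postNewCueFraction * config@sequencesPerBlock)
      cued[sample.int(config@sequencesPerBlock, nNew)] <- "new"
    }
    gaps <- sample(seq.int(config@randomGapRange[1], config@randomGapRange[2]),
                   config@sequencesPerBlock + 1L, replace = TRUE)

    rl <- vapply(seq_len(config@sequencesPerBlock), function(i)
      realizedLength(cueType[i], compliance[i], config), integer(1))
    nRandom <- sum(gaps)
    nTrialsBlock <- nRandom + sum(rl)

    digit <- integer(nTrialsBlock)
    colour <- character(nTrialsBlock)
    role <- character(nTrialsBlock)
    pos <- 0L
    seqRows <- vector("list", config@sequencesPerBlock)
    randomSlots <- integer(0)

    for (i in seq_len(config@sequencesPerBlock)) {
      randomSlots <- c(randomSlots, pos + seq_len(gaps[i]))
      pos <- pos + gaps[i]
      poolPtr <- poolPtr + 1L
      digits <- makeSequence(startPool[poolPtr], rl[i])
      sel <- pos + seq_len(rl[i])
      digit[sel] <- digits
      role[sel] <- c("cue", rep("sequential", rl[i] - 1L))
      cueCol <- if (cued[i] == "learned") {
        config@cueColours[if (cueType[i] == "short") 1L else 2L]
      } else newCueCols[[cueType[i]]]
      colour[sel[1]] <- cueCol
      seqRows[[i]] <- data.frame(
        seqId = seqId + i, cueType = cueType[i], compliance = compliance[i],
        startIndex = idx + pos, realizedLength = rl[i], cuedColour = cued[i],
        colour = cueCol, block = b, uncertainty = unc[b],
        stringsAsFactors = FALSE)
      pos <- pos + rl[i]
    }
    randomSlots <- c(randomSlots, pos + seq_len(gaps[config@sequencesPerBlock + 1L]))
    role[randomSlots] <- "random"

    ## random-trial digits: balanced pool, never predecessor + 1 (so only
    ## genuine sequences ascend and post-sequence trials break the rule)
    rndPool <- sample(rep(0:9, length.out = length(randomSlots)))
    digit[randomSlots] <- rndPool
    for (r in seq_along(randomSlots)) {
      slot <- randomSlots[r]
      prev <- if (slot > 1L) digit[slot - 1L] else NA_integer_
      if (!is.na(prev) && digit[slot] == (prev + 1L) %% 10L) {
        later <- randomSlots[randomSlots > slot]
        ok <- later[digit[later] != (prev + 1L) %% 10L]
        if (length(ok)) {          # swap with a later random trial
          j <- ok[1]
          tmp <- digit[slot]; digit[slot] <- digit[j]; digit[j] <- tmp
        } else {                   # rare: replace, accepting slight imbalance
          alt <- setdiff(0:9, (prev + 1L) %% 10L)
          digit[slot] <- alt[sample.int(9L, 1L)]
        }
      }
    }

    ## filler colours for non-cue trials, balanced round-robin
    nonCue <- which(colour == "")
    colour[nonCue] <- sample(rep(fillerCols, length.out = length(nonCue)))

    trialsList[[b]] <- data.frame(
      index = idx + seq_len(nTrialsBlock) - 1L,
      digit = digit, colour = colour, role = role, block = b,
      stringsAsFactors = FALSE)
    seqList[[b]] <- do.call(rbind, seqRows)
    idx <- idx + nTrialsBlock
    seqId <- seqId + config@sequencesPerBlock
  }

  trialsDf <- do.call(rbind, trialsList)
  trialsDf$onset <- trialsDf$index * config@trialDuration
  trialsDf <- trialsDf[, c("index", "onset", "digit", "colour", "role", "block")]
  seqDf <- do.call(rbind, seqList)
  rownames(trialsDf) <- rownames(seqDf) <- NULL

  session <- new("Session", trials = trialsDf, sequences = seqDf,
                 events = data.frame(), blocks = blocksDf, config = config,
                 seed = as.integer(seed))
  session@events <- labelEvents(session)
  validObject(session)
  session
}

#' Label checkpoint, prediction-error and standard events
#'
#' For each cued sequence with regular length L and shortening/prolongation
#' delta, sequence position L - delta + 1 (1-based from the cue) carries the
#' termination check: a prediction error (\code{PE_termination}, a random digit
#' where a sequential one was cued) if the sequence was terminated, else a
#' checkpoint (\code{CP_term_check}). Position L + 1 carries the extension
#' check for sequences still running there: \code{PE_extension} (an unexpected
#' sequential digit) if extended, else \code{CP_ext_check} (the expected
#' regular end). The fourth position of every long extended sequence is a
#' deterministic standard (\code{STD}).
#'
#' @param session a [Session-class] built by [buildSession()].
#' @return data.frame with \code{trialIndex}, \code{onset}, \code{klass},
#'   \code{seqId}, \code{uncertainty}, \code{block}.
#' @export
labelEvents <- function(session) {
  cfg <- session@config
  sq <- session@sequences
  rows <- vector("list", nrow(sq) * 3L)
  n <- 0L
  for (i in seq_len(nrow(sq))) {
    L <- if (sq$cueType[i] == "short") cfg@regularLengthShort else
      cfg@regularLengthLong
    d <- cfg@deltaItems
    at <- function(pos) sq$startIndex[i] + pos - 1L   # 1-based position
    add <- function(pos, klass) {
      n <<- n + 1L
      rows[[n]] <<- data.frame(trialIndex = at(pos), klass = klass,
                               seqId = sq$seqId[i],
                               uncertainty = sq$uncertainty[i],
                               block = sq$block[i], stringsAsFactors = FALSE)
    }
    comp <- sq$compliance[i]
    if (comp == "terminated") {
      add(L - d + 1L, "PE_termination")
    } else {
      add(L - d + 1L, "CP_term_check")
      add(L + 1L, if (comp == "extended") "PE_extension" else "CP_ext_check")
      if (comp == "extended" && sq$cueType[i] == "long") add(4L, "STD")
    }
  }
  ev <- do.call(rbind, rows[seq_len(n)])
  ev$onset <- ev$trialIndex * cfg@trialDuration
  ev <- ev[order(ev$trialIndex), c("trialIndex", "onset", "klass", "seqId",
                                   "uncertainty", "block")]
  rownames(ev) <- NULL
  ev
}

#' Write a session to TSV files
#'
#' Writes \code{trials.tsv}, \code{sequences.tsv} and \code{events.tsv}
#' (events in an events-table layout with onset and duration in ms) into a
#' directory.
#'
#' @param session a [Session-class].
#' @param dir output directory (created if missing).
#' @param meta optional named character vector written as `# key: value`
#'   header lines.
#' @return invisibly, the paths written.
#' @export
writeSessionTsv <- function(session, dir, meta = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- session@events
  ev$duration <- session@config@trialDuration
  ev <- ev[, c("onset", "duration", "trialIndex", "klass", "seqId",
               "uncertainty", "block")]
  paths <- c(trials = file.path(dir, "trials.tsv"),
             sequences = file.path(dir, "sequences.tsv"),
             events = file.path(dir, "events.tsv"))
  writeTaggedTsv(session@trials, paths["trials"], meta)
  writeTaggedTsv(session@sequences, paths["sequences"], meta)
  writeTaggedTsv(ev, paths["events"], meta)
  invisible(paths)
}
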