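#' @useDynLib surpriseERP, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject setClass setValidity setGeneric setMethod is slot
#' @importFrom stats aggregate aov cor dist median na.omit p.adjust pnorm pt
#'   qt rnorm runif sd t.test setNames var
#' @importFrom utils head read.delim write.table packageVersion combn
#' @importFrom tools md5sum
NULL

COMPLIANCE_LEVELS <- c("terminated", "regular", "extended")
EVENT_CLASSES <- c("CP_term_check", "CP_ext_check", "PE_termination",
                   "PE_extension", "STD")

#' Task configuration for the cued serial-pattern paradigm
#'
#' Holds the generative parameters of a session of the serial-pattern detection
#' task: coloured single digits are streamed at a fixed rate; two colours act as
#' cues announcing an ascending digit sequence of regular length 5 (short cue)
#' or 7 (long cue); sequences may be terminated (\code{deltaItems} shorter),
#' regular, or extended (\code{deltaItems} longer). Block-wise composition of
#' the three outcomes sets the irreducible uncertainty of a block.
#'
#' @slot nBlocksLow,nBlocksHigh number of low/high-uncertainty blocks.
#' @slot sequencesPerBlock cued sequences per block.
#' @slot compositionLow,compositionHigh named proportions
#'   (terminated, regular, extended); each must sum to 1 and yield integral
#'   counts when multiplied by \code{sequencesPerBlock}.
#' @slot regularLengthShort,regularLengthLong cued regular sequence lengths in
#'   digits (cue included).
#' @slot deltaItems number of items removed/added by termination/extension.
#' @slot cueColours two colour identifiers used as learned cues (short, long).
#' @slot nFillerColours number of non-cue colours.
#' @slot trialDuration stimulus duration in ms.
#' @slot randomGapRange integer range of random trials between sequences.
#' @slot sessionKind one of \code{"training"}, \code{"main"}, \code{"post"}.
#' @slot postNewCueFraction fraction of sequences cued by new (non-learned)
#'   colours in a post session.
#' @seealso [taskConfig()] for the user-facing constructor with defaults.
#' @exportClass TaskConfig
setClass("TaskConfig", representation(
  nBlocksLow = "integer", nBlocksHigh = "integer",
  sequencesPerBlock = "integer",
  compositionLow = "numeric", compositionHigh = "numeric",
  regularLengthShort = "integer", regularLengthLong = "integer",
  deltaItems = "integer",
  cueColours = "character", nFillerColours = "integer",
  trialDuration = "numeric", randomGapRange = "integer",
  sessionKind = "character", postNewCueFraction = "numeric"
))

setValidity("TaskConfig", function(object) {
  msgs <- character()
  chkComp <- function(comp, what) {
    m <- character()
    if (!identical(sort(names(comp)), sort(COMPLIANCE_LEVELS)))
      m <- c(m, sprintf("%s must be named terminated/regular/extended", what))
    else {
      if (abs(sum(comp) - 1) > 1e-8)
        m <- c(m, sprintf("%s must sum to 1", what))
      counts <- comp * object@sequencesPerBlock
      if (any(abs(counts - round(counts)) > 1e-8))
        m <- c(m, sprintf("%s x sequencesPerBlock must be integral", what))
    }
    m
  }
  if (object@nBlocksLow > 0L)
    msgs <- c(msgs, chkComp(object@compositionLow, "compositionLow"))
  if (object@nBlocksHigh > 0L)
    msgs <- c(msgs, chkComp(object@compositionHigh, "compositionHigh"))
  if (object@regularLengthShort >= object@regularLengthLong)
    msgs <- c(msgs, "regularLengthShort must be < regularLengthLong")
  if (object@deltaItems < 1L)
    msgs <- c(msgs, "deltaItems must be >= 1")
  if (object@deltaItems >= object@regularLengthShort)
    msgs <- c(msgs, "deltaItems must be smaller than regularLengthShort")
  if (length(object@cueColours) != 2L)
    msgs <- c(msgs, "cueColours must have length 2")
  if (length(object@randomGapRange) != 2L ||
      object@randomGapRange[1] < 1L ||
      object@randomGapRange[1] > object@randomGapRange[2])
    msgs <- c(msgs, "randomGapRange must be increasing and >= 1")
  if (!object@sessionKind %in% c("training", "main", "post"))
    msgs <- c(msgs, "sessionKind must be training, main or post")
  if (object@postNewCueFraction < 0 || object@postNewCueFraction > 1)
    msgs <- c(msgs, "postNewCueFraction must be in [0, 1]")
  if (object@trialDuration <= 0)
    msgs <- c(msgs, "trialDuration must be positive")
  if (length(msgs)) msgs else TRUE
})

#' A generated session of the serial-pattern task
#'
#' Container for one session: the trial stream, the cued sequences, the
#' labelled events (checkpoints, prediction errors, standards), the block
#' table, and the configuration that generated it.
#'
#' @slot trials data.frame with columns \code{index} (0-based stream
#'   position), \code{onset} (ms), \code{digit} (0-9), \code{colour},
#'   \code{role} (random/cue/sequential), \code{block}.
#' @slot sequences data.frame with one row per cued sequence (\code{seqId},
#'   \code{cueType}, \code{compliance}, \code{startIndex},
#'   \code{realizedLength}, \code{cuedColour}, \code{colour}, \code{block},
#'   \code{uncertainty}).
#' @slot events data.frame of labelled events (see [labelEvents()]).
#' @slot blocks data.frame with \code{block} and \code{uncertainty}.
#' @slot config the [TaskConfig-class] used.
#' @slot seed integer seed the stream was built from.
#' @exportClass Session
setClass("Session", representation(
  trials = "data.frame", sequences = "data.frame", events = "data.frame",
  blocks = "data.frame", config = "TaskConfig", seed = "integer"
))

setValidity("Session", function(object) {
  msgs <- character()
  tr <- object@trials
  need <- c("index", "onset", "digit", "colour", "role", "block")
  if (!all(need %in% names(tr)))
    msgs <- c(msgs, "trials must have index/onset/digit/colour/role/block")
  else {
    if (nrow(tr) && !isTRUE(all.equal(tr$onset,
                                      tr$index * object@config@trialDuration)))
      msgs <- c(msgs, "trial onsets must equal index x trialDuration")
  }
  sq <- object@sequences
  if (nrow(sq) > 1) {
    ends <- sq$startIndex + sq$realizedLength - 1L
    if (any(sq$startIndex[-1] <= ends[-nrow(sq)]))
      msgs <- c(msgs, "sequences must not overlap")
  }
  if (length(msgs)) msgs else TRUE
})

#' Multichannel epoch container
#'
#' Epoched EEG-like data: an \code{epochs x channels x time} array in microvolt
#' with a uniform time grid (ms), channel metadata, and a condition label per
#' epoch.
#'
#' @slot data numeric array \code{[epoch, channel, time]} in microvolt.
#' @slot times numeric vector of sample times (ms), strictly increasing and
#'   uniformly spaced.
#' @slot channels data.frame with \code{name}, \code{x}, \code{y} (schematic
#'   2-D scalp coordinates).
#' @slot labels character condition label per epoch.
#' @slot participant participant identifier.
#' @slot log list of processing logs (rejections, interpolations).
#' @exportClass EpochSet
setClass("EpochSet", representation(
  data = "array", times = "numeric", channels = "data.frame",
  labels = "character", participant = "character", log = "list"
))

setValidity("EpochSet", function(object) {
  msgs <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-d array [epoch, channel, time]")
  if (d[2] != nrow(object@channels))
    msgs <- c(msgs, "channel dimension must match channels table")
  if (d[3] != length(object@times))
    msgs <- c(msgs, "time dimension must match times")
  if (d[1] != length(object@labels))
    msgs <- c(msgs, "one label per epoch required")
  if (length(object@times) > 1) {
    dt <- diff(object@times)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9)
      msgs <- c(msgs, "times must be strictly increasing and uniform")
  }
  if (length(msgs)) msgs else TRUE
})

#' Condition-average ERP container
#'
#' Per-condition channel-by-time averages, either for a single participant or
#' as a grand average across participants.
#'
#' @slot erps named list of \code{channels x time} matrices (microvolt), one
#'   per condition.
#' @slot nEpochs named integer vector: epochs averaged per condition.
#' @slot times time grid (ms).
#' @slot channels channel metadata data.frame.
#' @slot level \code{"participant"} or \code{"grand"}.
#' @slot participant identifier (empty for grand averages).
#' @exportClass ERPSet
setClass("ERPSet", representation(
  erps = "list", nEpochs = "integer", times = "numeric",
  channels = "data.frame", level = "character", participant = "character"
))

setValidity("ERPSet", function(object) {
  msgs <- character()
  if (!length(object@erps)) msgs <- c(msgs, "at least one condition required")
  for (nm in names(object@erps)) {
    m <- object@erps[[nm]]
    if (!is.matrix(m) || nrow(m) != nrow(object@channels) ||
        ncol(m) != length(object@times))
      msgs <- c(msgs, sprintf("condition '%s' has wrong dimensions", nm))
  }
  if (!object@level %in% c("participant", "grand"))
    msgs <- c(msgs, "level must be participant or grand")
  if (length(msgs)) msgs else TRUE
})

#' Result of a cluster-mass permutation test
#'
#' @slot clusters data.frame with one row per observed cluster: \code{id},
#'   \code{sign}, \code{mass} (summed t), \code{nMembers}, \code{pCorrected}.
#' @slot members list of data.frames (\code{channel}, \code{time}) giving each
#'   cluster's member points.
#' @slot tMap observed \code{channels x time} matrix of paired t-scores.
#' @slot df t-test degrees of freedom.
#' @slot nullMaxMasses null distribution of the most extreme cluster mass (the
#'   observed set included).
#' @slot nComparisons number of channel-time points tested.
#' @slot mode \code{"sampled"} or \code{"enumeration"}.
#' @slot spec list of test parameters (window, sidedness, alphas, seed).
#' @exportClass ClusterResult
setClass("ClusterResult", representation(
  clusters = "data.frame", members = "list", tMap = "matrix", df = "integer",
  nullMaxMasses = "numeric", nComparisons = "integer", mode = "character",
  spec = "list"
))

setValidity("ClusterResult", function(object) {
  msgs <- character()
  np <- length(object@nullMaxMasses)
  if (nrow(object@clusters)) {
    p <- object@clusters$pCorrected
    if (any(p < 1 / np - 1e-12) || any(p > 1 + 1e-12))
      msgs <- c(msgs, "cluster p-values must lie in [1/nPerm, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Microstate back-fitting result
#'
#' Labels every time sample of one condition's ERP with the template map that
#' fits it best (spatial correlation), together with the global field power
#' trace and the explained variance of the fit.
#'
#' @slot labels integer template id per sample (NA where unassigned).
#' @slot times time grid (ms).
#' @slot gfp global field power per sample (microvolt).
#' @slot explainedVariance fraction of spatial variance explained.
#' @slot condition condition name.
#' @slot polarity \code{"respect"} or \code{"ignore"}.
#' @exportClass Segmentation
setClass("Segmentation", representation(
  labels = "integer", times = "numeric", gfp = "numeric",
  explainedVariance = "numeric", condition = "character", polarity = "character"
))

setValidity("Segmentation", function(object) {
  msgs <- character()
  if (length(object@labels) != length(object@times) ||
      length(object@gfp) != length(object@times))
    msgs <- c(msgs, "labels, gfp and times must have equal length")
  if (any(object@gfp < 0)) msgs <- c(msgs, "gfp must be non-negative")
  if (object@explainedVariance < -1e-9 || object@explainedVariance > 1 + 1e-9)
    msgs <- c(msgs, "explainedVariance must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Behavioural response model for synthetic participants
#'
#' Generative parameters for button press/release times. Default latency means
#' and standard deviations (trial level, ms) are calibrated so a simulated
#' cohort reproduces the empirical offset/onset latency structure of the task:
#' slow releases after terminated sequences, intermediate after regular, fast
#' (and often premature) after extended sequences; faster presses after learned
#' than after new cue colours.
#'
#' @slot offsetMean,offsetSd named (terminated/regular/extended) release
#'   latency mean/sd in ms, relative to the first random trial after a
#'   sequence.
#' @slot onsetMean,onsetSd named (learned/new) press latency mean/sd in ms,
#'   relative to the second sequence trial.
#' @slot gainEffectMean,gainEffectSd named (gain/no_gain) distribution of the
#'   per-participant cue-learning gain (ms added to new-cue presses).
#' @slot surpriseSlope named (gain/no_gain) coupling of release latency to
#'   condition-centred surprise, ms per nat (negative: surprising outcomes
#'   speed the release).
#' @slot prematureReleaseRate named (gain/no_gain) probability of releasing at
#'   the would-be end of an extended sequence.
#' @slot missRate,faRate miss probability per sequence / false-alarm
#'   probability per inter-sequence gap.
#' @exportClass BehaviourModel
setClass("BehaviourModel", representation(
  offsetMean = "numeric", offsetSd = "numeric",
  onsetMean = "numeric", onsetSd = "numeric",
  gainEffectMean = "numeric", gainEffectSd = "numeric",
  surpriseSlope = "numeric", prematureReleaseRate = "numeric",
  missRate = "numeric", faRate = "numeric"
))

setValidity("BehaviourModel", function(object) {
  msgs <- character()
  if (!all(COMPLIANCE_LEVELS %in% names(object@offsetMean)) ||
      !all(COMPLIANCE_LEVELS %in% names(object@offsetSd)))
    msgs <- c(msgs, "offsetMean/offsetSd must be named by compliance level")
  if (!all(c("learned", "new") %in% names(object@onsetMean)))
    msgs <- c(msgs, "onsetMean must be named learned/new")
  if (any(object@offsetSd <= 0) || any(object@onsetSd <= 0))
    msgs <- c(msgs, "standard deviations must be positive")
  rates <- c(object@prematureReleaseRate, object@missRate, object@faRate)
  if (any(rates < 0 | rates > 1))
    msgs <- c(msgs, "rates must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Forward model for synthetic multichannel ERP epochs
#'
#' Components are scalp topographies (Gaussian bumps over the 2-D layout,
#' average-referenced and unit-normed) modulated by Gaussian temporal kernels
#' with condition-specific peak latency and weight. Epochs are the weighted sum
#' of components plus spatially smoothed Gaussian sensor noise.
#'
#' @slot channels channel layout data.frame (\code{name}, \code{x}, \code{y}).
#' @slot samplingRate Hz.
#' @slot window epoch window in ms, half-open \code{[lo, hi)}.
#' @slot components list; each element a list with \code{name}, \code{centre}
#'   (channel name), \code{spread} (layout units), \code{amplitude} (microvolt),
#'   \code{width} (ms), \code{peak} (named by condition, ms) and \code{weight}
#'   (named by condition).
#' @slot noiseSd sensor noise sd (microvolt).
#' @slot noiseSmoothing spatial Gaussian smoothing scale (layout units).
#' @exportClass ERPModel
setClass("ERPModel", representation(
  channels = "data.frame", samplingRate = "numeric", window = "numeric",
  components = "list", noiseSd = "numeric", noiseSmoothing = "numeric"
))

setValidity("ERPModel", function(object) {
  msgs <- character()
  if (!all(c("name", "x", "y") %in% names(object@channels)))
    msgs <- c(msgs, "channels must have name/x/y")
  if (object@samplingRate <= 0) msgs <- c(msgs, "samplingRate must be > 0")
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msgs <- c(msgs, "window must be an increasing ms interval")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  for (comp in object@components) {
    if (!all(c("name", "centre", "spread", "amplitude", "width",
               "peak", "weight") %in% names(comp)))
      msgs <- c(msgs, "each component needs name/centre/spread/amplitude/width/peak/weight")
    else if (!comp$centre %in% object@channels$name)
      msgs <- c(msgs, sprintf("component centre '%s' not in layout", comp$centre))
  }
  if (length(msgs)) msgs else TRUE
})

#' AAHC microstate fit over a range of map counts
#'
#' @slot results list keyed by \code{"K"}: each element holds \code{templates}
#'   (channels x K, unit norm), \code{labels} (sample assignment),
#'   \code{explainedVariance} and \code{sigma2} (residual variance).
#' @slot kRange integer vector of evaluated map counts.
#' @slot nChannels,nSamples input dimensions.
#' @exportClass MicrostateFit
setClass("MicrostateFit", representation(
  results = "list", kRange = "integer", nChannels = "integer",
  nSamples = "integer"
))
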