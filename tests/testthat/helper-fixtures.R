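## shared fixtures: small sessions, tiny channel layouts, response builders

smallTaskConfig <- function(...) {
  taskConfig(nBlocksLow = 1L, nBlocksHigh = 1L, sequencesPerBlock = 10L,
             compositionLow = c(terminated = 0.1, regular = 0.8,
                                extended = 0.1),
             compositionHigh = c(terminated = 0.2, regular = 0.6,
                                 extended = 0.2),
             ...)
}

## a line of channels with chain adjacency
lineLayout <- function(n, prefix = "ch") {
  data.frame(name = paste0(prefix, seq_len(n)),
             x = seq(0, by = 0.2, length.out = n), y = 0,
             stringsAsFactors = FALSE)
}

## perfect responses: press shortly after the second trial, release shortly
## after the sequence end, for a subset of sequences
perfectResponses <- function(session, which = NULL, pressLat = 300,
                             releaseLat = 400) {
  sq <- sequences(session)
  if (is.null(which)) which <- seq_len(nrow(sq))
  td <- session@config@trialDuration
  cue <- sq$startIndex[which] * td
  data.frame(press = cue + td + pressLat,
             release = cue + sq$realizedLength[which] * td + releaseLat)
}

## sequence position (1-based from cue) of an event within its sequence
eventPosition <- function(session, ev) {
  sq <- sequences(session)
  ev$trialIndex - sq$startIndex[match(ev$seqId, sq$seqId)] + 1L
}
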