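#' Ideal-observer state
#'
#' Running counts of past sequence outcomes from which surprise is computed.
#'
#' @param terminated,regular,extended non-negative integer counts of past
#'   observations of each outcome.
#' @param scopeKey context identifier under which the counts accumulate.
#' @return a list of class \code{"ObserverState"} with elements \code{counts}
#'   and \code{scopeKey}.
#' @export
observerState <- function(terminated = 0L, regular = 0L, extended = 0L,
                          scopeKey = NA_character_) {
  counts <- c(terminated = as.integer(terminated),
              regular = as.integer(regular),
              extended = as.integer(extended))
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, scopeKey = scopeKey),
            class = "ObserverState")
}

#' Surprise of a sequence outcome
#'
#' Shannon surprise of observing outcome \eqn{j} given the counts accumulated
#' so far: \eqn{p(x_i) = (n_{ji} + 1) / (\sum_k n_{ki} + 1)} and
#' \eqn{I(x_i) = -\ln p(x_i)} (nats). The counts are taken *before* the
#' current observation and the state is left unchanged. Note the weights over
#' the three outcomes are probability-like but not normalized (an empty
#' history gives p = 1 for every outcome); the formula is used exactly in this
#' form. An opt-in \code{normalized} variant divides by
#' \eqn{\sum_k n_{ki} + K} (with K the number of outcome types) for
#' sensitivity analyses.
#'
#' @param state an \code{ObserverState}.
#' @param outcome "terminated", "regular" or "extended".
#' @param normalized use the normalized denominator (default FALSE).
#' @return list with \code{outcome}, \code{p} and \code{I} (nats).
#' @examples
#' s <- observerState(2, 5, 1)
#' surprise(s, "extended")$p # 2/9
#' @export
surprise <- function(state, outcome, normalized = FALSE) {
  outcome <- match.arg(outcome, COMPLIANCE_LEVELS)
  denom <- sum(state$counts) + if (normalized) length(state$counts) else 1L
  p <- (state$counts[[outcome]] + 1) / denom
  list(outcome = outcome, p = p, I = -log(p))
}

#' Update observer counts with an observed outcome
#'
#' @inheritParams surprise
#' @return a new \code{ObserverState} with the outcome's count incremented.
#' @export
updateObserver <- function(state, outcome) {
  outcome <- match.arg(outcome, COMPLIANCE_LEVELS)
  state$counts[[outcome]] <- state$counts[[outcome]] + 1L
  state
}

#' Score every sequence of a session with ideal-observer surprise
#'
#' Sequences are visited in stream order; for each, surprise is computed from
#' the counts accumulated so far, then the counts are updated. The counting
#' scope controls when counts reset: \code{"block"} (default; uncertainty is
#' manipulated block-wise, so surprise fluctuates within blocks),
#' \code{"session"} (never reset), or \code{"block_cue"} (separate counts per
#' block and cue type).
#'
#' @param session a [Session-class].
#' @param scope "block", "session" or "block_cue".
#' @param normalized passed to [surprise()].
#' @return data.frame with \code{seqId}, \code{block}, \code{cueType},
#'   \code{outcome}, \code{p}, \code{I}, \code{scope}.
#' @export
scoreSession <- function(session, scope = c("block", "session", "block_cue"),
                         normalized = FALSE) {
  scope <- match.arg(scope)
  sq <- session@sequences[order(session@sequences$startIndex), ]
  key <- switch(scope,
                session = rep("all", nrow(sq)),
                block = as.character(sq$block),
                block_cue = paste(sq$block, sq$cueType, sep = ":"))
  states <- list()
  p <- I <- numeric(nrow(sq))
  for (i in seq_len(nrow(sq))) {
    k <- key[i]
    if (is.null(states[[k]])) states[[k]] <- observerState(scopeKey = k)
    rec <- surprise(states[[k]], sq$compliance[i], normalized = normalized)
    p[i] <- rec$p; I[i] <- rec$I
    states[[k]] <- updateObserver(states[[k]], sq$compliance[i])
  }
  data.frame(seqId = sq$seqId, block = sq$block, cueType = sq$cueType,
             outcome = sq$compliance, p = p, I = I, scope = scope,
             stringsAsFactors = FALSE)
}
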