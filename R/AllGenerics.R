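#' Accessors for package containers
#'
#' Small accessor generics so slots never need to be reached into directly:
#' \code{trials}, \code{sequences}, \code{events}, \code{blocks} for
#' [Session-class]; \code{epochsArray}, \code{epochTimes}, \code{channelInfo},
#' \code{epochLabels}, \code{nEpochs} for [EpochSet-class] and
#' [ERPSet-class]; \code{erps} for [ERPSet-class]; \code{clusters} and
#' \code{tMap} for [ClusterResult-class]; \code{templateMaps} and
#' \code{explainedVariance} for [MicrostateFit-class] and
#' [Segmentation-class].
#'
#' @param x object.
#' @param ... further arguments for methods.
#' @return The corresponding slot content (data.frame, array, list or vector).
#' @name accessors
#' @aliases trials sequences events blocks epochsArray epochTimes channelInfo
#'   epochLabels nEpochs erps clusters tMap templateMaps explainedVariance
#'   segmentLabels
NULL

#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))
#' @rdname accessors
#' @export
setGeneric("epochsArray", function(x) standardGeneric("epochsArray"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))
#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("erps", function(x) standardGeneric("erps"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))
#' @rdname accessors
#' @export
setGeneric("templateMaps", function(x, ...) standardGeneric("templateMaps"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x, ...) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' @rdname accessors
setMethod("trials", "Session", function(x) x@trials)
#' @rdname accessors
setMethod("sequences", "Session", function(x) x@sequences)
#' @rdname accessors
setMethod("events", "Session", function(x) x@events)
#' @rdname accessors
setMethod("blocks", "Session", function(x) x@blocks)

#' @rdname accessors
setMethod("epochsArray", "EpochSet", function(x) x@data)
#' @rdname accessors
setMethod("epochTimes", "EpochSet", function(x) x@times)
#' @rdname accessors
setMethod("channelInfo", "EpochSet", function(x) x@channels)
#' @rdname accessors
setMethod("epochLabels", "EpochSet", function(x) x@labels)
#' @rdname accessors
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1])

#' @rdname accessors
setMethod("erps", "ERPSet", function(x) x@erps)
#' @rdname accessors
setMethod("epochTimes", "ERPSet", function(x) x@times)
#' @rdname accessors
setMethod("channelInfo", "ERPSet", function(x) x@channels)
#' @rdname accessors
setMethod("nEpochs", "ERPSet", function(x) x@nEpochs)

#' @rdname accessors
setMethod("clusters", "ClusterResult", function(x) x@clusters)
#' @rdname accessors
setMethod("tMap", "ClusterResult", function(x) x@tMap)

#' @rdname accessors
#' @param k map count at which to extract templates / explained variance.
setMethod("templateMaps", "MicrostateFit", function(x, k) {
  key <- as.character(k)
  if (!key %in% names(x@results))
    stop("K = ", k, " was not evaluated (kRange: ",
         paste(range(x@kRange), collapse = ".."), ")")
  x@results[[key]]$templates
})
#' @rdname accessors
setMethod("explainedVariance", "MicrostateFit", function(x, k = NULL) {
  ev <- vapply(x@results, function(r) r$explainedVariance, numeric(1))
  names(ev) <- names(x@results)
  if (is.null(k)) ev else ev[[as.character(k)]]
})
#' @rdname accessors
setMethod("explainedVariance", "Segmentation", function(x) x@explainedVariance)
#' @rdname accessors
setMethod("segmentLabels", "Segmentation", function(x) x@labels)

setMethod("show", "Session", function(object) {
  cat(sprintf("Session (%s): %d trials, %d sequences, %d events, %d blocks\n",
              object@config@sessionKind, nrow(object@trials),
              nrow(object@sequences), nrow(object@events),
              nrow(object@blocks)))
  comp <- table(object@sequences$compliance)
  cat("  compliance:", paste(names(comp), comp, sep = "=", collapse = ", "),
      "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples [%g, %g] ms\n",
              d[1], d[2], d[3], min(object@times), max(object@times)))
  tab <- table(object@labels)
  cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ERPSet", function(object) {
  cat(sprintf("ERPSet (%s): %d conditions x %d channels x %d samples\n",
              object@level, length(object@erps), nrow(object@channels),
              length(object@times)))
  cat("  conditions:", paste(names(object@erps), collapse = ", "), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult (%s, %d comparisons, %d permutation sets)\n",
              object@mode, object@nComparisons, length(object@nullMaxMasses)))
  if (nrow(object@clusters)) {
    sig <- object@clusters$pCorrected <= object@spec$familywiseAlpha
    cat(sprintf("  %d cluster(s), %d familywise-significant\n",
                nrow(object@clusters), sum(sig)))
    print(head(object@clusters, 10))
  } else cat("  no supra-threshold clusters\n")
})

setMethod("show", "MicrostateFit", function(object) {
  cat(sprintf("MicrostateFit: K = %s over %d samples x %d channels\n",
              paste(range(object@kRange), collapse = ".."),
              object@nSamples, object@nChannels))
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation '%s': %d samples, %d templates used, EV = %.3f\n",
              object@condition, length(object@labels),
              length(unique(na.omit(object@labels))),
              object@explainedVariance))
})
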