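#' Global field power
#'
#' Spatial standard deviation of a scalp map:
#' \eqn{\mathrm{GFP}(u) = \sqrt{\frac{1}{C}\sum_i (u_i - \bar u)^2}}.
#' For a channels x time matrix the GFP of every column is returned.
#'
#' @param x numeric vector (one map) or channels x time matrix.
#' @return scalar or per-sample numeric vector (microvolt).
#' @examples
#' gfp(c(1, -1)) # 1
#' @export
gfp <- function(x) {
  if (is.matrix(x)) {
    centred <- sweep(x, 2, colMeans(x))
    sqrt(colMeans(centred^2))
  } else sqrt(mean((x - mean(x))^2))
}

## centre maps (columns) to average reference
avgRefCols <- function(X) sweep(X, 2, colMeans(X))

#' Atomize-and-agglomerate hierarchical clustering of scalp maps
#'
#' AAHC microstate clustering: every sample map starts as its own cluster; at
#' each step the cluster contributing least to the global explained variance
#' is atomized and each freed map is reassigned to the cluster whose centroid
#' has the highest squared spatial correlation with it, until the smallest
#' requested number of clusters remains. Centroids are polarity-aligned,
#' unit-norm member means. Snapshots are recorded at every K in
#' \code{kRange}.
#'
#' @param maps channels x samples matrix, or a list of channels x time
#'   condition ERPs that are concatenated in time (\code{mode = "pooled"}) or
#'   clustered separately (\code{mode = "per_condition"}, returning one fit
#'   per condition).
#' @param kRange integer vector of cluster counts to record.
#' @param mode "pooled" or "per_condition" (for list input).
#' @return a [MicrostateFit-class] (or a named list of fits for
#'   \code{mode = "per_condition"}).
#' @export
aahc <- function(maps, kRange = 2:20, mode = c("pooled", "per_condition")) {
  mode <- match.arg(mode)
  if (is.list(maps) && !is.data.frame(maps)) {
    if (mode == "per_condition")
      return(lapply(maps, aahc, kRange = kRange))
    maps <- do.call(cbind, maps)
  }
  maps <- as.matrix(maps)
  kRange <- sort(unique(as.integer(kRange)))
  if (max(kRange) > ncol(maps)) stop("K cannot exceed the number of samples")
  if (min(kRange) < 1) stop("K must be >= 1")
  X <- avgRefCols(maps)
  res <- aahcCpp(X, kRange)
  new("MicrostateFit", results = res[as.character(kRange)],
      kRange = kRange, nChannels = nrow(maps), nSamples = ncol(maps))
}

#' Select the number of template maps
#'
#' Map-count criteria evaluated on an AAHC sweep: the cross-validation
#' criterion \eqn{CV(K) = \hat\sigma^2_K \left(\frac{C-1}{C-1-K}\right)^2}
#' (minimized; K at or above C - 1 excluded), a Krzanowski-Lai criterion on
#' the residual within-cluster dispersion (maximized), or a meta mode taking
#' the rounded median of the available criteria's choices.
#'
#' @param fit a [MicrostateFit-class].
#' @param method "cv", "kl" or "meta".
#' @return selected K (integer).
#' @export
selectNMaps <- function(fit, method = c("cv", "kl", "meta")) {
  method <- match.arg(method)
  ks <- fit@kRange
  C <- fit@nChannels
  sigma2 <- vapply(as.character(ks), function(k) fit@results[[k]]$sigma2,
                   numeric(1))
  cvK <- function() {
    ok <- ks < C - 1
    cv <- sigma2[ok] * ((C - 1) / (C - 1 - ks[ok]))^2
    ks[ok][which.min(cv)]
  }
  klK <- function() {
    W <- sigma2                      # proportional to within dispersion
    dif <- numeric(length(ks))
    for (i in seq_along(ks)) {
      if (i == 1) { dif[i] <- NA; next }
      dif[i] <- (ks[i - 1])^(2 / C) * W[i - 1] - (ks[i])^(2 / C) * W[i]
    }
    kl <- rep(NA_real_, length(ks))
    for (i in seq_along(ks))
      if (i > 1 && i < length(ks) && is.finite(dif[i]) &&
          is.finite(dif[i + 1]) && abs(dif[i + 1]) > 0)
        kl[i] <- abs(dif[i]) / abs(dif[i + 1])
    if (all(is.na(kl))) return(cvK())
    ks[which.max(kl)]
  }
  switch(method,
         cv = cvK(),
         kl = klK(),
         meta = as.integer(round(median(c(cvK(), klK())))))
}

#' Fit template maps back onto an ERP
#'
#' Labels every time sample with the template of maximal spatial correlation.
#' With \code{polarity = "respect"} (ERP convention) the signed correlation is
#' maximized and samples with no positively correlated template stay
#' unassigned; with \code{polarity = "ignore"} the squared correlation is
#' maximized, making labels invariant to flipping the ERP's sign.
#'
#' @param templates channels x K matrix of template maps.
#' @param erp channels x time matrix for one condition.
#' @param polarity "respect" or "ignore".
#' @param condition condition name stored in the result.
#' @param times optional ms grid (defaults to sample indices).
#' @param minDuration optional minimum run length in samples; shorter runs
#'   are reassigned to the neighbouring run's label (no smoothing by
#'   default).
#' @return a [Segmentation-class].
#' @export
backfit <- function(templates, erp, polarity = c("respect", "ignore"),
                    condition = "cond", times = NULL, minDuration = 0L) {
  polarity <- match.arg(polarity)
  templates <- as.matrix(templates)
  erp <- as.matrix(erp)
  stopifnot(nrow(templates) == nrow(erp))
  if (is.null(times)) times <- seq_len(ncol(erp)) - 1
  U <- avgRefCols(erp)
  Tm <- avgRefCols(templates)
  Tm <- sweep(Tm, 2, sqrt(colSums(Tm^2)), "/")
  uNorm <- sqrt(colSums(U^2))
  corr <- t(Tm) %*% U / rep(pmax(uNorm, 1e-300), each = ncol(Tm))  # K x T
  if (polarity == "respect") {
    lab <- apply(corr, 2, which.max)
    best <- corr[cbind(lab, seq_len(ncol(U)))]
    lab[best <= 0] <- NA_integer_
  } else {
    lab <- apply(corr^2, 2, which.max)
  }
  lab[uNorm == 0] <- NA_integer_
  if (minDuration > 0L) {
    r <- rle(lab)
    while (any(short <- r$lengths < minDuration) && length(r$lengths) > 1) {
      i <- which(short)[1]
      donor <- if (i > 1) i - 1L else i + 1L
      r$values[i] <- r$values[donor]
      r <- rle(inverse.rle(r))
    }
    lab <- inverse.rle(r)
  }
  assigned <- !is.na(lab)
  expl <- sum((corr[cbind(lab[assigned], which(assigned))] *
                 uNorm[assigned])^2)
  ev <- if (sum(uNorm^2) > 0) expl / sum(uNorm^2) else 0
  new("Segmentation", labels = as.integer(lab), times = as.numeric(times),
      gfp = gfp(erp), explainedVariance = ev, condition = condition,
      polarity = polarity)
}

#' Onsets, durations and field power of template visits
#'
#' Each maximal run of a template's label is one visit: its onset is the time
#' of the first sample, its duration the run length times the sampling step,
#' and its field power the mean GFP over the run. Templates can visit a
#' condition several times (reported in order).
#'
#' @param segmentation a [Segmentation-class].
#' @return data.frame with \code{condition}, \code{template}, \code{visit},
#'   \code{onset}, \code{duration}, \code{meanGfp}.
#' @export
segmentStats <- function(segmentation) {
  lab <- segmentation@labels
  times <- segmentation@times
  dt <- if (length(times) > 1) diff(times[1:2]) else 1
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values)
  df <- data.frame(condition = segmentation@condition,
                   template = r$values[keep],
                   onset = times[starts[keep]],
                   duration = r$lengths[keep] * dt,
                   meanGfp = vapply(which(keep), function(i)
                     mean(segmentation@gfp[starts[i]:ends[i]]), numeric(1)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$template, df$onset), ]
  df$visit <- stats::ave(df$onset, df$template, FUN = seq_along)
  rownames(df) <- NULL
  df[, c("condition", "template", "visit", "onset", "duration", "meanGfp")]
}

#' Welch comparison of per-participant segment metrics
#'
#' Welch's two-sample t-test (unequal variances, Satterthwaite degrees of
#' freedom) on per-participant values of a segment metric (e.g. first onset
#' or mean GFP of one template) between two conditions or groups. Participants
#' missing the template contribute NA and are dropped.
#'
#' @param a,b numeric vectors of per-participant values.
#' @param alternative "two.sided", "less" or "greater".
#' @return data.frame with \code{t}, \code{df}, \code{p}, \code{meanA},
#'   \code{meanB}, \code{nA}, \code{nB}.
#' @export
compareConditions <- function(a, b, alternative = c("two.sided", "less",
                                                    "greater")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 values per group")
  tt <- t.test(a, b, var.equal = FALSE, alternative = alternative)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, meanA = mean(a), meanB = mean(b),
             nA = length(a), nB = length(b))
}
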