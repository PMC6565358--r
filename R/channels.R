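#' Standard 62-channel 10-10 electrode layout
#'
#' A 62-electrode subset of the extended 10-10 system with schematic 2-D
#' scalp coordinates (unit head, nose up). Includes the parieto-central
#' (CP1, CPz, CP2, P1, Pz, P2) and fronto-central (F1, Fz, F2) subsets used as
#' regions of interest, and lateral sites such as CP4 and P6.
#'
#' @return data.frame with \code{name}, \code{x}, \code{y}.
#' @export
electrodeLayout62 <- function() {
  rows <- list(
    list(y = 0.85,  names = c("Fp1", "Fp2")),
    list(y = 0.68,  names = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    list(y = 0.51,  names = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6",
                              "F8")),
    list(y = 0.255, names = c("FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4",
                              "FC6", "FT8", "FT10")),
    list(y = 0,     names = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
                              "T8")),
    list(y = -0.255, names = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4",
                               "CP6", "TP8")),
    list(y = -0.51, names = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6",
                              "P8")),
    list(y = -0.68, names = c("PO7", "PO3", "POz", "PO4", "PO8")),
    list(y = -0.85, names = c("O1", "Oz", "O2")),
    list(y = -1.0,  names = "Iz"))
  lateralX <- function(nm) {
    suffix <- sub("^[A-Za-z]+", "", nm)
    if (suffix == "z" || suffix == "") return(0)
    num <- as.integer(suffix)
    rank <- ceiling(num / 2)
    side <- if (num %% 2 == 1) -1 else 1    # odd = left
    side * rank * 0.22
  }
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r$names,
               x = vapply(r$names, lateralX, numeric(1)),
               y = r$y, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  stopifnot(nrow(out) == 62L)
  out
}

#' Channel adjacency from layout coordinates
#'
#' Two channels are neighbours when their 2-D distance is at most
#' \code{scale} times the median nearest-neighbour distance of the layout.
#' Alternatively a JSON file (channel name to neighbour-name list) can be
#' supplied and overrides the geometric rule.
#'
#' @param channels layout data.frame (\code{name}, \code{x}, \code{y}).
#' @param scale multiple of the median nearest-neighbour distance (default
#'   1.5).
#' @param json optional path to a JSON adjacency override.
#' @return named list: channel name -> character vector of neighbour names.
#' @export
channelAdjacency <- function(channels, scale = 1.5, json = NULL) {
  if (!is.null(json)) {
    adj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
    adj <- lapply(adj, as.character)
    missing <- setdiff(channels$name, names(adj))
    if (length(missing))
      stop("adjacency JSON misses channels: ", paste(missing, collapse = ", "))
    return(adj[channels$name])
  }
  xy <- as.matrix(channels[, c("x", "y")])
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  thr <- scale * median(nnd)
  adj <- lapply(seq_len(nrow(d)), function(i)
    channels$name[which(d[i, ] <= thr + 1e-12)])
  names(adj) <- channels$name
  adj
}

## adjacency list as 0-based integer indices for the C++ routines
adjacencyIndices <- function(adjacency, channelNames) {
  lapply(channelNames, function(nm)
    as.integer(match(intersect(adjacency[[nm]], channelNames),
                     channelNames) - 1L))
}
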