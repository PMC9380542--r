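## Sliding-window local-enrichment peak calling.
##
## The statistic: tile each contig into windowSize-bp sections overlapping by
## windowStep; for every section compare its read density to the density of
## the flankSize bp centred on the section (the section itself excluded,
## truncated at contig ends):
##
##   E_w = log2( (d_w + eps) / (d_flank + eps) ),  d = mass / bp
##
## Control tracks are subtracted on the log2 scale, and runs of windows with
## subtracted enrichment at or above log2(threshold) are merged into peaks.

#' Tile a genome into overlapping windows
#'
#' Windows start at 1, 1+step, 1+2*step, ...; a partial window at the contig
#' end is dropped, so every window is fully contained.  Contigs are treated
#' as linear and independent; windows never wrap.
#'
#' @param genome a \code{DNAStringSet}, or a named integer vector of contig
#'   lengths.
#' @param windowSize window width in bp (default 30).
#' @param windowStep step between window starts in bp (default 15).
#' @return a \code{GRanges} of windows with seqlengths set.
#' @examples
#' makeWindows(c(chr = 60L))   # three windows: 1-30, 16-45, 31-60
#' @export
makeWindows <- function(genome, windowSize = 30, windowStep = 15) {
  lens <- if (is(genome, "DNAStringSet"))
    setNames(width(genome), names(genome)) else genome
  windowSize <- as.integer(windowSize); windowStep <- as.integer(windowStep)
  if (windowStep > windowSize || windowStep < 1L)
    stop("need 1 <= windowStep <= windowSize")
  if (any(lens < windowSize))
    stop("contig shorter than one window: ",
         paste(names(lens)[lens < windowSize], collapse = ", "))
  grs <- lapply(names(lens), function(ct) {
    starts <- seq.int(1L, lens[[ct]] - windowSize + 1L, by = windowStep)
    GRanges(ct, IRanges(starts, width = windowSize))
  })
  gr <- do.call(c, grs)
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Sum per-base depth over each window
#'
#' @param cov per-base depth \code{RleList} (one element per contig).
#' @param grid window \code{GRanges} from \code{\link{makeWindows}}.
#' @return numeric vector of per-window mass, aligned with \code{grid}.
#' @export
countInWindows <- function(cov, grid) {
  cts <- as.character(seqnames(grid))
  if (!all(unique(cts) %in% names(cov)))
    stop("coverage track lacks contig(s) present in the window grid")
  out <- numeric(length(grid))
  for (ct in unique(cts)) {
    i <- which(cts == ct)
    out[i] <- viewSums(Views(cov[[ct]], IRanges::ranges(grid[i])))
  }
  out
}

#' Per-window log2 local enrichment
#'
#' Compares each window's read density to the density of the local
#' background: the \code{flankSize} bp centred on the window, excluding the
#' window itself and truncated at contig ends (densities are always computed
#' over the bases actually available).  A pseudocount bounds the statistic
#' on sparse tracks; all-zero coverage gives enrichment 0 everywhere.
#'
#' @param cov per-base depth \code{RleList}.
#' @param grid window \code{GRanges} with seqlengths set.
#' @param flankSize total background span in bp (default 3000).
#' @param pseudocount density-unit pseudocount; default one read per flank,
#'   \code{1/(flankSize - windowSize)}.  Use 0 for the raw ratio.
#' @param sampleLabel label stored on the returned track.
#' @return an \linkS4class{EnrichmentTrack} (not yet control-subtracted).
#' @export
localEnrichment <- function(cov, grid, flankSize = 3000, pseudocount = NULL,
                            sampleLabel = "sample") {
  windowSize <- unique(width(grid))
  if (length(windowSize) != 1L) stop("grid windows must have equal width")
  flankSize <- as.integer(flankSize)
  if (flankSize <= windowSize) stop("flankSize must exceed windowSize")
  if (is.null(pseudocount)) pseudocount <- 1 / (flankSize - windowSize)
  lens <- GenomeInfoDb::seqlengths(grid)
  if (any(is.na(lens))) stop("grid needs seqlengths")

  half <- (flankSize - windowSize) %/% 2L
  winMass <- countInWindows(cov, grid)
  cts <- as.character(seqnames(grid))
  regMass <- numeric(length(grid))
  regWidth <- integer(length(grid))
  for (ct in unique(cts)) {
    i <- which(cts == ct)
    rs <- pmax(start(grid)[i] - half, 1L)
    re <- pmin(end(grid)[i] + half, lens[[ct]])
    regMass[i] <- viewSums(Views(cov[[ct]], IRanges(rs, re)))
    regWidth[i] <- re - rs + 1L
  }
  dWin <- winMass / windowSize
  dFlank <- (regMass - winMass) / (regWidth - windowSize)
  e <- log2((dWin + pseudocount) / (dFlank + pseudocount))
  new("EnrichmentTrack", windows = grid, enrichment = e,
      sampleLabel = sampleLabel, controlSubtracted = FALSE)
}

#' @describeIn EnrichmentTrack-class per-window log2 enrichment values.
#' @export
setMethod("enrichment", "EnrichmentTrack", function(x) x@enrichment)

#' @describeIn EnrichmentTrack-class the window grid.
#' @export
setMethod("windows", "EnrichmentTrack", function(x) x@windows)

#' @describeIn EnrichmentTrack-class the sample label.
#' @export
setMethod("sampleLabel", "EnrichmentTrack", function(x) x@sampleLabel)

#' @describeIn EnrichmentTrack-class whether a control has been subtracted.
#' @export
setMethod("isControlSubtracted", "EnrichmentTrack",
          function(x) x@controlSubtracted)

setMethod("show", "EnrichmentTrack", function(object) {
  cat(sprintf("EnrichmentTrack '%s': %d windows on %d contig(s)%s\n",
              object@sampleLabel, length(object@windows),
              length(GenomeInfoDb::seqlevels(object@windows)),
              if (object@controlSubtracted) ", control-subtracted" else ""))
  cat(sprintf("  log2 enrichment: min %.3g, median %.3g, max %.3g\n",
              min(object@enrichment), median(object@enrichment),
              max(object@enrichment)))
})

#' @rdname subtractControl
#' @export
setMethod("subtractControl", c("EnrichmentTrack", "EnrichmentTrack"),
          function(x, control) {
  if (x@controlSubtracted || control@controlSubtracted)
    stop("tracks must not already be control-subtracted")
  if (length(x@windows) != length(control@windows) ||
      !identical(granges(x@windows), granges(control@windows)))
    stop("sample and control tracks are on different window grids")
  new("EnrichmentTrack", windows = x@windows,
      enrichment = x@enrichment - control@enrichment,
      sampleLabel = paste0(x@sampleLabel, "-", control@sampleLabel),
      controlSubtracted = TRUE)
})

#' Call peaks from a control-subtracted enrichment track
#'
#' Windows with subtracted log2 enrichment at or above
#' \code{log2(thresholdFold)} are selected; runs of consecutive selected
#' windows are merged into one peak.  There is no gap bridging: a single
#' sub-threshold window splits a run, even though with half-overlapping
#' windows the two flanking runs still abut as intervals.  The summit is
#' the midpoint of the window with maximal enrichment (leftmost on ties).
#'
#' @param track a control-subtracted \linkS4class{EnrichmentTrack}.
#' @param thresholdFold linear fold threshold (default 2).
#' @return a \code{GRanges} of peaks with metadata columns \code{name},
#'   \code{summit} (1-based bp), \code{maxLog2Enrichment} and
#'   \code{windowCount}; empty if nothing passes.
#' @export
callPeaks <- function(track, thresholdFold = 2) {
  if (!isControlSubtracted(track))
    stop("peaks are called on control-subtracted tracks")
  keep <- which(enrichment(track) >= log2(thresholdFold))
  grid <- windows(track)
  if (length(keep) == 0L) {
    gr <- GRanges(name = character(0), summit = integer(0),
                  maxLog2Enrichment = numeric(0), windowCount = integer(0))
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(grid)
    GenomeInfoDb::seqlengths(gr) <- GenomeInfoDb::seqlengths(grid)
    return(gr)
  }
  sel <- grid[keep]
  e <- enrichment(track)[keep]
  # a run = consecutive selected window indices on one contig
  newRun <- c(TRUE, diff(keep) != 1L |
                as.character(seqnames(sel))[-1] !=
                as.character(seqnames(sel))[-length(sel)])
  runId <- cumsum(newRun)
  windowSize <- unique(width(grid))
  parts <- split(seq_along(sel), runId)
  peaks <- lapply(parts, function(i) {
    best <- i[which.max(e[i])]                # which.max: leftmost on ties
    gr <- GRanges(seqnames(sel)[i[1]],
                  IRanges(min(start(sel)[i]), max(end(sel)[i])))
    gr$summit <- as.integer(start(sel)[best] + windowSize %/% 2L)
    gr$maxLog2Enrichment <- max(e[i])
    gr$windowCount <- length(i)
    gr
  })
  merged <- sort(do.call(c, unname(peaks)))
  merged$name <- sprintf("peak_%04d", seq_along(merged))
  merged[, c("name", "summit", "maxLog2Enrichment", "windowCount")]
}

#' Peak-level log2 fold change between two enrichment tracks
#'
#' For each peak, the maximal window enrichment over the peak interval in
#' \code{trackA} minus the maximum over the same interval in \code{trackB};
#' with A = untreated and B = MMC-treated ChIP (both control-subtracted),
#' this is the reported untreated-vs-treated ChIP fold change.
#'
#' @param peaks peak \code{GRanges}.
#' @param trackA,trackB \linkS4class{EnrichmentTrack}s sharing the grid the
#'   peaks were called on.
#' @return numeric vector of log2 differences, one per peak.
#' @export
peakFoldChange <- function(peaks, trackA, trackB) {
  if (!identical(granges(windows(trackA)), granges(windows(trackB))))
    stop("tracks are on different window grids")
  maxOver <- function(track) {
    hits <- GenomicRanges::findOverlaps(peaks, windows(track))
    if (length(hits) < length(peaks))
      stop("peak interval outside the window grid")
    vapply(split(enrichment(track)[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits), seq_along(peaks))),
           max, numeric(1))
  }
  unname(maxOver(trackA) - maxOver(trackB))
}

#' One-call enrichment computation for a sample
#'
#' Convenience wrapper: window grid + window masses + local enrichment under
#' a \linkS4class{SosConfig}.
#'
#' @param cov per-base depth \code{RleList}.
#' @param genome \code{DNAStringSet} (defines contigs and lengths).
#' @param config a \linkS4class{SosConfig}.
#' @param sampleLabel label for the track.
#' @param pseudocount forwarded to \code{\link{localEnrichment}}.
#' @return an \linkS4class{EnrichmentTrack}.
#' @export
computeEnrichment <- function(cov, genome, config = sosConfig(),
                              sampleLabel = "sample", pseudocount = NULL) {
  grid <- makeWindows(genome, config@windowSize, config@windowStep)
  localEnrichment(cov, grid, flankSize = config@flankSize,
                  pseudocount = pseudocount, sampleLabel = sampleLabel)
}
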