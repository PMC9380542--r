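## Peak-to-gene association rules.
##
## A peak is assigned to the promoter of a transcriptional unit when (a) the
## unit's first gene's start codon lies within assocMaxDistance bp of the
## peak interval, and (b) the peak summit's strand-aware offset from that
## start codon falls inside the regulatory window (default -200..+100 bp).
## Offset convention: 0 = first base of the start codon, negative upstream
## on the gene's strand.  Peaks more than intragenicMinOffset bp into a gene
## body that are not part of any downstream promoter are intragenic.

#' Associate peaks with transcriptional-unit promoters
#'
#' @param peaks peak \code{GRanges} from \code{\link{callPeaks}}.
#' @param annotation annotation \code{GRanges} (see
#'   \code{\link{readAnnotation}}).
#' @param config a \linkS4class{SosConfig}.
#' @return a \code{DataFrame} with one row per (peak, unit) association:
#'   \code{peak_id}, \code{unit_id}, \code{gene_id}, \code{category}
#'   (\code{"promoter"}), \code{offset} (bp, summit relative to start
#'   codon), \code{distance} (bp, peak edge to start codon, 0 when
#'   overlapping) and \code{tss_proximal} (\code{NA}; evaluated only for
#'   intragenic sites).  A peak between two divergent units may appear
#'   twice.
#' @export
associatePromoters <- function(peaks, annotation, config = sosConfig()) {
  fg <- firstGenes(annotation)
  empty <- DataFrame(peak_id = character(0), unit_id = character(0),
                     gene_id = character(0), category = character(0),
                     offset = integer(0), distance = integer(0),
                     tss_proximal = logical(0))
  if (length(peaks) == 0L || length(fg) == 0L) return(empty)
  rows <- lapply(seq_along(peaks), function(i) {
    sameCt <- as.character(seqnames(fg)) == as.character(seqnames(peaks))[i]
    sc <- fg$startCodon
    dist <- pmax(0L, pmax(start(peaks)[i] - sc, sc - end(peaks)[i]))
    off <- summitOffset(peaks$summit[i], sc, as.character(strand(fg)))
    ok <- sameCt & dist <= config@assocMaxDistance &
      off >= config@promoterWindow[1] & off <= config@promoterWindow[2]
    if (!any(ok)) return(NULL)
    DataFrame(peak_id = peaks$name[i], unit_id = fg$unit_id[ok],
              gene_id = fg$gene_id[ok], category = "promoter",
              offset = as.integer(off[ok]), distance = as.integer(dist[ok]),
              tss_proximal = NA)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

## Strand-aware offset of a genomic position from a start codon:
## 0 = first base of the start codon, negative upstream on the gene strand.
summitOffset <- function(pos, startCodon, geneStrand) {
  ifelse(geneStrand == "+", pos - startCodon, startCodon - pos)
}

#' Classify intragenic binding sites
#'
#' A peak is intragenic for gene g when its summit lies inside g with a
#' strand-aware offset of more than \code{intragenicMinOffset} bp past the
#' start codon, and the summit is not within the promoter window of any
#' transcriptional unit's first gene (promoter assignment takes precedence).
#' A site is TSS-proximal when an annotated TSS lies within
#' \code{tssRadius} bp of the summit.
#'
#' @param peaks peak \code{GRanges}.
#' @param annotation annotation \code{GRanges}.
#' @param tssPositions optional \code{GRanges} or per-gene \code{tss}
#'   metadata column of \code{annotation} (default) giving TSS positions.
#' @param config a \linkS4class{SosConfig}.
#' @return a \code{DataFrame} with columns as in
#'   \code{\link{associatePromoters}} but \code{category}
#'   \code{"intragenic"}, \code{gene_id} the host gene, \code{offset} the
#'   summit offset into that gene, and \code{tss_proximal} evaluated
#'   (\code{NA} when no TSS data are available).
#' @export
classifyIntragenic <- function(peaks, annotation, tssPositions = NULL,
                               config = sosConfig()) {
  fg <- firstGenes(annotation)
  tss <- if (is.null(tssPositions)) {
    k <- !is.na(annotation$tss)
    if (any(k)) GRanges(seqnames(annotation)[k],
                        IRanges(annotation$tss[k], width = 1L)) else NULL
  } else tssPositions
  empty <- DataFrame(peak_id = character(0), unit_id = character(0),
                     gene_id = character(0), category = character(0),
                     offset = integer(0), distance = integer(0),
                     tss_proximal = logical(0))
  if (length(peaks) == 0L || length(annotation) == 0L) return(empty)
  rows <- lapply(seq_along(peaks), function(i) {
    s <- peaks$summit[i]
    ct <- as.character(seqnames(peaks))[i]
    ann <- annotation[as.character(seqnames(annotation)) == ct]
    if (length(ann) == 0L) return(NULL)
    off <- summitOffset(s, startCodonPos(ann), as.character(strand(ann)))
    inside <- s >= start(ann) & s <= end(ann) &
      off > config@intragenicMinOffset
    if (!any(inside)) return(NULL)
    # promoter precedence: summit inside any first gene's regulatory window?
    fgc <- fg[as.character(seqnames(fg)) == ct]
    if (length(fgc)) {
      pOff <- summitOffset(s, fgc$startCodon, as.character(strand(fgc)))
      if (any(pOff >= config@promoterWindow[1] &
              pOff <= config@promoterWindow[2]))
        return(NULL)
    }
    prox <- NA
    if (!is.null(tss)) {
      tc <- tss[as.character(seqnames(tss)) == ct]
      prox <- length(tc) > 0 && any(abs(start(tc) - s) <= config@tssRadius)
    }
    DataFrame(peak_id = peaks$name[i], unit_id = ann$unit_id[inside],
              gene_id = ann$gene_id[inside], category = "intragenic",
              offset = as.integer(off[inside]),
              distance = 0L, tss_proximal = prox)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Associate every peak (promoter rules first, then intragenic)
#'
#' @inheritParams classifyIntragenic
#' @return a \code{DataFrame} combining \code{\link{associatePromoters}}
#'   and \code{\link{classifyIntragenic}} rows; peaks matching neither rule
#'   are absent.
#' @export
associatePeaks <- function(peaks, annotation, tssPositions = NULL,
                           config = sosConfig()) {
  rbind(associatePromoters(peaks, annotation, config),
        classifyIntragenic(peaks, annotation, tssPositions, config))
}
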