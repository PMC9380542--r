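## Regulon integration: join promoter associations with DEG calls and
## classify each binding site's dissociation response to DNA damage.

#' Build the regulon table
#'
#' One entry per (peak, unit) promoter association whose transcriptional
#' unit is differentially expressed; the unit's expression is read from its
#' first gene (the gene whose promoter carries the site).  Units missing
#' from the DE table are skipped with a warning.
#'
#' @param associations promoter-category \code{DataFrame} from
#'   \code{\link{associatePromoters}}.
#' @param deResults \code{DataFrame} from \code{\link{runDE}}.
#' @return a \code{DataFrame}: \code{peak_id}, \code{unit_id},
#'   \code{gene_id}, \code{direction} (\code{"up"}/\code{"down"}),
#'   \code{rnaseq_log2FC}, \code{fdr}.
#' @export
buildRegulon <- function(associations, deResults) {
  associations <- associations[associations$category == "promoter", ,
                               drop = FALSE]
  idx <- match(associations$gene_id, deResults$gene)
  if (any(is.na(idx))) {
    warning("units missing from the DE table were skipped: ",
            paste(unique(associations$gene_id[is.na(idx)]), collapse = ", "))
    associations <- associations[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  keep <- deResults$is_deg[idx]
  associations <- associations[keep, , drop = FALSE]
  idx <- idx[keep]
  DataFrame(peak_id = associations$peak_id,
            unit_id = associations$unit_id,
            gene_id = associations$gene_id,
            direction = ifelse(deResults$log2FC[idx] > 0, "up", "down"),
            rnaseq_log2FC = deResults$log2FC[idx],
            fdr = deResults$fdr[idx])
}

#' Classify a binding site's dissociation response to DNA damage
#'
#' Three-way classification of a peak's behaviour under MMC treatment from
#' two peak-level log2 enrichment comparisons: (i) \emph{complete}
#' dissociation when the treated-vs-control enrichment falls below the
#' complete cutoff (default 0.25); otherwise (ii) \emph{none} when the
#' enrichment drop from untreated to treated is at most the none cutoff
#' (default 0.2); otherwise (iii) \emph{partial}.  Boundary values resolve
#' to the less-dissociated class (none over partial over complete).
#'
#' @param eTreatedVsCtrl log2 enrichment of the treated ChIP over its
#'   control at the peak (\code{\link{peakFoldChange}}).
#' @param drop log2 enrichment drop, untreated minus treated ChIP.
#' @param config a \linkS4class{SosConfig} supplying the cutoffs.
#' @return character vector over \code{"complete"}, \code{"partial"},
#'   \code{"none"}; the three predicates are exhaustive and mutually
#'   exclusive.
#' @export
classifyDissociation <- function(eTreatedVsCtrl, drop,
                                 config = sosConfig()) {
  if (any(!is.finite(eTreatedVsCtrl)) || any(!is.finite(drop)))
    stop("enrichment comparisons must be finite")
  ifelse(eTreatedVsCtrl < config@dissocCompleteCutoff, "complete",
         ifelse(drop <= config@dissocNoneCutoff, "none", "partial"))
}

#' Summarise a regulon table
#'
#' @param entries regulon \code{DataFrame}, optionally carrying a
#'   \code{dissociation_class} column.
#' @return named integer vector with totals, DEG directions and (when
#'   available) dissociation classes.
#' @export
summarizeRegulon <- function(entries) {
  out <- c(total = nrow(entries),
           up = sum(entries$direction == "up"),
           down = sum(entries$direction == "down"))
  if (!is.null(entries$dissociation_class))
    out <- c(out,
             complete = sum(entries$dissociation_class == "complete"),
             partial = sum(entries$dissociation_class == "partial"),
             none = sum(entries$dissociation_class == "none"))
  out
}

#' Integrate peaks, expression and dissociation into the regulon table
#'
#' Convenience wrapper over \code{\link{buildRegulon}},
#' \code{\link{peakFoldChange}} and \code{\link{classifyDissociation}}:
#' given the peaks called on untreated data, their promoter associations, DE
#' results, and the four enrichment tracks of the +/-MMC design, it returns
#' the regulon table with the dissociation class of every entry.
#'
#' @param peaks peak \code{GRanges} (untreated ChIP vs control).
#' @param associations promoter associations for these peaks.
#' @param deResults \code{DataFrame} from \code{\link{runDE}}.
#' @param trackUntreated,trackTreated control-subtracted
#'   \linkS4class{EnrichmentTrack}s of the untreated and MMC-treated ChIP.
#' @param config a \linkS4class{SosConfig}.
#' @return the \code{\link{buildRegulon}} table plus
#'   \code{chip_fc_untreated_vs_treated} and \code{dissociation_class}.
#' @export
integrateRegulon <- function(peaks, associations, deResults,
                             trackUntreated, trackTreated,
                             config = sosConfig()) {
  reg <- buildRegulon(associations, deResults)
  idx <- match(reg$peak_id, peaks$name)
  if (any(is.na(idx))) stop("regulon entry refers to an unknown peak")
  sub <- peaks[idx]
  drop <- peakFoldChange(sub, trackUntreated, trackTreated)
  # treated-vs-control enrichment: the treated track is already
  # control-subtracted, so its peak maximum is the comparison itself
  hits <- GenomicRanges::findOverlaps(sub, windows(trackTreated))
  eTr <- vapply(split(enrichment(trackTreated)[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits), seq_along(sub))),
                max, numeric(1))
  reg$chip_fc_untreated_vs_treated <- drop
  reg$dissociation_class <- classifyDissociation(unname(eTr), drop, config)
  reg
}
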