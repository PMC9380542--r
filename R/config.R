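#' Build a pipeline configuration
#'
#' @param windowSize,windowStep,flankSize window grid and local-background
#'   geometry in bp.
#' @param enrichmentThreshold linear fold-enrichment threshold for peak
#'   calling.
#' @param assocMaxDistance,promoterWindow,intragenicMinOffset,tssRadius
#'   peak-to-gene association geometry in bp.
#' @param deLfcCutoff,deFdrCutoff DEG cutoffs.
#' @param dissocCompleteCutoff,dissocNoneCutoff log2 cutoffs of the
#'   three-way dissociation classification.
#' @param motifSeqLength length of summit-centred sequences for motif
#'   discovery.
#' @param rngSeed integer seed recorded with simulations.
#' @return a validated \linkS4class{SosConfig}.
#' @examples
#' cfg <- sosConfig()
#' cfg@windowSize
#' @export
sosConfig <- function(windowSize = 30, windowStep = 15, flankSize = 3000,
                      enrichmentThreshold = 2, assocMaxDistance = 300,
                      promoterWindow = c(-200, 100),
                      intragenicMinOffset = 100, tssRadius = 50,
                      deLfcCutoff = 1, deFdrCutoff = 0.05,
                      dissocCompleteCutoff = 0.25, dissocNoneCutoff = 0.2,
                      motifSeqLength = 100, rngSeed = 1) {
  new("SosConfig",
      windowSize = as.integer(windowSize),
      windowStep = as.integer(windowStep),
      flankSize = as.integer(flankSize),
      enrichmentThreshold = as.numeric(enrichmentThreshold),
      assocMaxDistance = as.integer(assocMaxDistance),
      promoterWindow = as.integer(promoterWindow),
      intragenicMinOffset = as.integer(intragenicMinOffset),
      tssRadius = as.integer(tssRadius),
      deLfcCutoff = as.numeric(deLfcCutoff),
      deFdrCutoff = as.numeric(deFdrCutoff),
      dissocCompleteCutoff = as.numeric(dissocCompleteCutoff),
      dissocNoneCutoff = as.numeric(dissocNoneCutoff),
      motifSeqLength = as.integer(motifSeqLength),
      rngSeed = as.integer(rngSeed))
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys are the \code{\link{sosConfig}} argument names; missing keys keep
#' their defaults, unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return a validated \linkS4class{SosConfig}.
#' @export
readSosConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sosConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(sosConfig, vals)
}

setMethod("show", "SosConfig", function(object) {
  cat("SosConfig\n")
  cat(sprintf("  windows: %d bp, step %d bp, flank %d bp\n",
              object@windowSize, object@windowStep, object@flankSize))
  cat(sprintf("  peak threshold: %g-fold; association: <=%d bp, window [%d, %d]\n",
              object@enrichmentThreshold, object@assocMaxDistance,
              object@promoterWindow[1], object@promoterWindow[2]))
  cat(sprintf("  DEG: |log2FC| >= %g, FDR <= %g\n",
              object@deLfcCutoff, object@deFdrCutoff))
  cat(sprintf("  dissociation cutoffs (log2): complete < %g, none drop < %g\n",
              object@dissocCompleteCutoff, object@dissocNoneCutoff))
})
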