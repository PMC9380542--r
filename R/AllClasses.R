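#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- Rle
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   strand<-
#' @importFrom IRanges IRanges Views viewSums coverage
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   readDNAStringSet writeXStringSet letterFrequency subseq subseq<-
#' @importFrom stats rpois rnbinom rnorm runif median var quantile setNames
#'   pt p.adjust optim sd mad complete.cases
#' @importFrom utils write.table read.delim head tail
NULL

#' Pipeline configuration
#'
#' Container for every tunable threshold of the SOS-regulon pipeline, so that
#' no stage hard-codes a cutoff.  Defaults follow the published analysis of
#' the \emph{S. venezuelae} LexA regulon: 30-nt genome sections overlapping by
#' 15 nt, local enrichment against the 3,000 nt around each section, a
#' 2-fold enrichment threshold, promoter association within 300 nt and a
#' regulatory window of -200..+100 bp around the start codon, intragenic
#' sites more than 100 bp into a gene, DEG cutoffs |log2FC| >= 1 and
#' FDR <= 0.05, dissociation cutoffs 0.25/0.2 (log2), and 100-nt summit
#' sequences for motif discovery.
#'
#' @slot windowSize integer, genome section width in bp.
#' @slot windowStep integer, step between section starts in bp.
#' @slot flankSize integer, total span (bp) of the local background region
#'   centred on a section; the section itself is excluded from the flank.
#' @slot enrichmentThreshold numeric, linear fold enrichment required to
#'   call a window enriched.
#' @slot assocMaxDistance integer, maximum distance (bp) between a peak and a
#'   start codon for promoter association.
#' @slot promoterWindow integer(2), strand-aware offsets (bp) around the start
#'   codon that count as regulatory region.
#' @slot intragenicMinOffset integer, minimum offset (bp) into a gene for an
#'   intragenic site.
#' @slot tssRadius integer, distance (bp) within which a summit counts as
#'   TSS-proximal.
#' @slot deLfcCutoff numeric, |log2FC| cutoff for DEG calls.
#' @slot deFdrCutoff numeric, FDR cutoff for DEG calls.
#' @slot dissocCompleteCutoff numeric (log2), treated-vs-control enrichment
#'   below which dissociation is complete.
#' @slot dissocNoneCutoff numeric (log2), untreated-minus-treated drop below
#'   which no dissociation is called.
#' @slot motifSeqLength integer, length (bp) of summit-centred sequences fed
#'   to motif discovery.
#' @slot rngSeed integer, seed recorded with simulated fixtures.
#' @export
setClass("SosConfig", representation(
    windowSize = "integer", windowStep = "integer", flankSize = "integer",
    enrichmentThreshold = "numeric", assocMaxDistance = "integer",
    promoterWindow = "integer", intragenicMinOffset = "integer",
    tssRadius = "integer", deLfcCutoff = "numeric", deFdrCutoff = "numeric",
    dissocCompleteCutoff = "numeric", dissocNoneCutoff = "numeric",
    motifSeqLength = "integer", rngSeed = "integer"),
  prototype(
    windowSize = 30L, windowStep = 15L, flankSize = 3000L,
    enrichmentThreshold = 2, assocMaxDistance = 300L,
    promoterWindow = c(-200L, 100L), intragenicMinOffset = 100L,
    tssRadius = 50L, deLfcCutoff = 1, deFdrCutoff = 0.05,
    dissocCompleteCutoff = 0.25, dissocNoneCutoff = 0.2,
    motifSeqLength = 100L, rngSeed = 1L))

setValidity("SosConfig", function(object) {
  msg <- character()
  pos <- c(windowSize = object@windowSize, windowStep = object@windowStep,
           flankSize = object@flankSize,
           assocMaxDistance = object@assocMaxDistance,
           intragenicMinOffset = object@intragenicMinOffset,
           tssRadius = object@tssRadius, motifSeqLength = object@motifSeqLength)
  if (any(pos <= 0))
    msg <- c(msg, paste("sizes must be positive:",
                        paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@windowStep > object@windowSize)
    msg <- c(msg, "windowStep must be <= windowSize")
  if (object@flankSize <= object@windowSize)
    msg <- c(msg, "flankSize must exceed windowSize")
  if (object@deFdrCutoff <= 0 || object@deFdrCutoff >= 1)
    msg <- c(msg, "deFdrCutoff must lie in (0, 1)")
  if (object@enrichmentThreshold <= 0)
    msg <- c(msg, "enrichmentThreshold must be positive")
  if (length(object@promoterWindow) != 2L ||
      object@promoterWindow[1] > object@promoterWindow[2])
    msg <- c(msg, "promoterWindow must be two ordered offsets")
  if (length(msg)) msg else TRUE
})

#' Per-window local enrichment along a genome
#'
#' Holds the sliding-window grid together with one log2 local-enrichment
#' value per window, for one ChIP or control sample (or, after
#' \code{\link{subtractControl}}, for a sample-minus-control comparison).
#'
#' @slot windows \code{GRanges} of the window grid (1-based, closed).
#' @slot enrichment numeric, log2 local enrichment per window.
#' @slot sampleLabel character scalar naming the sample.
#' @slot controlSubtracted logical, whether a control track has been
#'   subtracted.
#' @export
setClass("EnrichmentTrack", representation(
    windows = "GRanges", enrichment = "numeric", sampleLabel = "character",
    controlSubtracted = "logical"))

setValidity("EnrichmentTrack", function(object) {
  msg <- character()
  if (length(object@windows) != length(object@enrichment))
    msg <- c(msg, "one enrichment value per window required")
  if (any(!is.finite(object@enrichment)))
    msg <- c(msg, "enrichment values must be finite")
  if (length(object@sampleLabel) != 1L)
    msg <- c(msg, "sampleLabel must be a single string")
  if (length(object@controlSubtracted) != 1L)
    msg <- c(msg, "controlSubtracted must be a single flag")
  if (length(msg)) msg else TRUE
})

#' Position-weight-matrix motif model
#'
#' Result of ZOOPS (zero-or-one-occurrence-per-sequence) EM motif discovery:
#' a PWM with its background model, mixed-case consensus (uppercase =
#' strongly conserved, lowercase = partially conserved, N = uninformative),
#' the fitted per-sequence occurrence prior, and likelihood bookkeeping used
#' for width selection.
#'
#' @slot width integer, motif width in bp.
#' @slot pwm 4 x width matrix of per-position base probabilities
#'   (rows A, C, G, T; columns sum to 1).
#' @slot background named numeric(4) of background base frequencies.
#' @slot consensus character, mixed-case consensus string.
#' @slot occurrencePrior numeric, fitted probability that a sequence carries
#'   a site.
#' @slot logLik numeric, observed-data log-likelihood of the fitted model.
#' @slot logLikRatio numeric, log-likelihood ratio against the pure
#'   background model.
#' @slot score numeric, BIC-penalised log-likelihood ratio used to select
#'   the width.
#' @slot nSeq integer, number of training sequences.
#' @slot llHistory numeric, penalised observed-data log-likelihood
#'   (likelihood plus Dirichlet column prior, the objective MAP-EM is
#'   guaranteed not to decrease) after each iteration of the winning run.
#' @export
setClass("MotifModel", representation(
    width = "integer", pwm = "matrix", background = "numeric",
    consensus = "character", occurrencePrior = "numeric", logLik = "numeric",
    logLikRatio = "numeric", score = "numeric", nSeq = "integer",
    llHistory = "numeric"))

setValidity("MotifModel", function(object) {
  msg <- character()
  if (nrow(object@pwm) != 4L || ncol(object@pwm) != object@width)
    msg <- c(msg, "pwm must be a 4 x width matrix")
  else if (any(abs(colSums(object@pwm) - 1) > 1e-9))
    msg <- c(msg, "pwm columns must each sum to 1")
  if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  if (nchar(object@consensus) != object@width)
    msg <- c(msg, "consensus length must equal width")
  if (length(msg)) msg else TRUE
})

#' Single-cycle SPR sensorgram
#'
#' A stepped-concentration (single-cycle kinetics) surface plasmon resonance
#' time course: consecutive analyte injections at increasing concentrations
#' followed by a terminal buffer-only dissociation segment, sampled as
#' response units over time.
#'
#' @slot time numeric, sampling times in seconds (strictly increasing,
#'   starting at 0).
#' @slot response numeric, response units at each sampling time.
#' @slot segments data.frame with columns \code{start} (s), \code{duration}
#'   (s) and \code{concentration} (molar; 0 marks a dissociation segment).
#' @export
setClass("Sensorgram", representation(
    time = "numeric", response = "numeric", segments = "data.frame"))

setValidity("Sensorgram", function(object) {
  msg <- character()
  if (length(object@time) != length(object@response))
    msg <- c(msg, "time and response must have equal length")
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (!all(c("start", "duration", "concentration") %in%
           names(object@segments)))
    msg <- c(msg, "segments needs columns start, duration, concentration")
  else {
    if (any(object@segments$duration <= 0))
      msg <- c(msg, "segment durations must be positive")
    if (any(object@segments$concentration < 0))
      msg <- c(msg, "concentrations must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted 1:1 Langmuir binding kinetics
#'
#' Result of least-squares fitting of the 1:1 interaction model to a
#' single-cycle sensorgram.  The equilibrium dissociation constant is always
#' the derived quantity KD = kd/ka, never independently fitted.
#'
#' @slot ka numeric, association rate constant, 1/(M s).
#' @slot kd numeric, dissociation rate constant, 1/s.
#' @slot rmax numeric, fitted maximal response, RU.
#' @slot residualRmse numeric, root-mean-square residual, RU.
#' @slot converged logical, optimiser convergence flag.
#' @slot nStarts integer, number of multi-start initialisations tried.
#' @export
setClass("KineticFit", representation(
    ka = "numeric", kd = "numeric", rmax = "numeric",
    residualRmse = "numeric", converged = "logical", nStarts = "integer"))

setValidity("KineticFit", function(object) {
  msg <- character()
  if (object@ka <= 0 || object@kd <= 0 || object@rmax <= 0)
    msg <- c(msg, "ka, kd and rmax must be positive")
  if (length(msg)) msg else TRUE
})
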