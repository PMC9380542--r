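## Synthetic-data generators with recorded ground truth.
##
## These emulate the study conditions a desk-scale re-analysis needs: a
## small high-GC linear genome with planted 16-bp SOS boxes of varying
## occupancy, matched ChIP/control coverage with and without DNA damage,
## NB-distributed count matrices with planted log2 fold changes, and noisy
## stepped-concentration sensorgrams.  Coverage is simulated as per-base
## Poisson depth rather than individual reads: the enrichment statistic
## only consumes densities.

#' Generate a random genome
#'
#' I.i.d. bases with P(G) + P(C) = \code{gc}; reproducible under
#' \code{seed}.
#'
#' @param lengths named integer vector of contig lengths (bp).
#' @param gc GC proportion in (0, 1); default 0.72, typical of
#'   \emph{Streptomyces}.
#' @param seed optional integer seed.
#' @return a \code{DNAStringSet}.
#' @export
generateGenome <- function(lengths = c(chr = 100000L), gc = 0.72,
                           seed = NULL) {
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly in (0, 1)")
  if (is.null(names(lengths)))
    names(lengths) <- paste0("contig", seq_along(lengths))
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(lengths, function(L)
    paste(sample(BASES, L, replace = TRUE, prob = p), collapse = ""),
    character(1))
  checkGenome(DNAStringSet(seqs))
}

#' Generate a random gene annotation
#'
#' Places non-overlapping genes with random strands along each contig, then
#' groups a fraction of them into 2-4-gene same-strand operons
#' (transcriptional units); the first gene of every unit gets a TSS at its
#' start codon.
#'
#' @param genome a \code{DNAStringSet}.
#' @param nGenes number of genes.
#' @param operonFraction fraction of genes belonging to multi-gene operons.
#' @param geneLength integer(2), uniform range of gene lengths (bp).
#' @param minGap minimum intergenic gap (bp); kept large enough by default
#'   for a -200..+100 regulatory window to fit.
#' @param seed optional integer seed.
#' @return an annotation \code{GRanges} (columns \code{gene_id},
#'   \code{unit_id}, \code{tss}).
#' @export
generateAnnotation <- function(genome, nGenes = 60, operonFraction = 0.3,
                               geneLength = c(500, 1500), minGap = 450,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- setNames(width(genome), names(genome))
  perContig <- table(factor(sample(names(lens), nGenes, replace = TRUE,
                                   prob = lens / sum(lens)),
                            levels = names(lens)))
  grs <- list()
  gid <- 0L
  for (ct in names(lens)) {
    n <- perContig[[ct]]
    if (n == 0L) next
    for (attempt in 1:50) {
      gl <- sample(geneLength[1]:geneLength[2], n, replace = TRUE)
      need <- sum(gl) + (n + 1L) * minGap
      if (need <= lens[[ct]]) break
      if (attempt == 50) stop("cannot place ", n, " genes on ", ct)
      n <- max(1L, n - 1L)
    }
    slack <- lens[[ct]] - sum(gl) - (n + 1L) * minGap
    extra <- floor(diff(c(0, sort(runif(n, 0, slack)))))
    starts <- as.integer(cumsum(c(1 + minGap + extra[1],
                                  head(gl, -1) + minGap + extra[-1])))
    grs[[ct]] <- GRanges(ct, IRanges(starts, width = gl),
                         strand = sample(c("+", "-"), n, replace = TRUE))
  }
  ann <- do.call(c, unname(grs))
  ann$gene_id <- sprintf("gene_%04d", seq_along(ann))
  ann$unit_id <- ann$gene_id
  # group runs of consecutive genes into same-strand operons
  i <- 1L
  while (i <= length(ann)) {
    if (runif(1) < operonFraction && i < length(ann)) {
      size <- min(sample(2:4, 1), length(ann) - i + 1L)
      idx <- i:(i + size - 1L)
      idx <- idx[as.character(seqnames(ann))[idx] ==
                   as.character(seqnames(ann))[i]]
      strand(ann)[idx] <- as.character(strand(ann))[idx[1]]
      ann$unit_id[idx] <- paste0("unit_", ann$gene_id[idx[1]])
      i <- i + length(idx)
    } else i <- i + 1L
  }
  fg <- firstGenes(ann)
  ann$tss <- fg$startCodon[match(ann$unit_id, fg$unit_id)]
  ann$tss[!(ann$gene_id %in% fg$gene_id)] <- NA_integer_
  checkAnnotation(ann, genome)
}

#' Plant SOS-box motif instances into a genome
#'
#' Overwrites the genome sequence with concrete instances of a consensus
#' (Ns sampled uniformly, optional mismatches) at promoter offsets drawn
#' from the regulatory window of randomly chosen transcriptional units, and
#' optionally deeper inside gene bodies.  The returned truth records exact
#' positions, strands, occupancies and the intended dissociation class of
#' every site.  Offset convention: 0 = first base of the start codon,
#' negative upstream on the gene's strand; the recorded offset is that of
#' the box's first base in gene orientation.
#'
#' @param genome a \code{DNAStringSet}.
#' @param annotation annotation \code{GRanges}.
#' @param consensus motif string with N wildcards (default the 16-bp SOS
#'   box \code{"TCGAACNNNNGNNCGA"}).
#' @param nPromoter,nIntragenic numbers of promoter and intragenic sites.
#' @param classes dissociation classes recycled over sites (default an even
#'   mix of complete/partial/none).  Occupancies: untreated
#'   \code{occupancyUntreated} everywhere; treated 1 (background) for
#'   complete, half for partial, unchanged for none — margins that
#'   guarantee the intended class.
#' @param occupancyUntreated linear fold-occupancy of untreated sites
#'   (default 8).
#' @param mismatches number of mismatched positions per planted instance
#'   (0-2, default 0).
#' @param offsets optional integer vector of promoter offsets (recycled).
#'   By default offsets are drawn uniformly from -150..-20, the typical
#'   placement of a repressor operator in the upstream part of the
#'   regulatory window: a box planted flush against a window boundary is
#'   not recoverable by summit-offset rules, because under a flat
#'   fragment-length enrichment plateau the called summit is only
#'   localised to about half a fragment length.
#' @param config a \linkS4class{SosConfig}.
#' @param seed optional integer seed.
#' @return a list with elements \code{genome} (modified) and \code{truth}:
#'   a list with \code{sites} (a \code{DataFrame}), \code{consensus} and
#'   \code{de_genes} (empty; filled by
#'   \code{\link{simulateSosExperiment}}).
#' @export
plantSites <- function(genome, annotation,
                       consensus = "TCGAACNNNNGNNCGA",
                       nPromoter = 30, nIntragenic = 0,
                       classes = c("complete", "partial", "none"),
                       occupancyUntreated = 8, mismatches = 0,
                       offsets = NULL, config = sosConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- nchar(consensus)
  fg <- firstGenes(annotation)
  if (nPromoter > length(fg))
    stop("more promoter sites requested than transcriptional units")
  classes <- rep_len(classes, nPromoter + nIntragenic)
  occT <- function(cl) switch(cl, complete = 1,
                              partial = occupancyUntreated / 2,
                              none = occupancyUntreated,
                              stop("unknown class: ", cl))
  used <- GRanges()
  rows <- list()
  seqChars <- setNames(as.character(genome), names(genome))

  placeInstance <- function(ct, fstart, geneStrand) {
    inst <- strsplit(consensus, "")[[1]]
    inst[inst == "N"] <- sample(BASES, sum(inst == "N"), replace = TRUE)
    if (mismatches > 0) {
      pos <- sample(w, min(mismatches, w))
      for (p in pos) inst[p] <- sample(setdiff(BASES, inst[p]), 1)
    }
    fwd <- paste(inst, collapse = "")
    if (geneStrand == "-")
      fwd <- as.character(reverseComplement(DNAString(fwd)))
    substr(seqChars[[ct]], fstart, fstart + w - 1L) <<- fwd
    paste(inst, collapse = "")
  }

  # promoter sites
  unitPick <- sample(seq_along(fg), nPromoter)
  for (k in seq_len(nPromoter)) {
    u <- fg[unitPick[k]]
    ct <- as.character(seqnames(u))
    gs <- as.character(strand(u))
    ok <- FALSE
    for (try in 1:50) {
      off <- if (!is.null(offsets)) offsets[(k - 1) %% length(offsets) + 1]
        else sample(max(-150L, config@promoterWindow[1]):
                      min(-20L, config@promoterWindow[2]), 1)
      fstart <- if (gs == "+") u$startCodon + off
        else u$startCodon - off - w + 1L
      if (fstart < 1L || fstart + w - 1L > width(genome)[[match(ct, names(genome))]])
        next
      cand <- GRanges(ct, IRanges(fstart, fstart + w - 1L))
      if (length(GenomicRanges::findOverlaps(cand, used)) == 0L) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place promoter site without collision")
    used <- c(used, cand)
    inst <- placeInstance(ct, fstart, gs)
    rows[[length(rows) + 1L]] <- DataFrame(
      contig = ct, position = fstart, strand = gs,
      occupancy_untreated = occupancyUntreated,
      occupancy_treated = occT(classes[k]), category = "promoter",
      target_unit = u$unit_id, target_gene = u$gene_id,
      true_class = classes[k], offset = as.integer(off), instance = inst)
  }

  # intragenic sites
  if (nIntragenic > 0) {
    wide <- annotation[width(annotation) >
                         config@intragenicMinOffset + w + 150L]
    genePick <- sample(seq_along(wide), nIntragenic)
    for (k in seq_len(nIntragenic)) {
      g <- wide[genePick[k]]
      ct <- as.character(seqnames(g))
      gs <- as.character(strand(g))
      ok <- FALSE
      for (try in 1:50) {
        off <- sample((config@intragenicMinOffset + 50L):
                        (width(g) - w - 50L), 1)
        fstart <- if (gs == "+") startCodonPos(g) + off
          else startCodonPos(g) - off - w + 1L
        cand <- GRanges(ct, IRanges(fstart, fstart + w - 1L))
        if (length(GenomicRanges::findOverlaps(cand, used)) == 0L) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place intragenic site without collision")
      used <- c(used, cand)
      cl <- classes[nPromoter + k]
      inst <- placeInstance(ct, fstart, gs)
      rows[[length(rows) + 1L]] <- DataFrame(
        contig = ct, position = fstart, strand = gs,
        occupancy_untreated = occupancyUntreated,
        occupancy_treated = occT(cl), category = "intragenic",
        target_unit = g$unit_id, target_gene = g$gene_id,
        true_class = cl, offset = as.integer(off), instance = inst)
    }
  }
  truth <- list(sites = do.call(rbind, rows), consensus = consensus,
                de_genes = setNames(numeric(0), character(0)),
                kinetics = list())
  list(genome = DNAStringSet(seqChars), truth = truth)
}

#' Simulate a ChIP or control coverage track
#'
#' Per-base Poisson depth with mean \code{backgroundDepth}; over a
#' \code{fragmentLen} window centred on each planted site the mean is
#' multiplied by the site's occupancy under the given condition.  Control
#' tracks ignore occupancies entirely.
#'
#' @param genome a \code{DNAStringSet}.
#' @param truth truth list from \code{\link{plantSites}}.
#' @param backgroundDepth mean per-base depth away from sites (default 20).
#' @param fragmentLen enriched window width (bp, default 200).
#' @param condition \code{"untreated"} or \code{"MMC"}.
#' @param control logical; a control (no-antibody/wild-type) track.
#' @param seed optional integer seed.
#' @return an \code{RleList} of per-base depth.
#' @export
simulateChipCoverage <- function(genome, truth, backgroundDepth = 20,
                                 fragmentLen = 200,
                                 condition = c("untreated", "MMC"),
                                 control = FALSE, seed = NULL) {
  condition <- match.arg(condition)
  if (backgroundDepth <= 0 || fragmentLen <= 0)
    stop("backgroundDepth and fragmentLen must be positive")
  if (!is.null(seed)) set.seed(seed)
  w <- nchar(truth$consensus)
  lam <- lapply(setNames(width(genome), names(genome)),
                function(L) rep(backgroundDepth, L))
  if (!control && !is.null(truth$sites) && nrow(truth$sites) > 0) {
    occCol <- if (condition == "untreated") "occupancy_untreated"
      else "occupancy_treated"
    for (i in seq_len(nrow(truth$sites))) {
      s <- truth$sites[i, ]
      mid <- s$position + w %/% 2L
      a <- max(1L, mid - fragmentLen %/% 2L)
      b <- min(length(lam[[s$contig]]), mid + fragmentLen %/% 2L - 1L)
      lam[[s$contig]][a:b] <- pmax(lam[[s$contig]][a:b],
                                   backgroundDepth * s[[occCol]])
    }
  }
  methods::as(lapply(lam, function(v) Rle(rpois(length(v), v))),
              "SimpleRleList")
}

#' Simulate an NB count matrix with planted fold changes
#'
#' Counts ~ NB(mean = baseMean x libFactor x 2^log2FC[treated],
#' dispersion); genes absent from \code{log2FC} are unchanged.
#'
#' @param annotation annotation \code{GRanges} (one count row per gene).
#' @param log2FC named numeric of true log2 fold changes (treated over
#'   untreated).
#' @param nReps replicates per condition (default 3, the triplicate
#'   design).
#' @param meanRange range of log-uniform base means (default 50-2000).
#' @param dispersion NB dispersion (must be positive; default 0.1).
#' @param libSizeFactors per-sample library factors (default all 1).
#' @param seed optional integer seed.
#' @return a \code{SummarizedExperiment} with a \code{counts} assay,
#'   \code{condition} in \code{colData} (untreated, treated) and
#'   \code{trueLog2FC} in \code{rowData}.
#' @export
simulateCounts <- function(annotation, log2FC = numeric(0), nReps = 3,
                           meanRange = c(50, 2000), dispersion = 0.1,
                           libSizeFactors = NULL, seed = NULL) {
  if (dispersion <= 0) stop("dispersion must be positive")
  if (!is.null(seed)) set.seed(seed)
  genes <- annotation$gene_id
  nS <- 2L * nReps
  if (is.null(libSizeFactors)) libSizeFactors <- rep(1, nS)
  baseMean <- exp(runif(length(genes), log(meanRange[1]), log(meanRange[2])))
  lfc <- setNames(rep(0, length(genes)), genes)
  lfc[names(log2FC)[names(log2FC) %in% genes]] <-
    log2FC[names(log2FC) %in% genes]
  condition <- factor(rep(c("untreated", "treated"), each = nReps),
                      levels = c("untreated", "treated"))
  mu <- outer(baseMean, libSizeFactors) *
    2^outer(lfc, as.numeric(condition == "treated"))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = length(genes),
                   dimnames = list(genes,
                                   paste0(condition, "_", rep(1:nReps, 2))))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(condition = condition),
    rowData = DataFrame(trueLog2FC = unname(lfc), baseMean = baseMean))
}

#' Simulate summit sequences carrying one planted motif instance each
#'
#' Emulates the summit-centred sequence set used for motif discovery: i.i.d.
#' background of the given GC content with exactly one instance of the
#' consensus planted per sequence at a uniform random position and strand
#' (Ns sampled uniformly, plus 0..\code{mismatchMax} random mismatches).
#'
#' @param n number of sequences (default 175).
#' @param length sequence length in bp (default 100).
#' @param consensus motif string with N wildcards.
#' @param gc background GC proportion (default 0.72).
#' @param mismatchMax per-instance mismatch count is drawn uniformly from
#'   0..\code{mismatchMax} (default 1).
#' @param seed optional integer seed.
#' @return a list: \code{seqs} (a \code{DNAStringSet}) and \code{sites}
#'   (a \code{DataFrame} of planted positions, strands and instances).
#' @export
simulateSummitSequences <- function(n = 175, length = 100,
                                    consensus = "TCGAACNNNNGNNCGA",
                                    gc = 0.72, mismatchMax = 1,
                                    seed = NULL) {
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  w <- nchar(consensus)
  if (length < w) stop("sequences must be longer than the consensus")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  out <- character(n)
  pos <- integer(n); std <- character(n); instc <- character(n)
  for (i in seq_len(n)) {
    s <- sample(BASES, length, replace = TRUE, prob = p)
    inst <- strsplit(consensus, "")[[1]]
    inst[inst == "N"] <- sample(BASES, sum(inst == "N"), replace = TRUE)
    nmm <- sample.int(mismatchMax + 1L, 1) - 1L
    if (nmm > 0) {
      at <- sample(w, nmm)
      for (j in at) inst[j] <- sample(setdiff(BASES, inst[j]), 1)
    }
    instc[i] <- paste(inst, collapse = "")
    std[i] <- sample(c("+", "-"), 1)
    if (std[i] == "-")
      inst <- strsplit(as.character(reverseComplement(
        DNAString(instc[i]))), "")[[1]]
    pos[i] <- sample.int(length - w + 1L, 1)
    s[pos[i]:(pos[i] + w - 1L)] <- inst
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- sprintf("seq_%03d", seq_len(n))
  list(seqs = DNAStringSet(out),
       sites = DataFrame(sequence_id = names(out), position = pos,
                         strand = std, instance = instc))
}

#' Simulate a single-cycle SPR sensorgram
#'
#' Stepped injections of increasing analyte concentration followed by one
#' terminal dissociation segment, from the closed-form 1:1 model plus
#' i.i.d. Gaussian noise.  The default series is the published doubling
#' series 0.78125-25 nM, 120 s per step, with 1200 s of dissociation.
#'
#' @param ka,kd,rmax true kinetic parameters (see
#'   \code{\link{modelResponse}}).
#' @param concentrations molar analyte concentrations, one per step.
#' @param stepDuration injection duration (s).
#' @param dissocDuration terminal buffer segment duration (s).
#' @param noiseSd Gaussian noise standard deviation (RU; 0 = noiseless).
#' @param samplingHz sampling rate (default 1 Hz).
#' @param seed optional integer seed.
#' @return a \linkS4class{Sensorgram}.
#' @export
simulateSensorgram <- function(ka, kd, rmax,
                               concentrations = 0.78125e-9 * 2^(0:5),
                               stepDuration = 120, dissocDuration = 1200,
                               noiseSd = 0, samplingHz = 1, seed = NULL) {
  if (ka <= 0 || kd < 0 || rmax <= 0)
    stop("rate constants and rmax must be positive")
  if (!is.null(seed)) set.seed(seed)
  seg <- data.frame(
    start = c(0, cumsum(rep(stepDuration, length(concentrations)))),
    duration = c(rep(stepDuration, length(concentrations)), dissocDuration),
    concentration = c(concentrations, 0))
  total <- sum(seg$duration)
  times <- seq(0, total, by = 1 / samplingHz)
  resp <- modelResponse(seg, ka, kd, rmax, times)
  if (noiseSd > 0) resp <- resp + rnorm(length(resp), 0, noiseSd)
  new("Sensorgram", time = times, response = resp, segments = seg)
}

#' Simulate a complete SOS-regulon experiment
#'
#' End-to-end fixture with recorded ground truth: genome, annotation,
#' planted promoter SOS boxes with an even mix of dissociation classes,
#' the four coverage tracks of the +/-MMC ChIP design, and a triplicate
#' count matrix in which every site's target unit is differentially
#' expressed (|log2FC| = \code{deEffect}, mostly up as LexA targets are
#' derepressed).
#'
#' @param genomeLength chromosome length in bp (default 1e5).
#' @param nGenes,nSites annotation and planted-site sizes.
#' @param occupancy untreated fold-occupancy of planted sites (default 8).
#' @param backgroundDepth mean coverage depth (default 20).
#' @param deEffect |log2FC| planted at target units (default 2).
#' @param upFraction fraction of targets upregulated (default 0.65).
#' @param config a \linkS4class{SosConfig}.
#' @param seed integer seed (drives every stage).
#' @return a list: \code{genome}, \code{annotation}, \code{truth},
#'   coverage tracks \code{chipUntreated}, \code{ctrlUntreated},
#'   \code{chipMMC}, \code{ctrlMMC}, and \code{counts}.
#' @export
simulateSosExperiment <- function(genomeLength = 1e5, nGenes = 60,
                                  nSites = 30, occupancy = 8,
                                  backgroundDepth = 20, deEffect = 2,
                                  upFraction = 0.65, config = sosConfig(),
                                  seed = 1) {
  set.seed(seed)
  genome <- generateGenome(c(chr = as.integer(genomeLength)), gc = 0.72)
  ann <- generateAnnotation(genome, nGenes = nGenes)
  planted <- plantSites(genome, ann, nPromoter = nSites, config = config)
  sites <- planted$truth$sites
  up <- runif(nrow(sites)) < upFraction
  lfc <- setNames(ifelse(up, deEffect, -deEffect), sites$target_gene)
  planted$truth$de_genes <- lfc
  counts <- simulateCounts(ann, log2FC = lfc)
  list(genome = planted$genome, annotation = ann, truth = planted$truth,
       chipUntreated = simulateChipCoverage(planted$genome, planted$truth,
                                            backgroundDepth,
                                            condition = "untreated"),
       ctrlUntreated = simulateChipCoverage(planted$genome, planted$truth,
                                            backgroundDepth,
                                            condition = "untreated",
                                            control = TRUE),
       chipMMC = simulateChipCoverage(planted$genome, planted$truth,
                                      backgroundDepth, condition = "MMC"),
       ctrlMMC = simulateChipCoverage(planted$genome, planted$truth,
                                      backgroundDepth, condition = "MMC",
                                      control = TRUE),
       counts = counts)
}
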