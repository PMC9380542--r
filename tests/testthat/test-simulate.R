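test_that("genome generation is seeded and GC-calibrated", {
  g1 <- generateGenome(c(chr = 20000L), gc = 0.72, seed = 91)
  g2 <- generateGenome(c(chr = 20000L), gc = 0.72, seed = 91)
  expect_identical(as.character(g1), as.character(g2))
  gcFrac <- sum(Biostrings::letterFrequency(g1, c("G", "C"))) / 20000
  expect_lt(abs(gcFrac - 0.72), 3 * sqrt(0.72 * 0.28 / 20000))
  expect_error(generateGenome(c(chr = 100L), gc = 1), "gc")
})

test_that("generated annotations have disjoint genes and sane units", {
  g <- generateGenome(c(chr = 80000L), seed = 92)
  annS <- generateAnnotation(g, nGenes = 50, operonFraction = 0, seed = 93)
  expect_length(unique(annS$unit_id), 50L)
  annO <- generateAnnotation(g, nGenes = 50, operonFraction = 0.8,
                             seed = 94)
  expect_lt(length(unique(annO$unit_id)), 40L)
  for (ann in list(annS, annO)) {
    expect_true(all(IRanges::countOverlaps(ann, ann) == 1))  # disjoint
    fg <- firstGenes(ann)
    # operon members share the strand of their first gene
    for (u in unique(ann$unit_id)) {
      expect_length(unique(as.character(strand(ann))[ann$unit_id == u]), 1)
    }
    expect_true(all(!is.na(fg$tss)))
  }
})

test_that("planted sites follow the Table-style offset convention", {
  g <- generateGenome(c(chr = 5000L), seed = 95)
  annP <- makeAnn(starts = 3001, ends = 4000, strands = "+")
  pl <- plantSites(g, annP, nPromoter = 1, offsets = -162, seed = 96)
  site <- pl$truth$sites[1, ]
  expect_equal(site$position, 3001L - 162L)
  planted <- as.character(Biostrings::subseq(pl$genome[["chr"]],
                                             site$position,
                                             site$position + 15L))
  # matches the consensus at every non-N position
  expect_true(grepl("^TCGAAC....G..CGA$", planted))
  expect_equal(planted, site$instance)

  # minus-strand planting leaves the reverse complement on the forward seq
  annM <- makeAnn(starts = 1001, ends = 2000, strands = "-")
  plM <- plantSites(g, annM, nPromoter = 1, offsets = -162, seed = 97)
  sM <- plM$truth$sites[1, ]
  expect_equal(sM$position, 2000L + 162L - 15L)
  fwd <- as.character(Biostrings::subseq(plM$genome[["chr"]], sM$position,
                                         sM$position + 15L))
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd))), sM$instance)
})

test_that("scanning the planted genome recovers every planted site", {
  g <- generateGenome(c(chr = 60000L), seed = 98)
  ann <- generateAnnotation(g, nGenes = 35, seed = 99)
  pl <- plantSites(g, ann, nPromoter = 12, nIntragenic = 4, seed = 100)
  model <- new("MotifModel", width = 16L,
               pwm = consensusToPwm(pl$truth$consensus),
               background = motifBackground(pl$genome),
               consensus = pl$truth$consensus, occurrencePrior = 0.5,
               logLik = 0, logLikRatio = 0, score = 0, nSeq = 1L,
               llHistory = numeric(0))
  hits <- scanMotif(model, pl$genome, thresholdBits = 15)
  found <- paste(hits$position, hits$strand)
  sites <- pl$truth$sites
  expect_true(all(paste(sites$position, sites$strand) %in% found |
                    paste(sites$position, "+") %in% found |
                    paste(sites$position, "-") %in% found))
})

test_that("ChIP coverage has the expected background, site and control means", {
  g <- generateGenome(c(chr = 30000L), seed = 101)
  ann <- makeAnn(starts = 15001, ends = 16000, strands = "+")
  pl <- plantSites(g, ann, nPromoter = 1, classes = "partial",
                   offsets = -100, seed = 102)
  site <- pl$truth$sites[1, ]
  covU <- simulateChipCoverage(pl$genome, pl$truth, backgroundDepth = 20,
                               condition = "untreated", seed = 103)
  v <- as.numeric(covU[["chr"]])
  far <- v[1:10000]
  expect_lt(abs(mean(far) - 20), 3 * sqrt(20 / length(far)))
  mid <- site$position + 8
  win <- v[(mid - 80):(mid + 79)]
  expect_lt(abs(mean(win) - 160), 3 * sqrt(160 / length(win)))
  # treated occupancy for a partial site is half the untreated one
  covT <- simulateChipCoverage(pl$genome, pl$truth, backgroundDepth = 20,
                               condition = "MMC", seed = 104)
  winT <- as.numeric(covT[["chr"]])[(mid - 80):(mid + 79)]
  expect_lt(abs(mean(winT) - 80), 3 * sqrt(80 / length(winT)))
  # control tracks ignore occupancy
  covC <- simulateChipCoverage(pl$genome, pl$truth, backgroundDepth = 20,
                               control = TRUE, seed = 105)
  winC <- as.numeric(covC[["chr"]])[(mid - 80):(mid + 79)]
  expect_lt(abs(mean(winC) - 20), 3 * sqrt(20 / length(winC)))
})

test_that("coverage mass scales linearly with background depth", {
  g <- generateGenome(c(chr = 20000L), seed = 106)
  truth <- list(sites = NULL, consensus = "TCGAACNNNNGNNCGA")
  m1 <- sum(simulateChipCoverage(g, truth, backgroundDepth = 10,
                                 seed = 107)[["chr"]])
  m2 <- sum(simulateChipCoverage(g, truth, backgroundDepth = 20,
                                 seed = 108)[["chr"]])
  expect_lt(abs(m2 / m1 - 2), 3 * sqrt(1 / (10 * 20000)) * 2 * 2)
})

test_that("count simulation matches its NB design", {
  g <- generateGenome(c(chr = 60000L), seed = 109)
  ann <- generateAnnotation(g, nGenes = 40, seed = 110)
  se <- simulateCounts(ann, log2FC = setNames(2, ann$gene_id[1]),
                       seed = 111)
  expect_equal(dim(se), c(40L, 6L))
  expect_equal(levels(SummarizedExperiment::colData(se)$condition),
               c("untreated", "treated"))
  expect_identical(
    SummarizedExperiment::assay(simulateCounts(ann, seed = 5)),
    SummarizedExperiment::assay(simulateCounts(ann, seed = 5)))
  expect_error(simulateCounts(ann, dispersion = 0), "positive")
  # near-Poisson limit: variance/mean ratio close to 1
  seP <- simulateCounts(ann, dispersion = 1e-6, meanRange = c(500, 500),
                        seed = 112)
  cnt <- SummarizedExperiment::assay(seP)
  expect_equal(mean(apply(cnt, 1, var) / rowMeans(cnt)), 1,
               tolerance = 0.15)
})

test_that("planted log2FC are estimated with small error at base mean 500", {
  # Monte-Carlo: 200 genes per fold-change level, n = 3 per condition
  lv <- c(-2, -1, 0, 1, 2)
  set.seed(113)
  mu <- 500
  err <- sapply(lv, function(l) {
    m <- outer(rep(mu, 200), c(1, 1, 1, 2^l, 2^l, 2^l))
    cnt <- matrix(rnbinom(length(m), mu = m, size = 10), nrow = 200)
    est <- log2((rowMeans(cnt[, 4:6]) + 0.5) / (rowMeans(cnt[, 1:3]) + 0.5))
    mean(abs(est - l))
  })
  expect_true(all(err < 0.5))
})

test_that("summit-sequence simulation plants one recoverable site each", {
  ss <- simulateSummitSequences(n = 40, seed = 114)
  expect_length(ss$seqs, 40L)
  expect_true(all(width(ss$seqs) == 100L))
  for (i in seq_len(10)) {
    s <- ss$sites[i, ]
    sub <- as.character(Biostrings::subseq(ss$seqs[[i]], s$position,
                                           s$position + 15L))
    if (s$strand == "-")
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    # planted instance differs from the recorded one only at mismatches
    expect_equal(sub, s$instance)
  }
})
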