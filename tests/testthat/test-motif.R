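test_that("consensus casing encodes conservation levels", {
  pwm1 <- matrix(c(0.97, 0.01, 0.01, 0.01,
                   0.6, 0.2, 0.1, 0.1,
                   0.3, 0.3, 0.2, 0.2), nrow = 4)
  rownames(pwm1) <- c("A", "C", "G", "T")
  expect_equal(buildConsensus(pwm1), "AaN")
  expect_error(buildConsensus(matrix(1, 4, 2)), "summing")
  # consensusToPwm inverts the casing convention
  expect_equal(buildConsensus(consensusToPwm("tCGAACNNNNGNNCGa")),
               "tCGAACNNNNGNNCGa")
})

test_that("the E-step posterior matches brute-force enumeration", {
  set.seed(61)
  for (rep in 1:3) {
    seqs <- randomSeqs(5, sample(20:40, 1), gc = 0.5)
    w <- sample(4:8, 1)
    pwmM <- matrix(rgamma(4 * w, 1), nrow = 4)
    pwmM <- sweep(pwmM, 2, colSums(pwmM), "/")
    rownames(pwmM) <- c("A", "C", "G", "T")
    q <- c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)
    gamma <- runif(1, 0.2, 0.9)
    fast <- zoopsPosterior(seqs, pwmM, q, gamma)
    slow <- bruteZoopsPosterior(seqs, pwmM, q, gamma)
    for (i in seq_along(fast)) {
      expect_equal(fast[[i]]$absent, slow[[i]]$absent, tolerance = 1e-9)
      expect_equal(fast[[i]]$plus, unname(slow[[i]]$plus),
                   tolerance = 1e-9)
      expect_equal(fast[[i]]$minus, unname(slow[[i]]$minus),
                   tolerance = 1e-9)
    }
  }
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  seqs <- randomSeqs(40, 60, plant = "TCGAACNNNNGNNCGA", seed = 62)
  m <- discoverMotif(seqs, widthRange = c(16, 16), nStarts = 3, seed = 63)
  ll <- m@llHistory
  expect_gt(length(ll), 2)
  expect_true(all(diff(ll) >= -1e-8 * abs(ll[-length(ll)])))
})

test_that("discovery recovers a planted motif and its width", {
  seqs <- randomSeqs(50, 80, plant = "TCGAACNNNNGNNCGA", seed = 64)
  m <- discoverMotif(seqs, widthRange = c(12, 20), nStarts = 6, seed = 65)
  expect_equal(motifWidth(m), 16L)
  cons <- consensus(m)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    chartr("acgt", "ACGT", cons))))
  fixed <- "TCGAAC....G..CGA"
  matchesPlanted <- function(x)
    grepl(paste0("^", fixed, "$"), chartr("acgtN", "ACGT.", x))
  expect_true(matchesPlanted(cons) || matchesPlanted(rc))
  expect_gt(m@occurrencePrior, 0.8)
  # background-only input yields a weaker per-width score
  bgOnly <- randomSeqs(50, 80, seed = 66)
  m0 <- discoverMotif(bgOnly, widthRange = c(16, 16), nStarts = 4, seed = 67)
  expect_lt(m0@logLikRatio, m@logLikRatio / 4)
})

test_that("a repeated single-site sequence gives near-point-mass columns", {
  one <- randomSeqs(1, 40, plant = "TCGAACGTACGTTCGA", seed = 68)
  seqs <- Biostrings::DNAStringSet(rep(as.character(one), 50))
  m <- discoverMotif(seqs, widthRange = c(16, 16), nStarts = 2, seed = 69)
  expect_true(all(apply(pwm(m), 2, max) > 0.9))
})

test_that("scanning finds exact instances on both strands", {
  model <- new("MotifModel", width = 16L,
               pwm = consensusToPwm("TCGAACAAAAGAACGA"),
               background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
               consensus = "TCGAACAAAAGAACGA", occurrencePrior = 0.5,
               logLik = 0, logLikRatio = 0, score = 0, nSeq = 1L,
               llHistory = numeric(0))
  pad <- strrep("A", 20)
  inst <- "TCGAACAAAAGAACGA"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(inst)))
  seqs <- Biostrings::DNAStringSet(c(fwd = paste0(pad, inst, pad),
                                     rev = paste0(pad, rc, pad)))
  hits <- scanMotif(model, seqs, thresholdFrac = 0.9)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$position, c(21L, 21L))
  expect_setequal(hits$strand, c("-", "+"))
  expect_equal(hits$score[1], hits$score[2])
  # a threshold above the maximum yields no hits
  expect_equal(nrow(scanMotif(model, seqs, thresholdBits = 1e6)), 0L)
  expect_error(scanMotif(model, seqs), "exactly one")
})

test_that("scan offsets follow the start-codon convention", {
  set.seed(70)
  g <- generateGenome(c(chr = 3000L), seed = 70)
  ann <- makeAnn(starts = 2001, ends = 2900, strands = "+")
  pl <- plantSites(g, ann, nPromoter = 1, offsets = -162, seed = 71)
  model <- new("MotifModel", width = 16L,
               pwm = consensusToPwm(pl$truth$consensus),
               background = motifBackground(g),
               consensus = pl$truth$consensus, occurrencePrior = 0.5,
               logLik = 0, logLikRatio = 0, score = 0, nSeq = 1L,
               llHistory = numeric(0))
  hits <- scanMotif(model, pl$genome, thresholdBits = 12,
                    annotation = ann)
  hit <- hits[which.max(hits$score), ]
  expect_equal(hit$offset_to_start_codon, -162L)
  expect_equal(hit$nearest_unit, "g01")
})

test_that("summit sequences are centred, truncated and flagged", {
  g <- Biostrings::DNAStringSet(c(chr = strrep("ACGT", 500)))  # 2 kb
  pk <- makePeaks(starts = c(450, 1), ends = c(550, 60),
                  summits = c(501, 21))
  ss <- extractSummitSequences(pk, g, length = 100)
  expect_equal(width(ss), c(100L, 70L))
  # 0-based [450, 550) is 1-based [451, 550]
  expect_equal(as.character(ss[[1]]),
               as.character(Biostrings::subseq(g[["chr"]], 451, 550)))
  expect_equal(S4Vectors::metadata(ss)$truncated, c(FALSE, TRUE))
  expect_length(extractSummitSequences(pk[0], g), 0)
})

test_that("motif model files round-trip", {
  seqs <- randomSeqs(30, 50, plant = "TCGAACNNNNGNNCGA", seed = 72)
  m <- discoverMotif(seqs, widthRange = c(16, 16), nStarts = 2, seed = 73)
  f <- tempfile(fileext = ".motif")
  writeMotif(m, f)
  back <- readMotif(f)
  expect_equal(motifWidth(back), motifWidth(m))
  expect_equal(consensus(back), consensus(m))
  expect_equal(pwm(back), pwm(m), tolerance = 1e-6)
  expect_equal(background(back), background(m), tolerance = 1e-6)
})

test_that("discovery refuses sequences shorter than the width range", {
  seqs <- Biostrings::DNAStringSet(c("ACGTACGT", "ACGTACGTACGT"))
  expect_error(discoverMotif(seqs, widthRange = c(6, 20)), "long")
})
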