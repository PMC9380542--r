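test_that("window grids tile contigs and drop partial tails", {
  expect_equal(start(makeWindows(c(chr = 60L))), c(1L, 16L, 31L))
  expect_equal(start(makeWindows(c(chr = 59L))), c(1L, 16L))
  expect_length(makeWindows(c(chr = 30L)), 1L)
  expect_error(makeWindows(c(chr = 29L)), "shorter")
  # with step = size/2 every interior base is covered by exactly 2 windows
  grid <- makeWindows(c(chr = 150L))
  covg <- IRanges::coverage(GenomicRanges::ranges(grid))
  expect_true(all(as.numeric(covg)[16:135] == 2))
})

test_that("window masses sum per-base depth", {
  grid <- makeWindows(c(chr = 60L))
  expect_equal(countInWindows(covTrack(rep(2, 60)), grid), rep(60, 3))
  expect_equal(countInWindows(covTrack(rep(0, 60)), grid), rep(0, 3))
  d <- rep(0, 60); d[21] <- 7       # base 21 lies in windows 1 and 2 only
  expect_equal(countInWindows(covTrack(d), grid), c(7, 7, 0))
})

test_that("local enrichment is zero for uniform and all-zero coverage", {
  grid <- makeWindows(c(chr = 5000L))
  et <- localEnrichment(covTrack(rep(3, 5000)), grid, flankSize = 300)
  inner <- start(grid) > 200 & end(grid) < 4800
  expect_equal(enrichment(et)[inner], rep(0, sum(inner)))
  et0 <- localEnrichment(covTrack(rep(0, 5000)), grid, flankSize = 300)
  expect_equal(enrichment(et0), rep(0, length(grid)))
})

test_that("a window at 4x its flank density scores log2(4) = 2", {
  d <- rep(1, 5000)
  d[2971:3000] <- 4                  # exactly window [2971, 3000]
  grid <- makeWindows(c(chr = 5000L))
  et <- localEnrichment(covTrack(d), grid, flankSize = 3000, pseudocount = 0)
  i <- which(start(grid) == 2971)
  expect_equal(enrichment(et)[i], 2)
})

test_that("local enrichment matches a brute-force per-base recomputation", {
  set.seed(11)
  for (L in c(2000L, 5000L)) {
    d <- rpois(L, 5)
    grid <- makeWindows(c(chr = L))
    eps <- 1 / (3000 - 30)
    fast <- enrichment(localEnrichment(covTrack(d), grid, flankSize = 3000))
    slow <- bruteLocalEnrichment(d, 30, 15, 3000, eps)
    expect_equal(fast, slow, tolerance = 1e-9)
  }
})

test_that("enrichment is invariant to depth scaling", {
  set.seed(12)
  d <- rpois(3000, 10) + 1           # strictly positive
  grid <- makeWindows(c(chr = 3000L))
  e1 <- enrichment(localEnrichment(covTrack(d), grid, 600, pseudocount = 0))
  e5 <- enrichment(localEnrichment(covTrack(5 * d), grid, 600,
                                   pseudocount = 0))
  expect_equal(e1, e5, tolerance = 1e-12)
})

test_that("control subtraction is a per-window log2 difference", {
  grid <- makeWindows(c(chr = 90L))
  a <- eTrack(c(3, 1, 0.5, 2, 0), grid, "chip", subtracted = FALSE)
  b <- eTrack(c(1, 1, 0.5, 0, 0), grid, "wt", subtracted = FALSE)
  s <- subtractControl(a, b)
  expect_equal(enrichment(s), c(2, 0, 0, 2, 0))
  expect_true(isControlSubtracted(s))
  expect_equal(enrichment(subtractControl(a, a)), rep(0, 5))
  zero <- eTrack(rep(0, 5), grid, "z", subtracted = FALSE)
  expect_equal(enrichment(subtractControl(a, zero)), enrichment(a))
  expect_error(subtractControl(s, b), "already")
  other <- eTrack(rep(0, 3), makeWindows(c(chr = 60L)), subtracted = FALSE)
  expect_error(subtractControl(a, other), "grids")
})

test_that("peak calling merges abutting enriched windows and places summits", {
  grid <- makeWindows(c(chr = 75L))    # windows at 1, 16, 31, 46
  pk <- callPeaks(eTrack(c(0, 1.2, 1.5, 0), grid))
  expect_length(pk, 1)
  expect_equal(start(pk), 16L)
  expect_equal(end(pk), 60L)
  expect_equal(pk$windowCount, 2L)
  expect_equal(pk$maxLog2Enrichment, 1.5)
  expect_equal(pk$summit, 46L)         # midpoint of window [31, 60]

  # sub-threshold windows are never bridged
  grid6 <- makeWindows(c(chr = 105L))
  pk2 <- callPeaks(eTrack(c(1.5, 1.5, 0.5, 1.3, 1.1, 0), grid6))
  expect_length(pk2, 2)
  expect_equal(pk2$windowCount, c(2L, 2L))

  # summit tie resolves to the leftmost maximal window
  pk3 <- callPeaks(eTrack(c(0, 1.4, 1.4, 0), grid))
  expect_equal(pk3$summit, 31L)

  expect_length(callPeaks(eTrack(c(0.9, 0.3, 0, 0), grid)), 0)
  expect_error(callPeaks(eTrack(c(1, 1, 1, 1), grid, subtracted = FALSE)),
               "control-subtracted")
})

test_that("peak fold change is an antisymmetric log2 difference of maxima", {
  grid <- makeWindows(c(chr = 75L))
  a <- eTrack(c(0, 3.0, 2.4, 0), grid)
  b <- eTrack(c(0, 1.16, 0.8, 0), grid)
  pk <- callPeaks(a)
  expect_equal(peakFoldChange(pk, a, a), 0)
  expect_equal(peakFoldChange(pk, a, b), 1.84)
  expect_equal(peakFoldChange(pk, a, b), -peakFoldChange(pk, b, a))
})
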