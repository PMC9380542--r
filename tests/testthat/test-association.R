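cfg <- sosConfig()

test_that("promoter association follows the strand-aware offset convention", {
  # plus-strand gene with start codon at 1001; summit at 839 gives the
  # canonical -162 operator offset
  ann <- makeAnn(starts = 1001, ends = 2000, strands = "+")
  pk <- makePeaks(starts = 800, ends = 880, summits = 839)
  a <- associatePromoters(pk, ann, cfg)
  expect_equal(nrow(a), 1L)
  expect_equal(a$offset, -162L)
  expect_equal(a$unit_id, "g01")
  expect_equal(a$category, "promoter")

  # the mirrored case on the minus strand gives the same offset
  annM <- makeAnn(starts = 2001, ends = 3000, strands = "-")
  pkM <- makePeaks(starts = 3120, ends = 3200, summits = 3162)
  aM <- associatePromoters(pkM, annM, cfg)
  expect_equal(aM$offset, -162L)

  # a summit exactly on the start codon is offset 0 and associated
  pk0 <- makePeaks(starts = 950, ends = 1050, summits = 1001)
  expect_equal(associatePromoters(pk0, ann, cfg)$offset, 0L)
})

test_that("peaks outside the window or distance rules are not associated", {
  ann <- makeAnn(starts = 1001, ends = 2000, strands = "+")
  # offset -250 (outside [-200, 100]) and edge 301 bp away
  pk <- makePeaks(starts = 600, ends = 700, summits = 751)
  expect_equal(nrow(associatePromoters(pk, ann, cfg)), 0L)
  # offset inside the window but peak edge beyond 300 bp fails rule (a)
  pkFar <- makePeaks(starts = 500, ends = 650, summits = 900)
  expect_equal(nrow(associatePromoters(pkFar, ann, cfg)), 0L)
})

test_that("a peak between divergent units associates with both", {
  ann <- makeAnn(starts = c(100, 1200), ends = c(1000, 2000),
                 strands = c("-", "+"))
  pk <- makePeaks(starts = 1050, ends = 1150, summits = 1100)
  a <- associatePromoters(pk, ann, cfg)
  expect_equal(sort(a$unit_id), c("g01", "g02"))
  expect_equal(a$offset[a$unit_id == "g01"], -100L)
  expect_equal(a$offset[a$unit_id == "g02"], -100L)
})

test_that("intragenic classification needs >100 bp into the gene body", {
  ann <- makeAnn(starts = 1001, ends = 3000, strands = "+")
  deep <- makePeaks(starts = 1450, ends = 1550, summits = 1501)  # +500
  a <- classifyIntragenic(deep, ann, config = cfg)
  expect_equal(a$category, "intragenic")
  expect_equal(a$offset, 500L)
  shallow <- makePeaks(starts = 1000, ends = 1100, summits = 1051) # +50
  expect_equal(nrow(classifyIntragenic(shallow, ann, config = cfg)), 0L)
})

test_that("promoter assignment takes precedence over intragenic", {
  # summit inside gene A but within the regulatory window of downstream B
  ann <- makeAnn(starts = c(1001, 3101), ends = c(3000, 4000),
                 strands = c("+", "+"))
  pk <- makePeaks(starts = 2900, ends = 3000, summits = 2951) # -150 of B
  expect_equal(associatePromoters(pk, ann, cfg)$unit_id, "g02")
  expect_equal(nrow(classifyIntragenic(pk, ann, config = cfg)), 0L)
  both <- associatePeaks(pk, ann, config = cfg)
  expect_equal(nrow(both), 1L)
  expect_equal(both$category, "promoter")
})

test_that("no peak is both promoter-associated and intragenic for one unit", {
  set.seed(31)
  ann <- generateAnnotation(generateGenome(c(chr = 40000L), seed = 31),
                            nGenes = 25, seed = 32)
  pk <- makePeaks(starts = seq(500, 39000, by = 1600),
                  ends = seq(500, 39000, by = 1600) + 120,
                  summits = seq(560, 39060, by = 1600))
  assoc <- associatePeaks(pk, ann, config = cfg)
  key <- paste(assoc$peak_id, assoc$unit_id)
  split_by <- split(assoc$category, key)
  expect_true(all(vapply(split_by, function(x) length(unique(x)) == 1,
                         logical(1))))
})

test_that("TSS proximity is evaluated within the configured radius", {
  ann <- makeAnn(starts = 1001, ends = 3000, strands = "+",
                 tss = 1480L)
  pk <- makePeaks(starts = 1450, ends = 1550, summits = 1501)
  a <- classifyIntragenic(pk, ann, config = cfg)
  expect_true(a$tss_proximal)
  annFar <- makeAnn(starts = 1001, ends = 3000, strands = "+",
                    tss = 1300L)
  expect_false(classifyIntragenic(pk, annFar, config = cfg)$tss_proximal)
})

test_that("associations are invariant under genome reflection", {
  L <- 50000L
  set.seed(33)
  ann <- generateAnnotation(generateGenome(c(chr = L), seed = 34),
                            nGenes = 20, seed = 35)
  starts <- seq(1000, 48000, by = 2400)
  pk <- makePeaks(starts = starts, ends = starts + 150,
                  summits = starts + 75)
  fwd <- associatePromoters(pk, ann, cfg)

  # reflect every coordinate (x -> L + 1 - x) and flip strands
  annR <- GRanges("chr", IRanges(L + 1L - end(ann), L + 1L - start(ann)),
                  strand = ifelse(as.character(strand(ann)) == "+",
                                  "-", "+"))
  mcols(annR) <- mcols(ann)
  pkR <- makePeaks(starts = L + 1L - end(pk), ends = L + 1L - start(pk),
                   summits = L + 1L - pk$summit)
  pkR$name <- pk$name
  rev_ <- associatePromoters(pkR, annR, cfg)
  o1 <- order(fwd$peak_id, fwd$unit_id)
  o2 <- order(rev_$peak_id, rev_$unit_id)
  expect_equal(fwd$unit_id[o1], rev_$unit_id[o2])
  expect_equal(fwd$offset[o1], rev_$offset[o2])
  expect_equal(fwd$distance[o1], rev_$distance[o2])
})
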