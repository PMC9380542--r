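# Shared fixture builders and independent oracle implementations.
# Oracles deliberately use plain loops / first-principles formulas and never
# call the code paths they check.

covTrack <- function(depth, contig = "chr") {
  methods::as(stats::setNames(list(S4Vectors::Rle(depth)), contig),
              "SimpleRleList")
}

makeAnn <- function(starts, ends, strands, contig = "chr",
                    units = NULL, tss = NULL) {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(starts, ends),
                               strand = strands)
  gr$gene_id <- sprintf("g%02d", seq_along(gr))
  gr$unit_id <- if (is.null(units)) gr$gene_id else units
  gr$tss <- if (is.null(tss)) rep(NA_integer_, length(gr)) else tss
  gr
}

makePeaks <- function(starts, ends, summits, contig = "chr") {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(starts, ends))
  gr$name <- sprintf("peak_%04d", seq_along(gr))
  gr$summit <- as.integer(summits)
  gr$maxLog2Enrichment <- rep(2, length(gr))
  gr$windowCount <- rep(1L, length(gr))
  gr
}

# Enrichment track wrapper for tests that start from a known E vector.
eTrack <- function(e, grid, label = "t", subtracted = TRUE) {
  methods::new("EnrichmentTrack", windows = grid, enrichment = e,
               sampleLabel = label, controlSubtracted = subtracted)
}

# Brute-force per-base local enrichment: explicit loops, no Views/cumsums.
bruteLocalEnrichment <- function(depth, windowSize, step, flankSize,
                                 pseudocount) {
  L <- length(depth)
  starts <- seq(1, L - windowSize + 1, by = step)
  half <- (flankSize - windowSize) %/% 2
  sapply(starts, function(s) {
    e <- s + windowSize - 1
    wm <- 0
    for (i in s:e) wm <- wm + depth[i]
    rs <- max(1, s - half); re <- min(L, e + half)
    rm <- 0
    for (i in rs:re) rm <- rm + depth[i]
    dw <- wm / windowSize
    df <- (rm - wm) / (re - rs + 1 - windowSize)
    log2((dw + pseudocount) / (df + pseudocount))
  })
}

# Brute-force Benjamini-Hochberg step-up.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# Brute-force ZOOPS E-step by enumeration of every configuration.
bruteZoopsPosterior <- function(seqs, pwmMat, bgFreq, gamma) {
  rcb <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]
  lapply(as.character(seqs), function(s) {
    ch <- strsplit(s, "")[[1]]
    L <- length(ch); w <- ncol(pwmMat); m <- L - w + 1
    pbg <- prod(bgFreq[ch])
    probSite <- function(p, strand) {
      inst <- ch[p:(p + w - 1)]
      if (strand == "-") inst <- rev(vapply(inst, rcb, ""))
      ps <- prod(vapply(seq_len(w), function(j) pwmMat[inst[j], j],
                        numeric(1)))
      rest <- prod(bgFreq[ch[-(p:(p + w - 1))]])
      gamma / (2 * m) * ps * rest
    }
    wAbs <- (1 - gamma) * pbg
    wPlus <- vapply(seq_len(m), probSite, numeric(1), strand = "+")
    wMinus <- vapply(seq_len(m), probSite, numeric(1), strand = "-")
    tot <- wAbs + sum(wPlus) + sum(wMinus)
    list(absent = wAbs / tot, plus = wPlus / tot, minus = wMinus / tot)
  })
}

# Background sequences of a given GC, optionally with one planted instance.
randomSeqs <- function(n, len, gc = 0.72, plant = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  out <- vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p)
    if (!is.null(plant)) {
      inst <- strsplit(plant, "")[[1]]
      inst[inst == "N"] <- sample(c("A", "C", "G", "T"), sum(inst == "N"),
                                  replace = TRUE)
      if (runif(1) < 0.5)
        inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
      at <- sample(len - length(inst) + 1, 1)
      s[at:(at + length(inst) - 1)] <- inst
    }
    paste(s, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(out)
}
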