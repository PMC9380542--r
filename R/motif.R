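## ZOOPS motif discovery and PWM scanning.
##
## Model: each sequence carries, with probability gamma, exactly one motif
## occurrence at a uniformly chosen (position, strand); otherwise it is pure
## 0-order background.  EM alternates a posterior over
## {absent} u {every (position, strand)} with PWM/gamma re-estimation
## (Dirichlet pseudocount 0.25 per base).  The width is chosen across a
## search range by BIC-penalised log-likelihood ratio.

BASES <- c("A", "C", "G", "T")

## Log prior of the Dirichlet(1 + 0.25) column regularisation (up to a
## constant).  The M-step maximises expected complete log-likelihood plus
## this term, so observed log-likelihood + prior is the quantity MAP-EM
## guarantees never to decrease; it is what llHistory records.
dirichletLogPrior <- function(pwmMat) 0.25 * sum(log(pwmMat))
COMP <- c(4L, 3L, 2L, 1L, 5L)          # A<->T, C<->G, N->N

## DNAStringSet -> list of integer matrices (codes 1..4, N = 5), grouped by
## sequence length; attribute "index" maps rows back to input order.
encodeSeqs <- function(seqs) {
  chars <- strsplit(as.character(seqs), "")
  codes <- lapply(chars, function(x) {
    i <- match(x, c(BASES, "N"))
    if (any(is.na(i))) stop("sequences must be over A/C/G/T/N")
    i
  })
  lens <- lengths(codes)
  lapply(split(seq_along(codes), lens), function(idx) {
    m <- do.call(rbind, codes[idx])
    attr(m, "index") <- idx
    m
  })
}

## Background log-probability of every sequence (N bases contribute 0).
bgLogLik <- function(groups, logq) {
  ll <- numeric(sum(vapply(groups, nrow, integer(1))))
  lq5 <- c(logq, 0)
  for (g in groups)
    ll[attr(g, "index")] <- rowSums(array(lq5[g], dim(g)))
  ll
}

## Strand-specific log-odds lookup tables, 5 rows (N scores 0).
## lomP[b,k]: forward base b as site offset k on the + strand.
## lomM[b,k]: forward base b at site offset k when the site is on -.
siteLookups <- function(logpwm, logq) {
  w <- ncol(logpwm)
  lomP <- rbind(logpwm - logq, 0)
  lomM <- rbind((logpwm[COMP[1:4], w:1, drop = FALSE] - logq), 0)
  list(P = lomP, M = lomM, w = w)
}

## Log odds-ratio matrices (n x m) for one length group, both strands.
siteLogOdds <- function(g, lk) {
  n <- nrow(g); L <- ncol(g); w <- lk$w
  m <- L - w + 1L
  sp <- sm <- matrix(0, n, m)
  for (k in seq_len(w)) {
    sub <- g[, k:(k + m - 1L), drop = FALSE]
    sp <- sp + lk$P[, k][sub]
    sm <- sm + lk$M[, k][sub]
  }
  list(P = sp, M = sm, m = m)
}

## One E-step: ZOOPS posteriors and the observed-data log-likelihood.
## Returns per group: ZP, ZM (n x m posteriors), qPresent, and ll per seq.
zoopsEStepGroups <- function(groups, logpwm, logq, gamma, bg) {
  lk <- siteLookups(logpwm, logq)
  la <- log1p(-gamma)
  res <- lapply(groups, function(g) {
    so <- siteLogOdds(g, lk)
    lsite <- log(gamma / (2 * so$m))
    wp <- lsite + so$P; wm <- lsite + so$M
    M <- pmax(apply(wp, 1, max), apply(wm, 1, max), la)
    ep <- exp(wp - M); em <- exp(wm - M)
    denom <- exp(la - M) + rowSums(ep) + rowSums(em)
    list(ZP = ep / denom, ZM = em / denom,
         qPresent = 1 - exp(la - M) / denom,
         ll = bg[attr(g, "index")] + M + log(denom),
         index = attr(g, "index"))
  })
  res
}

#' ZOOPS E-step posteriors
#'
#' Posterior probability, for every sequence, of carrying the motif at each
#' (position, strand) versus carrying no site, under the current model.
#' Exposed for diagnostics and for validating the EM against enumeration.
#'
#' @param seqs a \code{DNAStringSet}.
#' @param pwm 4 x width probability matrix (rows A, C, G, T).
#' @param bgFreq named background frequencies over A, C, G, T.
#' @param gamma per-sequence occurrence prior.
#' @return a list with one element per sequence: \code{absent} and
#'   matrices-less vectors \code{plus}, \code{minus} of site posteriors by
#'   starting position.
#' @export
zoopsPosterior <- function(seqs, pwm, bgFreq, gamma) {
  groups <- encodeSeqs(seqs)
  q <- bgFreq[BASES]; logq <- log(q)
  bg <- bgLogLik(groups, logq)
  es <- zoopsEStepGroups(groups, log(pwm), logq, gamma, bg)
  out <- vector("list", length(seqs))
  for (r in es)
    for (i in seq_along(r$index))
      out[[r$index[i]]] <- list(absent = 1 - r$qPresent[i],
                                plus = r$ZP[i, ], minus = r$ZM[i, ])
  out
}

## Full EM for one width from one start. Returns model pieces + ll history.
zoopsEM <- function(groups, q, width, maxIter, tol, bg, nSeq) {
  logq <- log(q)
  # seed the PWM from one random subsequence (MEME-style start)
  gl <- vapply(groups, nrow, integer(1))
  gi <- sample.int(length(groups), 1, prob = gl)
  g <- groups[[gi]]
  i <- sample.int(nrow(g), 1)
  p <- sample.int(ncol(g) - width + 1L, 1)
  sub <- g[i, p:(p + width - 1L)]
  if (runif(1) < 0.5) sub <- COMP[rev(sub)]
  pwm <- matrix(0.15, 4, width)
  for (k in seq_len(width))
    if (sub[k] <= 4L) pwm[sub[k], k] <- 0.55 else pwm[, k] <- 0.25
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  gamma <- 0.5
  llHist <- numeric(0)
  llPrev <- -Inf
  for (iter in seq_len(maxIter)) {
    es <- zoopsEStepGroups(groups, log(pwm), logq, gamma, bg)
    ll <- sum(vapply(es, function(r) sum(r$ll), numeric(1)))
    llHist <- c(llHist, ll + dirichletLogPrior(pwm))
    if (is.finite(llPrev) && ll - llPrev < tol * abs(llPrev)) break
    llPrev <- ll
    # M-step
    counts <- matrix(0.25, 4, width)
    qp <- 0
    for (k in seq_along(groups)) {
      g <- groups[[k]]; r <- es[[k]]
      m <- ncol(r$ZP)
      qp <- qp + sum(r$qPresent)
      for (off in seq_len(width)) {
        sub <- g[, off:(off + m - 1L), drop = FALSE]
        for (b in 1:4) {
          hit <- sub == b
          counts[b, off] <- counts[b, off] + sum(r$ZP[hit])
          counts[COMP[b], width + 1L - off] <-
            counts[COMP[b], width + 1L - off] + sum(r$ZM[hit])
        }
      }
    }
    pwm <- sweep(counts, 2, colSums(counts), "/")
    gamma <- min(max(qp / nSeq, 1e-6), 1 - 1e-6)
  }
  list(pwm = pwm, gamma = gamma, logLik = ll, llHistory = llHist)
}

#' Discover a motif by ZOOPS expectation-maximisation
#'
#' Searches both strands of the input sequences for a single ungapped motif
#' under the zero-or-one-occurrence-per-sequence model, over a range of
#' candidate widths.  For each width, several random starts are run briefly
#' and the best is refined to convergence; across widths the model with the
#' highest BIC-penalised log-likelihood ratio
#' (LLR - 3/2 * width * log(n)) is returned.  Deterministic given
#' \code{seed}.
#'
#' @param seqs a \code{DNAStringSet} (at least 10 sequences recommended).
#' @param widthRange integer(2), inclusive width search range (default
#'   \code{c(6, 30)}).
#' @param background named base frequencies, a \code{DNAStringSet} to
#'   estimate them from, or \code{NULL} to estimate from \code{seqs}.
#' @param nStarts random starts per width (default 10).
#' @param maxIter maximum EM iterations for the refinement run (default
#'   500; exploratory starts run at most \code{startIter}).
#' @param startIter iteration cap for exploratory starts (default 50).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return a \linkS4class{MotifModel}.
#' @export
discoverMotif <- function(seqs, widthRange = c(6, 30), background = NULL,
                          nStarts = 10, maxIter = 500, startIter = 50,
                          tol = 1e-6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  widths <- seq.int(widthRange[1], widthRange[2])
  if (min(width(seqs)) < max(widths))
    stop("all sequences must be at least as long as the largest width")
  q <- motifBackground(if (is.null(background)) seqs else background)
  groups <- encodeSeqs(seqs)
  bg <- bgLogLik(groups, log(q))
  ll0 <- sum(bg)
  nSeq <- length(seqs)
  best <- NULL
  for (w in widths) {
    runs <- lapply(seq_len(nStarts), function(s)
      zoopsEM(groups, q, w, maxIter = startIter, tol = tol, bg = bg,
              nSeq = nSeq))
    top <- runs[[which.max(vapply(runs, `[[`, numeric(1), "logLik"))]]
    fit <- refineEM(groups, q, top, maxIter, tol, bg, nSeq)
    # alignment-phase moves: a run can converge to a shifted optimum, so
    # try sliding the PWM one column either way and keep improvements
    for (round in 1:4) {
      improved <- FALSE
      for (s in c(-1L, 1L)) {
        cand <- fit
        cand$pwm <- shiftPwm(fit$pwm, s, q)
        cand <- refineEM(groups, q, cand, maxIter, tol, bg, nSeq)
        if (cand$logLik > fit$logLik + 1e-6 * abs(fit$logLik)) {
          fit <- cand
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    score <- (fit$logLik - ll0) - 1.5 * w * log(nSeq)
    if (is.null(best) || score > best$score)
      best <- c(fit, list(score = score, width = w))
  }
  pwm <- best$pwm
  dimnames(pwm) <- list(BASES, NULL)
  new("MotifModel", width = as.integer(best$width), pwm = pwm,
      background = q, consensus = buildConsensus(pwm),
      occurrencePrior = best$gamma, logLik = best$logLik,
      logLikRatio = best$logLik - ll0, score = best$score,
      nSeq = as.integer(nSeq), llHistory = best$llHistory)
}

## Slide a PWM s columns (s > 0: motif content moves right), padding the
## vacated columns with the background distribution.
shiftPwm <- function(pwmMat, s, q) {
  w <- ncol(pwmMat)
  out <- matrix(q, nrow = 4, ncol = w)
  src <- seq_len(w) - s
  ok <- src >= 1 & src <= w
  out[, ok] <- pwmMat[, src[ok]]
  out
}

## Continue EM from an exploratory run's parameters to full convergence.
## The returned llHistory covers this chain only, so it is the monotone
## trace of one EM run.
refineEM <- function(groups, q, start, maxIter, tol, bg, nSeq) {
  logq <- log(q)
  pwm <- start$pwm; gamma <- start$gamma
  llHist <- numeric(0)
  llPrev <- -Inf
  ll <- -Inf
  for (iter in seq_len(maxIter)) {
    es <- zoopsEStepGroups(groups, log(pwm), logq, gamma, bg)
    counts <- matrix(0.25, 4, ncol(pwm))
    qp <- 0
    width <- ncol(pwm)
    for (k in seq_along(groups)) {
      g <- groups[[k]]; r <- es[[k]]
      m <- ncol(r$ZP)
      qp <- qp + sum(r$qPresent)
      for (off in seq_len(width)) {
        sub <- g[, off:(off + m - 1L), drop = FALSE]
        for (b in 1:4) {
          hit <- sub == b
          counts[b, off] <- counts[b, off] + sum(r$ZP[hit])
          counts[COMP[b], width + 1L - off] <-
            counts[COMP[b], width + 1L - off] + sum(r$ZM[hit])
        }
      }
    }
    ll <- sum(vapply(es, function(r) sum(r$ll), numeric(1)))
    llHist <- c(llHist, ll + dirichletLogPrior(pwm))
    if (is.finite(llPrev) && ll - llPrev < tol * abs(llPrev)) break
    llPrev <- ll
    pwm <- sweep(counts, 2, colSums(counts), "/")
    gamma <- min(max(qp / nSeq, 1e-6), 1 - 1e-6)
  }
  list(pwm = pwm, gamma = gamma, logLik = ll, llHistory = llHist)
}

#' 0-order background base frequencies
#'
#' @param x a \code{DNAStringSet} or an already-named frequency vector.
#' @return named numeric(4) over A, C, G, T summing to 1 (N ignored).
#' @export
motifBackground <- function(x) {
  if (is.numeric(x)) {
    q <- x[BASES]
    if (any(is.na(q)) || any(q <= 0)) stop("background needs positive A/C/G/T")
    return(q / sum(q))
  }
  cnt <- colSums(letterFrequency(x, BASES))
  cnt <- cnt + 1          # guard empty letters
  setNames(cnt / sum(cnt), BASES)
}

#' Mixed-case consensus of a PWM
#'
#' Per column: the top base in uppercase when its probability reaches
#' \code{upperCutoff}, lowercase when it reaches \code{lowerCutoff},
#' otherwise \code{N} — the casing convention of published SOS-box logos.
#'
#' @param pwm 4 x width probability matrix (rows A, C, G, T).
#' @param upperCutoff,lowerCutoff probability cutoffs (defaults 0.9, 0.5).
#' @return consensus string.
#' @export
buildConsensus <- function(pwm, upperCutoff = 0.9, lowerCutoff = 0.5) {
  if (nrow(pwm) != 4L || any(abs(colSums(pwm) - 1) > 1e-6))
    stop("pwm must be a 4-row matrix with columns summing to 1")
  paste(vapply(seq_len(ncol(pwm)), function(j) {
    b <- which.max(pwm[, j]); p <- pwm[b, j]
    if (p >= upperCutoff) BASES[b]
    else if (p >= lowerCutoff) tolower(BASES[b])
    else "N"
  }, character(1)), collapse = "")
}

#' Turn a consensus string into a PWM
#'
#' Uppercase letters become near-certain columns (p = 0.91), lowercase
#' partially conserved ones (p = 0.7), and \code{N} uniform — handy for
#' scanning with a known consensus such as the planted SOS box.
#'
#' @param consensus string over \code{A C G T a c g t N}.
#' @return 4 x width probability matrix.
#' @export
consensusToPwm <- function(consensus) {
  chars <- strsplit(consensus, "")[[1]]
  pwm <- vapply(chars, function(ch) {
    if (ch == "N") return(rep(0.25, 4))
    b <- match(toupper(ch), BASES)
    if (is.na(b)) stop("illegal consensus character: ", ch)
    p <- if (ch %in% BASES) 0.91 else 0.7
    out <- rep((1 - p) / 3, 4); out[b] <- p
    out
  }, numeric(4))
  rownames(pwm) <- BASES
  pwm
}

#' @describeIn MotifModel-class the position weight matrix.
#' @export
setMethod("pwm", "MotifModel", function(x) x@pwm)

#' @describeIn MotifModel-class the mixed-case consensus.
#' @export
setMethod("consensus", "MotifModel", function(x) x@consensus)

#' @describeIn MotifModel-class the motif width in bp.
#' @export
setMethod("motifWidth", "MotifModel", function(x) x@width)

#' @describeIn MotifModel-class the background base frequencies.
#' @export
setMethod("background", "MotifModel", function(x) x@background)

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel: width %d, consensus %s\n",
              object@width, object@consensus))
  cat(sprintf("  occurrence prior %.3f, LLR %.1f over %d sequences\n",
              object@occurrencePrior, object@logLikRatio, object@nSeq))
})

#' Extract summit-centred sequences for motif discovery
#'
#' One forward-strand sequence per peak, centred on the summit; sequences
#' running over a contig end are truncated and flagged.
#'
#' @param peaks peak \code{GRanges} with a \code{summit} column.
#' @param genome a \code{DNAStringSet}.
#' @param length sequence length in bp (default 100).
#' @return a \code{DNAStringSet} named by peak, with a logical
#'   \code{truncated} entry in \code{metadata()}.
#' @export
extractSummitSequences <- function(peaks, genome, length = 100) {
  if (length(peaks) == 0L) return(DNAStringSet())
  cts <- as.character(seqnames(peaks))
  if (!all(cts %in% names(genome))) stop("peak on unknown contig")
  lens <- setNames(width(genome), names(genome))
  half <- as.integer(length) %/% 2L
  from <- peaks$summit - half
  to <- peaks$summit + half - 1L
  s <- pmax(from, 1L)
  e <- pmin(to, lens[cts])
  out <- DNAStringSet(vapply(seq_along(peaks), function(i)
    as.character(subseq(genome[[cts[i]]], s[i], e[i])), character(1)))
  names(out) <- peaks$name
  metadata(out)$truncated <- s != from | e != to
  metadata(out)$start <- s            # genomic position of base 1
  out
}

#' Scan sequences with a motif model
#'
#' Scores every offset on both strands with the log2-odds of the PWM
#' against its background; all hits at or above the threshold are reported
#' (overlapping hits are not masked).  For a minus-strand hit the reported
#' position is the site's first forward-strand base.
#'
#' @param model a \linkS4class{MotifModel}.
#' @param seqs a \code{DNAStringSet}; sequences shorter than the motif give
#'   no hits.
#' @param thresholdBits absolute log2-odds threshold, or
#' @param thresholdFrac threshold as a fraction of the maximal attainable
#'   score; exactly one of the two must be given.
#' @param annotation optional annotation \code{GRanges}; when given and the
#'   sequence names are its contigs, each hit gets the strand-aware offset
#'   of the box's first base to the nearest transcriptional-unit start
#'   codon (Table-style position convention).
#' @return a \code{DataFrame}: \code{sequence_id}, \code{position} (1-based
#'   forward strand), \code{strand}, \code{score} (bits),
#'   \code{offset_to_start_codon}, \code{nearest_unit}.
#' @export
scanMotif <- function(model, seqs, thresholdBits = NULL,
                      thresholdFrac = NULL, annotation = NULL) {
  if (is.null(thresholdBits) == is.null(thresholdFrac))
    stop("give exactly one of thresholdBits or thresholdFrac")
  q <- model@background[BASES]
  slo <- log2(model@pwm / q)              # 4 x w, bits
  maxScore <- sum(apply(slo, 2, max))
  thr <- if (!is.null(thresholdBits)) thresholdBits else
    thresholdFrac * maxScore
  w <- model@width
  keep <- width(seqs) >= w
  empty <- DataFrame(sequence_id = character(0), position = integer(0),
                     strand = character(0), score = numeric(0),
                     offset_to_start_codon = integer(0),
                     nearest_unit = character(0))
  if (!any(keep)) return(empty)
  sub <- seqs[keep]
  groups <- encodeSeqs(sub)
  lk <- list(P = rbind(slo, 0),
             M = rbind(slo[COMP[1:4], w:1, drop = FALSE], 0), w = w)
  rows <- list()
  for (g in groups) {
    so <- siteLogOdds(g, lk)
    idx <- attr(g, "index")
    for (i in seq_len(nrow(g))) {
      hp <- which(so$P[i, ] >= thr); hm <- which(so$M[i, ] >= thr)
      if (length(hp) + length(hm) == 0L) next
      rows[[length(rows) + 1L]] <- DataFrame(
        sequence_id = names(sub)[idx[i]],
        position = as.integer(c(hp, hm)),
        strand = rep(c("+", "-"), c(length(hp), length(hm))),
        score = c(so$P[i, hp], so$M[i, hm]))
    }
  }
  if (length(rows) == 0L) return(empty)
  hits <- do.call(rbind, rows)
  hits$offset_to_start_codon <- NA_integer_
  hits$nearest_unit <- NA_character_
  if (!is.null(annotation)) {
    fg <- firstGenes(annotation)
    for (r in seq_len(nrow(hits))) {
      fgc <- fg[as.character(seqnames(fg)) == hits$sequence_id[r]]
      if (length(fgc) == 0L) next
      # first base of the box in gene orientation
      firstBase <- ifelse(as.character(strand(fgc)) == "+",
                          hits$position[r], hits$position[r] + w - 1L)
      off <- summitOffset(firstBase, fgc$startCodon,
                          as.character(strand(fgc)))
      j <- which.min(abs(off))
      hits$offset_to_start_codon[r] <- as.integer(off[j])
      hits$nearest_unit[r] <- fgc$unit_id[j]
    }
  }
  hits
}

#' Write/read a motif model file
#'
#' Versioned plain-text format: metadata lines (\code{#key value}) followed
#' by a tab-separated PWM, one row per motif position.
#'
#' @param model a \linkS4class{MotifModel}.
#' @param path file path.
#' @export
writeMotif <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#format sosmap-motif 1",
               sprintf("#width %d", model@width),
               sprintf("#consensus %s", model@consensus),
               sprintf("#background %s",
                       paste(sprintf("%.8f", model@background), collapse = " ")),
               sprintf("#occurrencePrior %.8f", model@occurrencePrior),
               sprintf("#logLikRatio %.6f", model@logLikRatio),
               paste(c("pos", BASES), collapse = "\t")), con)
  for (j in seq_len(model@width))
    writeLines(paste(c(j, sprintf("%.8f", model@pwm[, j])), collapse = "\t"),
               con)
}

#' @rdname writeMotif
#' @export
readMotif <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    ln <- meta[startsWith(meta, paste0("#", key, " "))]
    if (length(ln) != 1L) stop("malformed motif file: missing ", key)
    sub(paste0("^#", key, " "), "", ln)
  }
  if (getv("format") != "sosmap-motif 1") stop("unknown motif file format")
  w <- as.integer(getv("width"))
  bgv <- setNames(as.numeric(strsplit(getv("background"), " ")[[1]]), BASES)
  tab <- read.delim(textConnection(lines[!startsWith(lines, "#")]))
  pwmM <- t(as.matrix(tab[, BASES]))
  pwmM <- sweep(pwmM, 2, colSums(pwmM), "/")   # renormalise rounding
  dimnames(pwmM) <- list(BASES, NULL)
  new("MotifModel", width = w, pwm = pwmM, background = bgv / sum(bgv),
      consensus = getv("consensus"),
      occurrencePrior = as.numeric(getv("occurrencePrior")),
      logLik = NA_real_, logLikRatio = as.numeric(getv("logLikRatio")),
      score = NA_real_, nSeq = NA_integer_, llHistory = numeric(0))
}
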