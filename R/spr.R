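## 1:1 Langmuir kinetics for single-cycle SPR.
##
## Within a segment at analyte concentration C the response follows
##   R(t) = Req + (R0 - Req) * exp(-(ka*C + kd) * (t - t0)),
##   Req  = ka*C*rmax / (ka*C + kd),
## continuous across segment boundaries; C = 0 gives pure exponential
## dissociation.  Fitting is least squares over (ka, kd, rmax) in log space
## with multi-start Levenberg-Marquardt.

#' Closed-form 1:1 binding model response
#'
#' @param segments data.frame with columns \code{start}, \code{duration}
#'   (s) and \code{concentration} (M); segments must tile time contiguously
#'   from 0.
#' @param ka association rate constant, 1/(M s).
#' @param kd dissociation rate constant, 1/s.
#' @param rmax maximal response, RU.
#' @param times numeric sampling times (s).
#' @param r0 response at t = 0 (default 0 RU).
#' @return numeric responses at \code{times}.
#' @examples
#' seg <- data.frame(start = 0, duration = 600, concentration = 1e-8)
#' modelResponse(seg, ka = 1e5, kd = 1e-3, rmax = 50, times = c(0, 600))
#' @export
modelResponse <- function(segments, ka, kd, rmax, times, r0 = 0) {
  if (ka <= 0 || kd < 0 || rmax <= 0)
    stop("ka and rmax must be positive, kd non-negative")
  segEnd <- segments$start + segments$duration
  if (any(abs(segments$start[-1] - segEnd[-nrow(segments)]) > 1e-9))
    stop("segments must be contiguous")
  out <- numeric(length(times))
  rStart <- r0
  for (s in seq_len(nrow(segments))) {
    C <- segments$concentration[s]
    t0 <- segments$start[s]
    rate <- ka * C + kd
    req <- if (rate > 0) ka * C * rmax / rate else rStart
    inSeg <- times >= t0 - 1e-9 &
      (times < segEnd[s] - 1e-9 | s == nrow(segments))
    out[inSeg] <- req + (rStart - req) * exp(-rate * (times[inSeg] - t0))
    rStart <- req + (rStart - req) * exp(-rate * segments$duration[s])
  }
  out
}

#' @describeIn KineticFit-class association rate constant, 1/(M s).
#' @export
setMethod("ka", "KineticFit", function(x) x@ka)

#' @describeIn KineticFit-class dissociation rate constant, 1/s.
#' @export
setMethod("kd", "KineticFit", function(x) x@kd)

#' @rdname KD
#' @export
setMethod("KD", "KineticFit", function(x) x@kd / x@ka)

#' @describeIn KineticFit-class fitted maximal response, RU.
#' @export
setMethod("rmax", "KineticFit", function(x) x@rmax)

setMethod("show", "KineticFit", function(object) {
  cat(sprintf(
    "KineticFit: ka %.4g 1/(M s), kd %.4g 1/s, KD %.4g M, Rmax %.4g RU\n",
    object@ka, object@kd, object@kd / object@ka, object@rmax))
  cat(sprintf("  residual RMSE %.4g RU, converged: %s (%d starts)\n",
              object@residualRmse, object@converged, object@nStarts))
})

#' Fit 1:1 kinetics to a single-cycle sensorgram
#'
#' Least-squares fit of \code{\link{modelResponse}} over (ka, kd, rmax),
#' parameterised in log10 space with bounds ka in [1e2, 1e9] 1/(M s) and
#' kd in [1e-6, 1] 1/s, using Levenberg-Marquardt from a log-grid of
#' starting points; the best converged start wins.
#'
#' @param sg a \linkS4class{Sensorgram} with at least two segments
#'   (including a terminal dissociation) and 20 sample points.
#' @param nStarts number of multi-start initialisations (default 8).
#' @param seed optional integer seed for the start jitter.
#' @return a \linkS4class{KineticFit}.
#' @export
fitSingleCycle <- function(sg, nStarts = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(sg@segments) < 2L || length(sg@time) < 20L)
    stop("need >= 2 segments and >= 20 sample points")
  lo <- c(2, -6, log10(max(sg@response) * 1e-3 + 1e-12))
  hi <- c(9, 0, log10(max(abs(sg@response)) * 1e3 + 1))
  resid <- function(par) {
    sg@response - modelResponse(sg@segments, 10^par[1], 10^par[2],
                                10^par[3], sg@time)
  }
  kaGrid <- seq(3, 7, length.out = max(2, ceiling(nStarts / 2)))
  kdGrid <- c(-4, -2)
  starts <- cbind(rep(kaGrid, each = 2), rep(kdGrid, length(kaGrid)),
                  log10(max(abs(sg@response)) * 1.2 + 1e-9))
  starts <- starts[seq_len(min(nStarts, nrow(starts))), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid,
                         lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(par = fit$par, ssr = ssr, info = fit$info)
  }
  if (is.null(best))
    return(new("KineticFit", ka = 1, kd = 1, rmax = 1,
               residualRmse = Inf, converged = FALSE,
               nStarts = as.integer(nStarts)))
  rmse <- sqrt(best$ssr / length(sg@time))
  atBound <- any(abs(best$par - lo) < 1e-6) || any(abs(best$par - hi) < 1e-6)
  new("KineticFit", ka = 10^best$par[1], kd = 10^best$par[2],
      rmax = 10^best$par[3], residualRmse = rmse,
      converged = best$info %in% 1:3 && !atBound,
      nStarts = as.integer(nrow(starts)))
}

#' Theoretical maximal SPR response
#'
#' \eqn{R_{max} = MW_{protein} / MW_{DNA} \times RU \times n \times 0.78},
#' with RU the DNA capture response, n the binding stoichiometry and 0.78
#' the empirical constant for DNA-protein interactions.
#'
#' @param mwProtein,mwDna molar masses (Da) of analyte protein and captured
#'   DNA.
#' @param ruCaptured DNA capture response, RU.
#' @param n binding stoichiometry (default 1).
#' @param constant empirical DNA-protein constant (default 0.78).
#' @return expected maximal response, RU.
#' @examples
#' rmaxExpected(mwProtein = 2, mwDna = 1, ruCaptured = 100)   # 156
#' @export
rmaxExpected <- function(mwProtein, mwDna, ruCaptured, n = 1,
                         constant = 0.78) {
  if (any(c(mwProtein, mwDna, ruCaptured, n, constant) <= 0))
    stop("all inputs must be positive")
  mwProtein / mwDna * ruCaptured * n * constant
}

#' Observed binding as a percentage of the theoretical maximum
#'
#' @param bindingRu observed analyte binding response, RU.
#' @param rmax theoretical or fitted maximal response, RU.
#' @return \code{100 * bindingRu / rmax}.
#' @export
percentRmax <- function(bindingRu, rmax) {
  if (rmax <= 0) stop("rmax must be positive")
  100 * bindingRu / rmax
}

setMethod("show", "Sensorgram", function(object) {
  cat(sprintf("Sensorgram: %d points over %.0f s, %d segments (%d injection)\n",
              length(object@time), max(object@time), nrow(object@segments),
              sum(object@segments$concentration > 0)))
})
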