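# Dose-response analysis: dilution-series construction, vehicle
# normalization, four-parameter-logistic (4PL) fitting, normalized AUC, and
# curve-shift comparison (the readout of the cDNA re-sensitization screen).

#' Construct a geometric dilution series
#'
#' Builds the descending concentration series `max, max/fold, ...,
#' max/fold^(n-1)` used on viability plates, e.g. an 11-point 2-fold series
#' from 20 uM reaches 0.01953 uM, and a 7-point 2-fold series from 5 uM
#' reaches 0.07813 uM.
#'
#' @param maxConcentration top concentration in micromolar (> 0).
#' @param nPoints number of concentrations (>= 1).
#' @param fold dilution factor between adjacent points (> 1; default 2).
#' @return A [DoseSeries-class].
#' @examples
#' makeDilutionSeries(20, 11)   # min 0.01953 uM
#' makeDilutionSeries(5, 7)     # min 0.07813 uM
#' @export
makeDilutionSeries <- function(maxConcentration, nPoints, fold = 2) {
  if (!is.numeric(maxConcentration) || maxConcentration <= 0)
    stop("'maxConcentration' must be positive")
  if (nPoints < 1) stop("'nPoints' must be >= 1")
  if (fold <= 1) stop("'fold' must be > 1")
  conc <- maxConcentration / fold^(seq_len(nPoints) - 1)
  new("DoseSeries", maxConcentration = maxConcentration,
      nPoints = as.integer(nPoints), fold = fold, concentrations = conc)
}

#' Normalize raw viability signal to the vehicle control
#'
#' Divides each raw well signal by the mean of the vehicle (e.g. DMSO) wells,
#' mirroring ATP-luminescence viability normalization. Values above 1
#' (stimulation) are preserved; negative values (signal below blank) are
#' floored at 0.
#'
#' @param rawSignal numeric vector or matrix of treated-well signals.
#' @param vehicleSignal numeric vector of vehicle-well signals with positive
#'   mean.
#' @return relative viabilities, same shape as `rawSignal`.
#' @export
normalizeViability <- function(rawSignal, vehicleSignal) {
  vm <- mean(vehicleSignal)
  if (!is.finite(vm) || vm <= 0)
    stop("vehicle mean must be positive")
  pmax(rawSignal / vm, 0)
}

.fourPL <- function(conc, top, bottom, ec50, hill) {
  bottom + (top - bottom) / (1 + (conc / ec50)^hill)
}

#' Fit a four-parameter logistic model to viability data
#'
#' Least-squares fit of `v(c) = bottom + (top - bottom)/(1 + (c/ec50)^hill)`
#' over all replicate observations, by Levenberg-Marquardt
#' ([minpack.lm::nlsLM]). Initial values follow standard 4PL practice: top =
#' max observed, bottom = min observed, ec50 = geometric midpoint of the
#' series, hill = 1; ec50 is bounded to `[min/4, 4*max]` of the assayed
#' range. Constant data return the degenerate `top = bottom = v` fit with
#' zero residual; non-convergence returns the best iterate with
#' `converged = FALSE`.
#'
#' @param curve a [ViabilityCurves-class] with at least 4 distinct
#'   concentrations.
#' @return A [SigmoidFit-class].
#' @export
fitSigmoid <- function(curve) {
  stopifnot(is(curve, "ViabilityCurves"))
  conc <- concentrations(doseSeries(curve))
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations to fit a sigmoid")
  v <- viabilities(curve)
  x <- rep(conc, times = ncol(v))
  y <- as.vector(v)
  gmid <- exp(mean(log(range(conc))))
  if (max(y) - min(y) < .Machine$double.eps^0.5) {
    return(new("SigmoidFit", top = y[1], bottom = y[1], ec50 = gmid,
               hill = 1, residualSS = sum((y - y[1])^2), converged = TRUE))
  }
  start <- c(top = max(y), bottom = min(y), ec50 = gmid, hill = 1)
  lower <- c(top = -Inf, bottom = -Inf, ec50 = min(conc) / 4, hill = 1e-3)
  upper <- c(top = Inf, bottom = Inf, ec50 = max(conc) * 4, hill = 1e3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (x / ec50)^hill),
      start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    rss <- sum((y - .fourPL(x, start["top"], start["bottom"],
                            start["ec50"], start["hill"]))^2)
    return(new("SigmoidFit", top = unname(start["top"]),
               bottom = unname(start["bottom"]), ec50 = unname(start["ec50"]),
               hill = 1, residualSS = rss, converged = FALSE))
  }
  cf <- stats::coef(fit)
  converged <- isTRUE(fit$convInfo$isConv)
  if (cf["bottom"] > cf["top"]) {   # increasing curve; report as degenerate
    cf[c("top", "bottom")] <- cf[c("bottom", "top")]
    converged <- FALSE
  }
  new("SigmoidFit", top = unname(cf["top"]), bottom = unname(cf["bottom"]),
      ec50 = unname(cf["ec50"]), hill = unname(cf["hill"]),
      residualSS = sum(stats::resid(fit)^2), converged = converged)
}

## Trapezoid over the log-concentration axis of a geometric series: equal
## log-fold spacing reduces to (v1/2 + v2 + ... + v_{n-1} + vn/2)/(n-1).
.trapAUC <- function(v) {
  v <- pmax(v, 0)
  n <- length(v)
  if (n < 2) stop("need at least 2 points for an AUC")
  (sum(v) - (v[1] + v[n]) / 2) / (n - 1)
}

#' Normalized area under a viability curve
#'
#' Trapezoidal mean of per-concentration replicate means over the
#' log-concentration axis, normalized so a completely insensitive curve
#' (flat at viability 1) scores exactly 1. Because the dilution series is
#' geometric, equal log spacing reduces the trapezoid to
#' `(v1/2 + v2 + ... + v(n-1) + vn/2)/(n-1)`.
#'
#' @param curve a normalized [ViabilityCurves-class] with >= 2 points.
#' @return list with `auc` and `nPoints`.
#' @export
normalizedAUC <- function(curve) {
  stopifnot(is(curve, "ViabilityCurves"))
  if (!isNormalized(curve))
    stop("curve is not vehicle-normalized; apply normalizeViability() first")
  means <- rowMeans(viabilities(curve))
  list(auc = .trapAUC(means), nPoints = length(means))
}

#' Compare two viability curves by replicate-level AUC shift
#'
#' Computes one AUC per replicate (replicate j uses the j-th well at every
#' concentration) for candidate and control, then reports the mean AUC
#' difference and a Student t-test p-value across replicates. This is the
#' quantitative reading of "significantly shifted sensitivity curves" in a
#' cDNA re-sensitization panel; the caller applies [bhAdjust()] across
#' candidates.
#'
#' @param candidate,control [ViabilityCurves-class] objects on the same
#'   [DoseSeries-class] with the same replicate count (>= 2).
#' @return list with `deltaAUC` (candidate - control), `p.value`,
#'   `aucCandidate`, `aucControl` (per-replicate AUC vectors).
#' @export
compareCurves <- function(candidate, control) {
  stopifnot(is(candidate, "ViabilityCurves"), is(control, "ViabilityCurves"))
  sc <- concentrations(doseSeries(candidate))
  st <- concentrations(doseSeries(control))
  if (length(sc) != length(st) || any(abs(sc - st) > 1e-9 * pmax(sc, st)))
    stop("candidate and control must share the same dose series")
  if (ncol(viabilities(candidate)) != ncol(viabilities(control)))
    stop("candidate and control must have the same replicate count")
  if (ncol(viabilities(candidate)) < 2)
    stop("need at least 2 replicates per curve")
  if (!isNormalized(candidate) || !isNormalized(control))
    stop("curves must be vehicle-normalized")
  aucA <- apply(viabilities(candidate), 2, .trapAUC)
  aucB <- apply(viabilities(control), 2, .trapAUC)
  tt <- studentTTest(aucA, aucB)
  list(deltaAUC = mean(aucA) - mean(aucB), p.value = tt$p.value,
       aucCandidate = aucA, aucControl = aucB)
}
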