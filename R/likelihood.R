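# Monte Carlo likelihood over trajectories x genealogies, the smoothed
# likelihood curve with MLE and profile-likelihood interval, and the
# allele-age posterior.

# One importance-sampling run at a fixed s: M trajectories, K genealogies
# each. Returns per-trajectory log joint weights and ages.
isRun <- function(s, cfg, geom, theta, demog, x0, M, K,
                  model = "additive", tMax = NULL, xLinked = FALSE,
                  maxEvents = 100000L) {
  sel <- selectionModel(s, model)
  N0 <- sizeAt(demog, 0, xLinked)
  rho <- 4 * N0 * geom$gTot
  I0 <- max(1L, round(2 * N0 * x0))
  logWm <- numeric(M)
  ages <- integer(M)
  nRejTraj <- 0L
  genRej <- 0; genTot <- 0
  for (m in seq_len(M)) {
    traj <- sampleTrajectory(I0, sel, demog, tMax, xLinked)
    ages[m] <- traj@age
    wt <- trajectoryWeight(traj)
    if (!is.finite(wt)) {
      nRejTraj <- nRejTraj + 1L
      logWm[m] <- -Inf
      next
    }
    gw <- genealogyWeights(cfg, traj, geom, theta, rho, K, maxEvents)
    genTot <- genTot + K
    genRej <- genRej + sum(gw$status != 0L)
    logWm[m] <- wt + logMeanExp(gw$logWeight)
  }
  list(logWm = logWm, ages = ages, nRejTraj = nRejTraj,
       genRejRate = if (genTot) genRej / genTot else NA_real_)
}

#' Monte Carlo log-likelihood of a selection coefficient
#'
#' Estimates log L(s), the log sampling probability of the coded
#' configuration, as the log of the double average over M sampled
#' trajectories and K genealogies per trajectory of the product of the
#' trajectory and genealogy importance weights. The Monte Carlo standard
#' error of the log-likelihood is obtained by the delta method from the
#' spread of the per-trajectory means.
#'
#' @param s selection coefficient.
#' @param cfg a \linkS4class{SampleConfig} from \code{\link{encodeSample}}.
#' @param geom geometry from \code{\link{haplotypeGeometry}} (sets rho =
#'   4 N_0 times the map length).
#' @param theta scaled mutation rate of the whole haplotype.
#' @param demog a \linkS4class{Demography}.
#' @param x0 present sample frequency of the mutant.
#' @param M,K trajectory and per-trajectory genealogy counts.
#' @param model selection scheme passed to \code{\link{selectionModel}}.
#' @param tMax trajectory horizon (default 4 * 2 N_0).
#' @param xLinked use the X-linked effective size.
#' @param maxEvents per-genealogy event cap.
#' @return list(loglik, se, nRejTraj, genRejRate, M, K).
#' @export
estimateLogLik <- function(s, cfg, geom, theta, demog, x0, M, K,
                           model = "additive", tMax = NULL,
                           xLinked = FALSE, maxEvents = 100000L) {
  run <- isRun(s, cfg, geom, theta, demog, x0, M, K, model, tMax,
               xLinked, maxEvents)
  ll <- logMeanExp(run$logWm)
  se <- if (is.finite(ll) && M > 1) {
    w <- exp(run$logWm - max(run$logWm[is.finite(run$logWm)]))
    sd(w) / sqrt(M) / mean(w)
  } else Inf
  if (!is.finite(ll))
    warning("all paths rejected at s = ", s,
            ": s incompatible with the data at this sampling effort")
  list(loglik = ll, se = se, nRejTraj = run$nRejTraj,
       genRejRate = run$genRejRate, M = M, K = K)
}

#' Local-linear smoother with tricube weights
#'
#' Weighted-least-squares fit of a linear function within a local window,
#' evaluated at the target points; the bandwidth is a fraction of the span
#' of \code{x} and is widened locally so that at least three points carry
#' weight.
#'
#' @param x,y data points (non-finite y dropped).
#' @param xout evaluation points (default x).
#' @param bandwidth window half-width as a fraction of the x span.
#' @return fitted values at xout.
#' @export
localLinearSmooth <- function(x, y, xout = x, bandwidth = 0.3) {
  keep <- is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least three finite points to smooth")
  h0 <- bandwidth * diff(range(x))
  vapply(xout, function(x0) {
    d <- abs(x - x0)
    h <- max(h0, sort(d)[min(3L, length(d))] * (1 + 1e-9))
    w <- pmax(0, (1 - (d / h)^3))^3
    use <- w > 0
    X <- cbind(1, x[use] - x0)
    fit <- stats::lm.wfit(X, y[use], w[use])
    fit$coefficients[1]
  }, numeric(1))
}

#' Monte Carlo likelihood curve over a grid of selection coefficients
#'
#' Estimates the log-likelihood on a grid of s values, smooths it with the
#' tricube local-linear smoother, and extracts the MLE (argmax of the
#' smoothed curve on a fine interpolation grid) and a profile-likelihood
#' confidence interval. With \code{crn = TRUE} the same seed is re-set
#' before every grid point (common random numbers), which removes most of
#' the Monte Carlo jitter between adjacent grid points.
#'
#' @param sGrid grid of selection coefficients (>= 5 points).
#' @param cfg,geom,theta,demog,x0,M,K,model,tMax,xLinked,maxEvents as in
#'   \code{\link{estimateLogLik}}.
#' @param seed integer seed; with \code{crn} also the per-point seed.
#' @param crn use common random numbers across grid points.
#' @param bandwidth smoother bandwidth (fraction of grid span).
#' @param level confidence level of the profile interval.
#' @return A \linkS4class{LikelihoodCurve}.
#' @export
likelihoodCurve <- function(sGrid, cfg, geom, theta, demog, x0, M, K,
                            model = "additive", tMax = NULL,
                            xLinked = FALSE, seed = NULL, crn = TRUE,
                            bandwidth = 0.3, level = 0.95,
                            maxEvents = 100000L) {
  if (length(sGrid) < 5) stop("grid must have at least 5 points")
  sGrid <- sort(sGrid)
  if (!is.null(seed)) set.seed(seed)
  ll <- se <- numeric(length(sGrid))
  for (i in seq_along(sGrid)) {
    if (crn && !is.null(seed)) set.seed(seed)
    est <- estimateLogLik(sGrid[i], cfg, geom, theta, demog, x0, M, K,
                          model, tMax, xLinked, maxEvents)
    ll[i] <- est$loglik; se[i] <- est$se
  }
  sm <- rep(NA_real_, length(sGrid))
  fin <- is.finite(ll)
  if (sum(fin) >= 3)
    sm[fin] <- localLinearSmooth(sGrid[fin], ll[fin], sGrid[fin], bandwidth)
  curve <- new("LikelihoodCurve",
               grid = data.frame(s = sGrid, loglik = ll, se = se,
                                 smooth = sm),
               sHat = NA_real_, ci = c(NA_real_, NA_real_),
               level = level, M = as.integer(M), K = as.integer(K),
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
               bandwidth = bandwidth)
  est <- mleCI(curve, level)
  curve@sHat <- est[1]; curve@ci <- est[2:3]
  curve
}

#' MLE and profile-likelihood interval from a likelihood curve
#'
#' The smoothed curve is evaluated on a fine grid; the MLE is its argmax and
#' the interval is \{s : loglik(sHat) - loglik(s) <= qchisq(level, 1) / 2\}
#' by interpolation. Endpoints outside the grid are clamped with a warning;
#' a non-unimodal smoothed curve yields the widest bracket with a warning.
#'
#' @param curve a \linkS4class{LikelihoodCurve}.
#' @param level confidence level.
#' @return c(sHat, lower, upper).
#' @export
mleCI <- function(curve, level = 0.95) {
  g <- curve@grid
  fin <- is.finite(g$loglik)
  if (sum(fin) < 3) return(c(NA_real_, NA_real_, NA_real_))
  x <- g$s[fin]; y <- g$loglik[fin]
  fine <- seq(min(x), max(x), length.out = 512)
  sm <- localLinearSmooth(x, y, fine, curve@bandwidth)
  iMax <- which.max(sm)
  sHat <- fine[iMax]
  dips <- sum(diff(sign(diff(sm))) == 2)
  if (dips > 0)
    warning("smoothed curve is not unimodal; taking the widest bracket")
  cut <- sm[iMax] - stats::qchisq(level, 1) / 2
  inside <- which(sm >= cut)
  lo <- fine[min(inside)]; hi <- fine[max(inside)]
  if (min(inside) == 1L || max(inside) == length(fine))
    warning("profile interval endpoint clamped to the grid edge")
  c(sHat, lo, hi)
}

#' @export
setMethod("show", "LikelihoodCurve", function(object) {
  cat(sprintf(
    "LikelihoodCurve: %d grid points, M = %d, K = %d\n  sHat = %.4g, %d%% CI (%.4g, %.4g)\n",
    nrow(object@grid), object@M, object@K, object@sHat,
    round(100 * object@level), object@ci[1], object@ci[2]))
})

#' Maximum-likelihood estimate of the selection coefficient
#' @param curve a \linkS4class{LikelihoodCurve}.
#' @return sHat.
#' @export
sHat <- function(curve) curve@sHat

#' Posterior distribution of the allele age at a fixed s
#'
#' Each sampled trajectory contributes its age T with weight equal to the
#' trajectory importance weight times the mean genealogy weight, normalized
#' over trajectories.
#'
#' @param s selection coefficient (usually the MLE).
#' @param cfg,geom,theta,demog,x0,M,K,model,tMax,xLinked as in
#'   \code{\link{estimateLogLik}}.
#' @return An \linkS4class{AgePosterior}.
#' @export
agePosterior <- function(s, cfg, geom, theta, demog, x0, M, K,
                         model = "additive", tMax = NULL,
                         xLinked = FALSE) {
  run <- isRun(s, cfg, geom, theta, demog, x0, M, K, model, tMax, xLinked)
  fin <- is.finite(run$logWm)
  if (!any(fin)) stop("zero total weight: no accepted paths at s = ", s)
  w <- exp(run$logWm[fin] - logSumExp(run$logWm[fin]))
  samples <- data.frame(age = run$ages[fin], weight = w)
  agg <- stats::aggregate(weight ~ age, samples, sum)
  new("AgePosterior", samples = agg[order(agg$age), ], s = s)
}

#' Summary statistics of an age posterior
#' @param post an \linkS4class{AgePosterior}.
#' @param probs quantiles to report.
#' @return named vector with mode, mean and the requested quantiles (in
#'   generations).
#' @export
ageSummary <- function(post, probs = c(0.025, 0.5, 0.975)) {
  s <- post@samples
  cw <- cumsum(s$weight)
  qs <- vapply(probs, function(p) s$age[which(cw >= p)[1]], numeric(1))
  c(mode = s$age[which.max(s$weight)],
    mean = sum(s$age * s$weight),
    stats::setNames(qs, paste0("q", probs)))
}

#' @export
setMethod("show", "AgePosterior", function(object) {
  sm <- ageSummary(object)
  cat(sprintf(
    "AgePosterior at s = %.4g: mean %.0f, mode %.0f, 95%% (%.0f, %.0f) generations\n",
    object@s, sm["mean"], sm["mode"], sm["q0.025"], sm["q0.975"]))
})
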