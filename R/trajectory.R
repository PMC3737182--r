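# Backward Wright-Fisher trajectory sampling with selection and demography,
# forward path probabilities and trajectory importance weights.

#' Deterministic one-generation selection map
#'
#' Frequency after selection given frequency \code{x} before selection under
#' genotype fitnesses (1, 1 + s2, 1 + s1).
#'
#' @param x allele frequency in [0, 1] (vectorized).
#' @param sel a \linkS4class{SelectionModel}.
#' @return the post-selection frequency.
#' @export
forwardSelectionMap <- function(x, sel) {
  s1 <- sel@s1; s2 <- sel@s2
  x * (1 + s1 * x + s2 * (1 - x)) / (1 + s1 * x^2 + 2 * s2 * x * (1 - x))
}

#' Inverse of the selection map
#'
#' The unique root Y' in [0, 1] with forwardSelectionMap(Y') = y: closed-form
#' quadratic under genic (additive) selection, monotone bisection otherwise.
#'
#' @param y target post-selection frequency (vectorized).
#' @param sel a \linkS4class{SelectionModel}.
#' @return the pre-selection frequency.
#' @export
selectionInverse <- function(y, sel) {
  s1 <- sel@s1; s2 <- sel@s2
  if (abs(s1) < 1e-14 && abs(s2) < 1e-14) return(y)
  out <- numeric(length(y))
  inner <- y > 0 & y < 1
  out[y >= 1] <- 1
  if (abs(s1 - 2 * s2) < 1e-12 && s2 > 1e-14) {
    sig <- s2
    b <- 1 + sig - 2 * sig * y[inner]
    out[inner] <- (-b + sqrt(b^2 + 4 * sig * y[inner])) / (2 * sig)
  } else {
    lo <- rep(0, sum(inner)); hi <- rep(1, sum(inner))
    yy <- y[inner]
    for (it in 1:100) {
      mid <- (lo + hi) / 2
      below <- forwardSelectionMap(mid, sel) < yy
      lo[below] <- mid[below]; hi[!below] <- mid[!below]
    }
    out[inner] <- (lo + hi) / 2
  }
  out
}

#' One backward Wright-Fisher step
#'
#' Given \code{Iprev} copies among 2 N_{t-1} chromosomes, draws the copy
#' number at generation t (one generation further into the past) as
#' Binomial(2 N_t, Y') where Y' inverts the selection map at
#' Iprev / (2 N_{t-1}).
#'
#' @param Iprev copy number at generation t - 1.
#' @param t target generation.
#' @param sel a \linkS4class{SelectionModel}.
#' @param demog a \linkS4class{Demography}.
#' @param xLinked use the X-linked effective size.
#' @return list with the draw \code{I} and its log-probability.
#' @export
backwardStep <- function(Iprev, t, sel, demog, xLinked = FALSE) {
  twoNprev <- round(2 * sizeAt(demog, t - 1, xLinked))
  twoN <- round(2 * sizeAt(demog, t, xLinked))
  stopifnot(Iprev > 0, Iprev <= twoNprev)
  yp <- selectionInverse(Iprev / twoNprev, sel)
  draw <- rbinom(1, twoN, yp)
  list(I = draw, logProb = dbinom(draw, twoN, yp, log = TRUE))
}

#' Sample an allele-frequency trajectory backward in time
#'
#' Iterates the backward binomial step from \code{I0} copies at present until
#' the allele is lost; the loss generation is the allele age T. Paths longer
#' than \code{tMax} are rejected (status "tmax", weight zero).
#'
#' @param I0 copy number at present (1 <= I0 <= 2 N_0).
#' @param sel a \linkS4class{SelectionModel}.
#' @param demog a \linkS4class{Demography}.
#' @param tMax horizon in generations (default 4 * 2 N_0).
#' @param xLinked use the X-linked effective size.
#' @return A \linkS4class{SweepTrajectory}.
#' @export
sampleTrajectory <- function(I0, sel, demog, tMax = NULL, xLinked = FALSE) {
  N0 <- sizeAt(demog, 0, xLinked)
  if (is.null(tMax)) tMax <- ceiling(8 * N0)
  stopifnot(I0 >= 1, I0 <= round(2 * N0))
  N <- sizeAt(demog, 0:tMax, xLinked)
  res <- traj_sample_cpp(as.integer(I0), sel@s1, sel@s2, N, as.integer(tMax))
  I <- res$I
  Tage <- length(I) - 1L
  Nt <- N[seq_len(length(I))]
  if (res$status == "tmax") {
    return(new("SweepTrajectory", I = I, N = Nt, age = Tage,
               logPB = res$logPB, logPF = -Inf, logWeight = -Inf,
               status = "tmax"))
  }
  traj <- new("SweepTrajectory", I = I, N = Nt, age = Tage,
              logPB = res$logPB, logPF = 0, logWeight = 0, status = "ok")
  traj@logPF <- forwardLogProb(traj, sel)
  traj@logWeight <- traj@logPF - traj@logPB + log(2 * Nt[length(Nt)])
  traj
}

#' Forward log-probability of a trajectory
#'
#' Product over generations of Binomial(I_{t-1}; 2 N_{t-1}, X'_t), X' the
#' post-selection frequency; the founding factor is 1 iff the path starts
#' from a single copy (otherwise the path has weight zero).
#'
#' @param traj a \linkS4class{SweepTrajectory}.
#' @param sel a \linkS4class{SelectionModel}.
#' @return log-probability (possibly -Inf).
#' @export
forwardLogProb <- function(traj, sel) {
  I <- traj@I; N <- traj@N
  Tage <- length(I) - 1L
  if (I[Tage + 1L] != 0L) stop("trajectory must end at loss")
  if (I[Tage] != 1L) return(-Inf)
  if (Tage == 1L) return(0)
  t <- seq(Tage - 1L, 1L)              # generations T-1 .. 1
  twoN <- round(2 * N[t + 1L])
  xp <- forwardSelectionMap(I[t + 1L] / twoN, sel)
  sum(dbinom(I[t], round(2 * N[t]), xp, log = TRUE))
}

#' Trajectory importance weight
#'
#' log of forward over backward path probability plus log(2 N_T), the
#' chromosome count at the first generation after loss (the influx of new
#' mutations is proportional to it).
#'
#' @param traj a \linkS4class{SweepTrajectory}.
#' @return the log importance weight.
#' @export
trajectoryWeight <- function(traj) traj@logWeight

#' @export
setMethod("show", "SweepTrajectory", function(object) {
  cat(sprintf(
    "SweepTrajectory: age T = %d generations, I0 = %d, status = %s\n",
    object@age, object@I[1], object@status))
})

#' Allele age of a trajectory
#' @param traj a \linkS4class{SweepTrajectory}.
#' @return T in generations.
#' @export
alleleAge <- function(traj) traj@age
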