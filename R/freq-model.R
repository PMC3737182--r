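# Expected ancestral-haplotype-class frequencies along a trajectory and the
# recombination transition model between coded classes.
#
# The class (R1, R2) collects selected chromosomes whose retained ancestral
# segment extends exactly R1 SNPs left and R2 SNPs right of the mutant. The
# expected frequency of the class among selected chromosomes at generation t
# is modeled through per-side survival of the segment against crossovers
# with background chromosomes: a lineage sampled in the selected class at t
# retains at least a SNPs on one side iff no background crossover hit the
# span g(a) during the meioses between t and the founding generation T - 1,
# with per-generation escape probability ~ g(a) * (1 - X_u). Sides are
# treated as independent and class probabilities are obtained by
# differencing adjacent "at least" extents.

# accumulated escape load C_t = sum_{u = t+1}^{T-1} (1 - X_u); C_{T-1} = 0 so
# the founder class has probability 1 at the founding generation.
escapeLoad <- function(traj) {
  Tage <- traj@age
  x <- traj@I[seq_len(Tage)] / (2 * traj@N[seq_len(Tage)]) # X_v, v = 0..T-1
  w <- 1 - x
  # C[v + 1] = sum of w at generations v+1 .. T-1
  rev(cumsum(rev(c(w[-1L], 0))))
}

# bundle of everything the ancestral process needs from one trajectory
frequencyModel <- function(traj, geom) {
  Tage <- traj@age
  idx <- seq_len(Tage)
  list(geom = geom,
       Tage = Tage,
       X = traj@I[idx] / (2 * traj@N[idx]),
       invI = 1 / traj@I[idx],
       Ct = escapeLoad(traj),
       N0 = traj@N[1])
}

# survival of at least `a` retained SNPs on one side at generation v (0-based)
atLeastSurvival <- function(a, side = c("left", "right"), v, fm) {
  side <- match.arg(side)
  g <- if (side == "left") fm$geom$gL else fm$geom$gR
  exp(-g[a + 1L] * fm$Ct[v + 1L])
}

#' Expected frequency of an ancestral-haplotype class
#'
#' The deterministic expectation of the frequency, among selected
#' chromosomes at generation \code{t}, of the class whose retained segment
#' extends exactly (R1, R2) SNPs around the mutant. Over the partition of
#' all (m_L + 1)(m_R + 1) classes the frequencies sum to 1.
#'
#' @param h a \linkS4class{CodedHaplotype} (only R1, R2 are used).
#' @param t generation, 0 <= t <= T - 1 (the founding generation).
#' @param traj a \linkS4class{SweepTrajectory}.
#' @param geom geometry from \code{\link{haplotypeGeometry}}.
#' @return the class frequency in [0, 1].
#' @export
classFrequency <- function(h, t, traj, geom) {
  if (t > traj@age - 1L) stop("t beyond the founding generation of the trajectory")
  fm <- frequencyModel(traj, geom)
  classFrequencyFM(h@R1, h@R2, t, fm)
}

classFrequencyFM <- function(R1, R2, v, fm) {
  mL <- fm$geom$mL; mR <- fm$geom$mR
  sL <- atLeastSurvival(R1, "left", v, fm)
  dLv <- if (R1 < mL) sL - atLeastSurvival(R1 + 1L, "left", v, fm) else sL
  sR <- atLeastSurvival(R2, "right", v, fm)
  dRv <- if (R2 < mR) sR - atLeastSurvival(R2 + 1L, "right", v, fm) else sR
  dLv * dRv
}

#' Recombination transition distribution from a coded class
#'
#' Backward in time a lineage of class h jumps, at a crossover, to the
#' class of the parent chromosome at that event: every single-coordinate
#' change h' (an extension past the current breakpoint, crossing the
#' breakpoint interval, or a shrink to a smaller coordinate, crossing the
#' interval at the new breakpoint) has raw weight r(interval crossed) *
#' P_[h'](v) * X_v, normalized over all reachable targets. Targets
#' differing in more than one coordinate have probability 0 (no double
#' cross-overs), as do crossovers with background chromosomes (the
#' dropped (1 - X) terms).
#'
#' @param h a \linkS4class{CodedHaplotype}.
#' @param v generation.
#' @param traj a \linkS4class{SweepTrajectory}.
#' @param geom geometry from \code{\link{haplotypeGeometry}}.
#' @return data.frame with columns side, newR, p (p sums to 1), w.
#' @export
recombTransitionProbs <- function(h, v, traj, geom) {
  fm <- frequencyModel(traj, geom)
  recombTransitionsFM(h, v, fm)
}

recombTransitionsFM <- function(h, v, fm) {
  geom <- fm$geom
  side <- character(); newR <- integer(); w <- numeric()
  if (geom$mL > 0L) {
    a <- setdiff(0:geom$mL, h@R1)
    rint <- geom$bpL[pmin(a, h@R1) + 1L]
    side <- c(side, rep("left", length(a))); newR <- c(newR, a)
    w <- c(w, rint * vapply(a, function(aa)
      classFrequencyFM(aa, h@R2, v, fm), numeric(1)) * fm$X[v + 1L])
  }
  if (geom$mR > 0L) {
    b <- setdiff(0:geom$mR, h@R2)
    rint <- geom$bpR[pmin(b, h@R2) + 1L]
    side <- c(side, rep("right", length(b))); newR <- c(newR, b)
    w <- c(w, rint * vapply(b, function(bb)
      classFrequencyFM(h@R1, bb, v, fm), numeric(1)) * fm$X[v + 1L])
  }
  keep <- w > 0
  df <- data.frame(side = side[keep], newR = newR[keep], w = w[keep],
                   stringsAsFactors = FALSE)
  df$p <- if (nrow(df)) df$w / sum(df$w) else numeric()
  df[, c("side", "newR", "p", "w")]
}

#' Dump the class-frequency surface to a TSV file
#'
#' Debug helper: expected class frequencies for every (R1, R2) class at a
#' set of generations.
#'
#' @param traj a \linkS4class{SweepTrajectory}.
#' @param geom geometry.
#' @param file output path.
#' @param at generations to tabulate (default 10 equally spaced).
#' @return invisibly, the data.frame written.
#' @export
dumpClassFrequencies <- function(traj, geom, file,
                                 at = unique(round(seq(0, traj@age - 1,
                                                       length.out = 10)))) {
  fm <- frequencyModel(traj, geom)
  grid <- expand.grid(t = at, R1 = 0:geom$mL, R2 = 0:geom$mR)
  grid$P <- mapply(function(t, a, b) classFrequencyFM(a, b, t, fm),
                   grid$t, grid$R1, grid$R2)
  write.table(grid, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(grid)
}
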