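# Exact two-locus oracle: dynamic programming over the backward ancestral
# process of (q1, q2) = (founder-type, recombinant-type) selected lineages
# at a single linked marker, conditional on a trajectory. This solves the
# same discrete-time chain the importance sampler targets (per-generation
# hazard gamma / (2 N_0), conditional move probabilities term / (2 gamma),
# founder singleton absorbing with value 1), so its value equals the
# expected importance-sampling weight exactly; it anchors the sampler's
# unbiasedness tests.

#' Exact two-locus sampling probability by dynamic programming
#'
#' State (q1, q2): numbers of selected lineages carrying / not carrying the
#' ancestral allele at one marker at genetic distance \code{r} (Morgans)
#' from the selected site. Events: coalescence within either type and the
#' backward recombination move of a recombinant lineage onto the founder
#' class. Absorbing states: a single founder lineage (probability mass 1)
#' and a single recombinant lineage (a dead end, mass 0).
#'
#' @param q1 number of founder-type (marker-ancestral) lineages at t = 0.
#' @param q2 number of recombinant-type lineages at t = 0.
#' @param traj a \linkS4class{SweepTrajectory}.
#' @param r recombination fraction between the selected site and the marker
#'   (Morgans).
#' @return the exact probability of observing (q1, q2).
#' @export
twoLocusOracle <- function(q1, q2, traj, r) {
  n <- q1 + q2
  if (n > 12) stop("state space too large (n > 12); use the importance sampler")
  if (n < 1) stop("empty configuration")
  N0 <- traj@N[1]
  Tage <- traj@age
  I <- traj@I
  rho <- 4 * N0 * r
  # states indexed [a + 1, b + 1], a = founder-type count, b = recombinant
  V <- matrix(0, n + 1L, n + 1L)
  V[2L, 1L] <- 1                                  # (1, 0) absorbing
  states <- expand.grid(a = 0:n, b = 0:n)
  states <- as.matrix(states[states$a + states$b >= 1 &
                             states$a + states$b <= n, ]) + 1L
  if (Tage >= 2L) for (t in seq(Tage - 2L, 0L)) {
    u <- t + 1L                                   # generation of next event
    Vn <- V
    for (row in seq_len(nrow(states))) {
      a <- states[row, 1] - 1L; b <- states[row, 2] - 1L
      nn <- a + b
      if (nn < 1L || (a == 1L && b == 0L)) next
      invLX <- 2 * N0 / I[u + 1L]
      gam <- 0.5 * nn * (nn - 1L) * invLX + 0.5 * rho * a  # beta: 1 and 0
      if (gam <= 0) { Vn[a + 1L, b + 1L] <- V[a + 1L, b + 1L]; next }
      hz <- min(1, 0.5 * nn * (nn - 1L) / I[u + 1L] + rho * a / (4 * N0))
      acc <- 0
      if (a >= 2L) acc <- acc + nn * (a - 1L) * invLX / (2 * gam) * V[a, b + 1L]
      if (b >= 2L) acc <- acc + nn * (b - 1L) * invLX / (2 * gam) * V[a + 1L, b]
      if (b >= 1L) acc <- acc + rho * (a + 1L) / (2 * gam) * V[a + 2L, b]
      Vn[a + 1L, b + 1L] <- (1 - hz) * V[a + 1L, b + 1L] + hz * acc
    }
    Vn[2L, 1L] <- 1
    V <- Vn
  }
  V[q1 + 1L, q2 + 1L]
}
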