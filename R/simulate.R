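# Forward sweep-data simulator with known truth: a Wright-Fisher trajectory
# conditioned on reaching the present frequency, backward tracing of the
# selected lineages (coalescence, segment escape by recombination with the
# background, new mutations on retained segments), and background alleles
# from i.i.d. per-site frequencies.

# Forward trajectory from a single copy until the count first reaches
# `target`, retried until success.
conditionedTrajectory <- function(sel, N, target, maxAttempts = 100000L,
                                  horizon = NULL) {
  twoN <- round(2 * N)
  if (is.null(horizon)) horizon <- 8L * twoN
  for (att in seq_len(maxAttempts)) {
    I <- integer(horizon)
    cur <- 1L
    I[1] <- cur
    t <- 1L
    while (cur > 0L && cur < target && t < horizon) {
      xp <- forwardSelectionMap(cur / twoN, sel)
      cur <- rbinom(1L, twoN, xp)
      t <- t + 1L
      I[t] <- cur
    }
    if (cur >= target) return(rev(c(0L, I[seq_len(t)])))
  }
  stop("trajectory retry budget exhausted (", maxAttempts, " attempts)")
}

#' Simulate a sweep dataset with known truth
#'
#' Generates (i) an allele-frequency trajectory of the selected mutant from
#' one copy to present frequency x0 by conditioned forward simulation;
#' (ii) the genealogy of the selected sample lineages backward along the
#' trajectory, with pairwise coalescence hazard 1/I_t per generation,
#' per-side segment escape at rate (genetic extent) x (1 - X_t), and new
#' mutations on retained segments at rate mu * beta, each creating its own
#' segregating site (infinitely-many-sites); (iii) background alleles at
#' the base markers from i.i.d. per-site frequencies (Uniform(0,1) draws).
#' Base markers are placed uniformly in genetic distance; mutation sites
#' fall at their continuous genetic positions.
#'
#' @param s selection coefficient (additive by default).
#' @param N constant diploid population size.
#' @param theta,rho scaled mutation and recombination rates (4 N mu, 4 N c)
#'   of the whole analyzed haplotype.
#' @param x0 present frequency of the selected allele.
#' @param nSample total sample size (selected rows = round(nSample * x0)).
#' @param mL,mR number of base markers left/right of the selected site.
#' @param model selection scheme.
#' @param regionBp physical length of the region in bp.
#' @param maxAttempts trajectory retry budget.
#' @return A \linkS4class{SweepDataset}.
#' @export
simulateSweepDataset <- function(s, N, theta, rho, x0, nSample,
                                 mL = 12L, mR = 12L, model = "additive",
                                 regionBp = 5e5, maxAttempts = 100000L) {
  stopifnot(s > 0 || model != "additive", N >= 1, x0 > 0, x0 < 1,
            nSample >= 2)
  sel <- selectionModel(s, model)
  twoN <- round(2 * N)
  target <- round(twoN * x0)
  I <- conditionedTrajectory(sel, N, target, maxAttempts)
  # backward orientation: I[1] = I_0 (present) ... I[T+1] = 0
  Tage <- length(I) - 1L
  X <- I / twoN

  cTot <- rho / (4 * N)             # Morgans across the region
  gMut <- cTot * mL / (mL + mR)     # genetic distance mutant -> left edge
  gMaxL <- gMut; gMaxR <- cTot - gMut
  nSel <- round(nSample * x0)
  mu <- theta / (4 * N)

  # per-sample retained genetic extents (Morgans; Inf = uncut side) and
  # mutation events
  minL <- rep(Inf, nSel); minR <- rep(Inf, nSel)
  lineages <- lapply(seq_len(nSel), identity)   # descendant index sets
  mutSide <- character(); mutDist <- numeric(); mutCarriers <- list()
  for (u in seq_len(max(Tage - 1L, 0L))) {      # generations 1 .. T-1
    L <- length(lineages)
    # coalescence among selected lineages, pair hazard 1 / I_u
    while (L > 1L && runif(1) < min(1, choose(L, 2) / I[u + 1L])) {
      pair <- sample.int(L, 2L)
      lineages[[pair[1]]] <- c(lineages[[pair[1]]], lineages[[pair[2]]])
      lineages[[pair[2]]] <- NULL
      L <- L - 1L
    }
    if (u == Tage - 1L && L > 1L) {             # founding: all merge
      lineages <- list(unlist(lineages))
      L <- 1L
    }
    bg <- 1 - X[u + 1L]
    for (l in seq_len(L)) {
      ds <- lineages[[l]]
      eL <- min(max(minL[ds]), gMaxL)
      eR <- min(max(minR[ds]), gMaxR)
      if (eL > 0 && runif(1) < eL * bg) {
        cut <- runif(1, 0, eL)
        minL[ds] <- pmin(minL[ds], cut)
      }
      if (eR > 0 && runif(1) < eR * bg) {
        cut <- runif(1, 0, eR)
        minR[ds] <- pmin(minR[ds], cut)
      }
      if (mu > 0 && runif(1) < mu * (eL + eR) / cTot) {
        # a new site at a uniform genetic position on the retained segment
        pos <- runif(1, 0, eL + eR)
        if (pos < eL) {
          carriers <- ds[minL[ds] > pos]
          if (length(carriers)) {
            mutSide <- c(mutSide, "left"); mutDist <- c(mutDist, pos)
            mutCarriers <- c(mutCarriers, list(carriers))
          }
        } else {
          pos <- pos - eL
          carriers <- ds[minR[ds] > pos]
          if (length(carriers)) {
            mutSide <- c(mutSide, "right"); mutDist <- c(mutDist, pos)
            mutCarriers <- c(mutCarriers, list(carriers))
          }
        }
      }
    }
  }

  # assemble the site list: base markers uniform in genetic distance plus
  # one site per sweep-era mutation at its genetic position
  gBase <- seq(0, cTot, length.out = mL + mR + 1L)   # from left edge
  gMutAbs <- ifelse(mutSide == "left", gMut - mutDist, gMut + mutDist)
  gAll <- c(gBase, gMutAbs)
  isMut <- c(rep(FALSE, length(gBase)), rep(TRUE, length(gMutAbs)))
  mutIdx <- c(rep(NA_integer_, length(gBase)), seq_along(gMutAbs))
  ord <- order(gAll, isMut)        # base markers first among ties
  gAll <- gAll[ord]; isMut <- isMut[ord]; mutIdx <- mutIdx[ord]
  # drop coincident positions (probability-zero ties)
  keep <- !duplicated(signif(gAll, 12))
  gAll <- gAll[keep]; isMut <- isMut[keep]; mutIdx <- mutIdx[keep]
  m <- length(gAll)
  j0 <- which(!isMut)[mL + 1L]
  positions <- 1 + gAll / max(cTot, .Machine$double.eps) * (regionBp - 1)
  positions <- round(positions)
  while (any(duplicated(positions)))
    positions[duplicated(positions)] <- positions[duplicated(positions)] + 1L
  map <- recombMap(positions, gAll * 100)

  # ancestral haplotype and background frequencies; mutation sites are
  # absent from the background and ancestral state 0
  bgFreq <- runif(m)
  bgFreq[isMut] <- 0
  anc <- rbinom(m, 1L, bgFreq)
  anc[isMut] <- 0L
  anc[j0] <- 1L
  bgFreq[j0] <- 0

  gDist <- gAll - gMut                  # signed distance from the mutant
  alle <- matrix(0L, nSample, m)
  mask <- matrix(FALSE, nSample, m)
  for (i in seq_len(nSel)) {
    inblk <- (gDist < 0 & -gDist < minL[i]) | (gDist > 0 & gDist < minR[i])
    inblk[j0] <- TRUE
    alle[i, ] <- rbinom(m, 1L, bgFreq)
    alle[i, inblk] <- anc[inblk]
    mask[i, ] <- inblk
    alle[i, j0] <- 1L
  }
  for (k in seq_along(mutCarriers)) {
    col <- which(mutIdx == k)
    if (length(col) != 1L) next
    alle[mutCarriers[[k]], col] <- 1L
  }
  if (nSample > nSel) {
    for (i in (nSel + 1L):nSample) {
      alle[i, ] <- rbinom(m, 1L, bgFreq)
      alle[i, j0] <- 0L
    }
  }
  new("SweepDataset", alleles = alle, mask = mask,
      positions = as.numeric(positions), mutantCol = as.integer(j0),
      nSelected = as.integer(nSel), map = map,
      truth = list(s = s, age = Tage, I = I, theta = theta, rho = rho,
                   N = N, x0 = x0, ancestral = anc, bgFreq = bgFreq))
}

#' Selected haplotypes of a simulated dataset
#'
#' @param ds a \linkS4class{SweepDataset}.
#' @return A \linkS4class{HaplotypeMatrix} of the selected rows.
#' @export
selectedHaplotypes <- function(ds) {
  idx <- seq_len(ds@nSelected)
  haplotypeMatrix(ds@alleles[idx, , drop = FALSE],
                  ds@mask[idx, , drop = FALSE],
                  ds@positions, ds@mutantCol, byIndex = TRUE)
}

#' @export
setMethod("show", "SweepDataset", function(object) {
  cat(sprintf(
    "SweepDataset: %d haplotypes (%d selected) x %d SNPs; true s = %g, age = %d\n",
    nrow(object@alleles), object@nSelected, ncol(object@alleles),
    object@truth$s, object@truth$age))
})
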