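# Event rates of the backward process: the total rate gamma, the proposal
# total rate hbar, and the enumeration of all candidate events with their
# proposal and target probabilities. This R implementation is the reference
# against which the compiled sampler is cross-checked.

configBetas <- function(cfg, geom)
  vapply(cfg@types, ancestralFraction, numeric(1), geom = geom)

#' Total event rate gamma(v, n)
#'
#' C(n,2) / (lambda_v X_v) + sum_i theta_i / 2 + sum_i rho_i / 2, in events
#' per 2 N_0 generations, with per-haplotype rates theta_i = theta * beta_i
#' and rho_i = rho * beta_i.
#'
#' @param cfg a \linkS4class{SampleConfig}.
#' @param v generation.
#' @param traj a \linkS4class{SweepTrajectory}.
#' @param geom geometry.
#' @param theta,rho scaled mutation and recombination rates of the whole
#'   haplotype (4 N_0 mu, 4 N_0 c).
#' @return gamma.
#' @export
totalRateGamma <- function(cfg, v, traj, geom, theta, rho) {
  n <- configSize(cfg)
  lamX <- traj@I[v + 1L] / (2 * traj@N[1])    # lambda_v X_v
  if (lamX <= 0 && n >= 2)
    stop("X_v = 0 with n >= 2: trajectory incompatible with configuration")
  betas <- configBetas(cfg, geom)
  sumBeta <- sum(cfg@mult * betas)
  coal <- if (n >= 2) choose(n, 2) / lamX else 0
  coal + (theta + rho) * sumBeta / 2
}

#' Event-type probabilities at time v
#'
#' The shares of gamma attributable to mutation, recombination and
#' coalescence; they sum to 1.
#'
#' @inheritParams totalRateGamma
#' @return named numeric vector (mutation, recombination, coalescence).
#' @export
eventTypeProbs <- function(cfg, v, traj, geom, theta, rho) {
  n <- configSize(cfg)
  lamX <- traj@I[v + 1L] / (2 * traj@N[1])
  sumBeta <- sum(cfg@mult * configBetas(cfg, geom))
  g <- totalRateGamma(cfg, v, traj, geom, theta, rho)
  c(mutation = theta * sumBeta / 2 / g,
    recombination = rho * sumBeta / 2 / g,
    coalescence = if (n >= 2) choose(n, 2) / lamX / g else 0)
}

#' Enumerate all candidate events of the proposal distribution
#'
#' Lists every event reachable from the configuration at generation v with
#' its term in hbar, its proposal probability term / hbar, and the forward
#' (target-chain) probability computed two independent ways: directly from
#' the event-type decomposition, and as term / (2 gamma). The per-step
#' importance weight forward / proposal equals hbar / (2 gamma) for every
#' event kind.
#'
#' @inheritParams totalRateGamma
#' @param dual also compute the independent event-type-decomposition route
#'   for the forward probability (column forwardAlt; slower).
#' @return data.frame with one row per candidate event and attributes
#'   \code{hbar}, \code{gamma}.
#' @export
enumerateEvents <- function(cfg, v, traj, geom, theta, rho, dual = FALSE) {
  fm <- frequencyModel(traj, geom)
  n <- configSize(cfg)
  betas <- configBetas(cfg, geom)
  invLX <- 2 * traj@N[1] / traj@I[v + 1L]
  keys <- vapply(cfg@types, hapKey, character(1))
  rows <- list()
  add <- function(kind, i, j, side, newR, term)
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, i = i, j = j, side = side, newR = newR, term = term,
      stringsAsFactors = FALSE)
  for (k in seq_along(cfg@types)) {
    if (cfg@mult[k] >= 2)
      add("coalescence", k, NA, NA_character_, NA, n * (cfg@mult[k] - 1) * invLX)
  }
  if (theta > 0) {
    for (k in seq_along(cfg@types)) {
      if (cfg@mult[k] != 1L || !length(cfg@types[[k]]@M)) next
      sh <- shiftFirstMutation(cfg@types[[k]])
      j <- match(hapKey(sh), keys)
      if (is.na(j)) add("mutation_shift", k, NA, NA_character_, NA,
                       theta * betas[k])
      else add("mutation_merge", k, j, NA_character_, NA,
               theta * (cfg@mult[j] + 1) * betas[j])
    }
  }
  if (rho > 0) {
    for (k in seq_along(cfg@types)) {
      tp <- recombTransitionsFM(cfg@types[[k]], v, fm)
      if (!nrow(tp)) next
      for (q in seq_len(nrow(tp))) {
        h2 <- coordinateChange(cfg@types[[k]], tp$side[q], tp$newR[q],
                               geom$mutantCol)
        jt <- match(hapKey(h2), keys)
        ntgt <- if (is.na(jt)) 0L else cfg@mult[jt]
        bT <- ancestralFraction(h2, geom)
        add("recombination", k, NA, tp$side[q], tp$newR[q],
            bT * rho * (ntgt + 1) * tp$p[q])
      }
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), i = integer(), j = integer(),
               side = character(), newR = integer(), term = numeric())
  hbar <- sum(ev$term)
  g <- totalRateGamma(cfg, v, traj, geom, theta, rho)
  ev$proposal <- if (hbar > 0) ev$term / hbar else numeric(nrow(ev))
  ev$forward <- ev$term / (2 * g)
  if (dual)
    ev$forwardAlt <- forwardProbAlt(ev, cfg, v, traj, geom, theta, rho, g)
  attr(ev, "hbar") <- hbar
  attr(ev, "gamma") <- g
  ev
}

# Independent assembly of the forward (target-chain) step probability via
# the event-type decomposition: P(event kind at v) from the rates of the
# one-step-more-ancient configuration, times the within-kind choice
# probability. Used to cross-check the term/(2 gamma) bookkeeping.
forwardProbAlt <- function(ev, cfg, v, traj, geom, theta, rho, g) {
  if (!nrow(ev)) return(numeric())
  n <- configSize(cfg)
  betas <- configBetas(cfg, geom)
  invLX <- 2 * traj@N[1] / traj@I[v + 1L]
  keys <- vapply(cfg@types, hapKey, character(1))
  fm <- frequencyModel(traj, geom)
  out <- numeric(nrow(ev))
  for (q in seq_len(nrow(ev))) {
    k <- ev$i[q]
    prior <- applyEvent(cfg, ev[q, ], geom$mutantCol)
    sumBetaPrior <- sum(prior@mult * configBetas(prior, geom))
    out[q] <- switch(ev$kind[q],
      coalescence = {
        pEvent <- choose(n, 2) * invLX / g
        pEvent * (cfg@mult[k] - 1) / (n - 1)
      },
      mutation_shift = {
        pEvent <- theta * sumBetaPrior / 2 / g
        pEvent * betas[k] / sumBetaPrior
      },
      mutation_merge = {
        j <- ev$j[q]
        pEvent <- theta * sumBetaPrior / 2 / g
        pEvent * (cfg@mult[j] + 1) * betas[j] / sumBetaPrior
      },
      recombination = {
        h2 <- coordinateChange(cfg@types[[k]], ev$side[q], ev$newR[q],
                               geom$mutantCol)
        jt <- match(hapKey(h2), keys)
        ntgt <- if (is.na(jt)) 0L else cfg@mult[jt]
        tp <- recombTransitionsFM(cfg@types[[k]], v, fm)
        p <- tp$p[tp$side == ev$side[q] & tp$newR == ev$newR[q]]
        bT <- ancestralFraction(h2, geom)
        pEvent <- rho * sumBetaPrior / 2 / g
        pEvent * bT * (ntgt + 1) * p / sumBetaPrior
      })
  }
  out
}

#' Proposal total rate hbar((T, n)_v)
#'
#' Sum of the coalescence terms n (n_k - 1) / (lambda_v X_v) over types with
#' n_k >= 2, the mutation terms theta * m, and the recombination terms
#' beta_j rho (n_j + 1) p_{h_j, h_i}.
#'
#' @inheritParams totalRateGamma
#' @return hbar; 0 signals a dead end.
#' @export
proposalRateHbar <- function(cfg, v, traj, geom, theta, rho) {
  ev <- enumerateEvents(cfg, v, traj, geom, theta, rho)
  attr(ev, "hbar")
}

# Apply an enumerated event to a configuration, returning the more-ancient
# configuration. mutantCol is needed to filter mutation coordinates on
# shrinking recombination moves.
applyEvent <- function(cfg, ev, mutantCol) {
  k <- ev$i
  switch(ev$kind,
    coalescence = {
      mult <- cfg@mult; mult[k] <- mult[k] - 1L
      if (mult[k] == 0L) sampleConfig(cfg@types[-k], mult[-k])
      else sampleConfig(cfg@types, mult)
    },
    mutation_shift = {
      types <- cfg@types
      types[[k]] <- shiftFirstMutation(types[[k]])
      sampleConfig(types, cfg@mult)
    },
    mutation_merge = {
      j <- ev$j
      mult <- cfg@mult; mult[j] <- mult[j] + 1L
      sampleConfig(cfg@types[-k], mult[-k])
    },
    recombination = {
      h2 <- coordinateChange(cfg@types[[k]], ev$side, ev$newR, mutantCol)
      keys <- vapply(cfg@types, hapKey, character(1))
      jt <- match(hapKey(h2), keys)
      types <- cfg@types; mult <- cfg@mult
      mult[k] <- mult[k] - 1L
      if (!is.na(jt)) mult[jt] <- mult[jt] + 1L
      else { types <- c(types, h2); mult <- c(mult, 1L) }
      keep <- mult > 0L
      sampleConfig(types[keep], mult[keep])
    })
}
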