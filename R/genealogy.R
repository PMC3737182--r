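# Sequential importance sampling over genealogical histories of the coded
# configuration, conditional on one allele-frequency trajectory. The pure-R
# single-path sampler here is the readable reference (with optional event
# trace and the dual weight cross-check); genealogyWeights() dispatches the
# compiled batch sampler for production runs.

#' Sample the time to the next event
#'
#' Sequential per-generation Bernoulli trials with hazard gamma(u, n) /
#' (2 N_0), the discrete-time geometric waiting law of the backward process.
#'
#' @param cfg a \linkS4class{SampleConfig}.
#' @param t generation of the previous event.
#' @param traj a \linkS4class{SweepTrajectory}.
#' @param geom geometry.
#' @param theta,rho scaled rates.
#' @return the event generation v, or NA if the trajectory ends first
#'   (beyond-trajectory signal; the caller rejects the path).
#' @export
sampleEventTime <- function(cfg, t, traj, geom, theta, rho) {
  n <- configSize(cfg)
  sumBeta <- sum(cfg@mult * configBetas(cfg, geom))
  hb <- n * (n - 1) / 2
  hm <- (theta + rho) * sumBeta / (4 * traj@N[1])
  Tend <- traj@age - 1L
  u <- t + 1L
  while (u <= Tend) {
    hz <- min(1, hb / traj@I[u + 1L] + hm)
    if (runif(1) < hz) return(u)
    u <- u + 1L
  }
  NA_integer_
}

#' Propose one event of the genealogical history
#'
#' Chooses among all candidate events at generation v with probability
#' proportional to its term in hbar, and applies it.
#'
#' @param cfg a \linkS4class{SampleConfig}.
#' @param v event generation.
#' @param traj a \linkS4class{SweepTrajectory}.
#' @param geom geometry.
#' @param theta,rho scaled rates.
#' @return list(event = chosen row, config = updated configuration,
#'   logStepWeight = log(hbar / (2 gamma))), or NULL on a dead end
#'   (hbar = 0).
#' @export
proposeEvent <- function(cfg, v, traj, geom, theta, rho) {
  ev <- enumerateEvents(cfg, v, traj, geom, theta, rho)
  hbar <- attr(ev, "hbar")
  if (!isTRUE(hbar > 0)) return(NULL)
  pick <- sample.int(nrow(ev), 1L, prob = ev$term)
  list(event = ev[pick, ],
       config = applyEvent(cfg, ev[pick, ], geom$mutantCol),
       logStepWeight = log(hbar) - log(2 * attr(ev, "gamma")))
}

#' Per-step importance weight of an event
#'
#' The ratio of the target one-step probability to the proposal one-step
#' probability; with this proposal it equals hbar / (2 gamma) for every
#' event kind. Computed both from the explicit ratio and from hbar /
#' (2 gamma) and cross-checked to 1e-9.
#'
#' @param event one row of \code{\link{enumerateEvents}}.
#' @param hbar,gamma the rates attached to the enumeration.
#' @return log step weight.
#' @export
stepWeight <- function(event, hbar, gamma) {
  direct <- event$forwardAlt / event$proposal
  ref <- hbar / (2 * gamma)
  if (abs(direct / ref - 1) > 1e-9)
    stop("step-weight identity violated: rate bookkeeping bug")
  log(ref)
}

isFounderSingleton <- function(cfg, geom) {
  length(cfg@types) == 1L && cfg@mult[1] == 1L &&
    cfg@types[[1]]@R1 == geom$mL && cfg@types[[1]]@R2 == geom$mR &&
    !length(cfg@types[[1]]@M)
}

#' Run one genealogical history (reference implementation)
#'
#' Iterates waiting-time sampling and event proposal backward from t = 0
#' until the configuration is absorbed at a single founder lineage (a single
#' non-founder lineage keeps taking mutation/recombination moves until it
#' reaches the founder code) or the path is rejected. With
#' \code{checkWeights = TRUE} every step weight is computed by the two
#' independent routes and compared.
#'
#' @param cfg0 starting configuration (from \code{\link{encodeSample}}).
#' @param traj a \linkS4class{SweepTrajectory}.
#' @param geom geometry.
#' @param theta,rho scaled rates.
#' @param trace record the event sequence.
#' @param checkWeights cross-check each step weight (slow; for tests).
#' @param maxEvents cap on the number of events.
#' @return list(logWeight, status in absorbed/beyond/deadend/cap, events
#'   data.frame when traced).
#' @export
runGenealogy <- function(cfg0, traj, geom, theta, rho, trace = FALSE,
                         checkWeights = FALSE, maxEvents = 100000L) {
  cfg <- cfg0
  t <- 0L
  lw <- 0
  events <- list()
  nev <- 0L
  repeat {
    if (isFounderSingleton(cfg, geom))
      return(list(logWeight = lw, status = "absorbed",
                  events = if (trace) do.call(rbind, events)))
    if (nev >= maxEvents)
      return(list(logWeight = -Inf, status = "cap", events = NULL))
    v <- sampleEventTime(cfg, t, traj, geom, theta, rho)
    if (is.na(v))
      return(list(logWeight = -Inf, status = "beyond", events = NULL))
    ev <- enumerateEvents(cfg, v, traj, geom, theta, rho,
                          dual = checkWeights)
    hbar <- attr(ev, "hbar")
    if (!isTRUE(hbar > 0))
      return(list(logWeight = -Inf, status = "deadend", events = NULL))
    pick <- sample.int(nrow(ev), 1L, prob = ev$term)
    chosen <- ev[pick, ]
    lw <- lw + if (checkWeights)
      stepWeight(chosen, hbar, attr(ev, "gamma"))
    else log(hbar) - log(2 * attr(ev, "gamma"))
    if (trace) {
      chosen$v <- v
      chosen$codeI <- hapKey(cfg@types[[chosen$i]])
      chosen$codeJ <- if (chosen$kind == "mutation_merge")
        hapKey(cfg@types[[chosen$j]]) else NA_character_
    }
    cfg <- applyEvent(cfg, chosen, geom$mutantCol)
    if (trace) {
      chosen$n <- configSize(cfg)
      events[[length(events) + 1L]] <- chosen
    }
    nev <- nev + 1L
    t <- v
  }
}

#' Batch genealogy importance weights (compiled sampler)
#'
#' Runs K independent genealogical histories of \code{cfg0} conditional on
#' one trajectory and returns their log importance weights (-Inf for
#' rejected paths), statuses and event counts.
#'
#' @param cfg0 starting configuration.
#' @param traj a \linkS4class{SweepTrajectory}.
#' @param geom geometry.
#' @param theta,rho scaled rates.
#' @param K number of paths.
#' @param maxEvents per-path cap.
#' @return list(logWeight, status (0 absorbed, 1 beyond, 2 deadend, 3 cap),
#'   events).
#' @export
genealogyWeights <- function(cfg0, traj, geom, theta, rho, K,
                             maxEvents = 100000L) {
  fm <- frequencyModel(traj, geom)
  typesR <- lapply(cfg0@types, function(h) c(h@R1, h@R2, h@M))
  genealogy_batch_cpp(typesR, cfg0@mult, fm$invI, fm$X, fm$Ct,
                      theta, rho, fm$N0, geom$mL, geom$mR,
                      geom$mutantCol, geom$gL, geom$gR,
                      as.numeric(geom$bpL), as.numeric(geom$bpR),
                      geom$gTot, as.integer(K), as.integer(maxEvents))
}
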