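# Event rates: gamma, hbar, event enumeration, the per-step weight identity
# and the proposal normalization.

makeRatesFixture <- function(seed = 33, m = 13L, j0 = 6L, totalCM = 1.6,
                             N0 = 60) {
  set.seed(seed)
  u <- uniformMapM(m, totalCM, j0)
  traj <- sampleTrajectory(round(2 * N0 * 0.6), selectionModel(0.15),
                           constantDemography(N0))
  list(geom = u$geom, traj = traj, N0 = N0)
}

test_that("gamma matches the closed formula in simple cases", {
  fx <- makeRatesFixture()
  geom <- fx$geom; traj <- fx$traj
  # n = 2 identical founders, theta = rho = 0: gamma = 1 / (lambda X)
  cfg <- sampleConfig(list(founderHaplotype(geom)), 2L)
  v <- 1L
  lamX <- traj@I[v + 1] / (2 * traj@N[1])
  expect_equal(totalRateGamma(cfg, v, traj, geom, 0, 0), 1 / lamX)
  # n = 1: only the theta and rho terms remain
  cfg1 <- sampleConfig(list(codedHaplotype(2, 3)), 1L)
  b <- ancestralFraction(codedHaplotype(2, 3), geom)
  expect_equal(totalRateGamma(cfg1, v, traj, geom, 8, 12),
               (8 + 12) * b / 2)
  # theta = 0 (G6PD setting): gamma = C(n,2)/(lambda X) + sum rho_i / 2
  cfgG <- g6pdConfig(); geomG <- g6pdGeometry()
  bG <- sum(cfgG@mult * vapply(cfgG@types, ancestralFraction, numeric(1),
                               geom = geomG))
  trajG <- fixedTrajectory(c(500L, 200L, 50L, 1L, 0L), 1000)
  lamXG <- trajG@I[2] / (2 * trajG@N[1])
  expect_equal(totalRateGamma(cfgG, 1L, trajG, geomG, 0, 30),
               choose(10, 2) / lamXG + 30 * bG / 2)
})

test_that("event-type probabilities sum to one", {
  fx <- makeRatesFixture()
  cfg <- sampleConfig(list(codedHaplotype(1, 2, 8L), codedHaplotype(4, 4),
                           founderHaplotype(fx$geom)), c(1L, 3L, 2L))
  for (v in c(0L, 2L, 5L)) {
    p <- eventTypeProbs(cfg, v, fx$traj, fx$geom, theta = 7, rho = 11)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
})

test_that("hbar is zero for all-singleton configurations without rates", {
  fx <- makeRatesFixture()
  cfg <- sampleConfig(list(codedHaplotype(1, 2), codedHaplotype(3, 1)),
                      c(1L, 1L))
  expect_equal(proposalRateHbar(cfg, 1L, fx$traj, fx$geom, 0, 0), 0)
  # a single type with n_1 = n: pure coalescence term n(n-1)/(lambda X)
  cfg2 <- sampleConfig(list(codedHaplotype(2, 2)), 4L)
  lamX <- fx$traj@I[2] / (2 * fx$traj@N[1])
  expect_equal(proposalRateHbar(cfg2, 1L, fx$traj, fx$geom, 0, 0),
               4 * 3 / lamX)
})

test_that("hbar equals the sum of individually enumerated event terms", {
  fx <- makeRatesFixture()
  cfg <- sampleConfig(list(codedHaplotype(1, 2, 8L), codedHaplotype(4, 4),
                           founderHaplotype(fx$geom)), c(1L, 3L, 2L))
  ev <- enumerateEvents(cfg, 2L, fx$traj, fx$geom, theta = 7, rho = 11)
  expect_equal(attr(ev, "hbar"), sum(ev$term))
  expect_gt(nrow(ev), 0)
})

test_that("proposal probabilities sum to exactly 1 over enumerated events", {
  fx <- makeRatesFixture()
  set.seed(91)
  for (rep in 1:6) {
    d <- sample(2:4, 1)
    types <- list(); seen <- character()
    while (length(types) < d) {
      h <- codedHaplotype(sample(0:fx$geom$mL, 1), sample(0:fx$geom$mR, 1))
      if (!hapKey(h) %in% seen) { types <- c(types, h); seen <- c(seen, hapKey(h)) }
    }
    cfg <- sampleConfig(types, sample(1:3, d, replace = TRUE))
    ev <- enumerateEvents(cfg, sample(0:3, 1), fx$traj, fx$geom,
                          theta = runif(1, 0, 20), rho = runif(1, 1, 30))
    if (nrow(ev)) expect_equal(sum(ev$proposal), 1, tolerance = 1e-12)
  }
})

test_that("every step weight equals hbar/(2 gamma) by two computations", {
  fx <- makeRatesFixture()
  set.seed(55)
  cfgs <- list(
    sampleConfig(list(codedHaplotype(1, 2, 8L), codedHaplotype(4, 4),
                      founderHaplotype(fx$geom)), c(1L, 3L, 2L)),
    sampleConfig(list(codedHaplotype(0, 0), codedHaplotype(2, 1),
                      codedHaplotype(2, 1, 7L)), c(2L, 2L, 1L)),
    sampleConfig(list(codedHaplotype(3, 2), codedHaplotype(5, 2)),
                 c(3L, 1L)))
  for (cfg in cfgs) {
    ev <- enumerateEvents(cfg, 1L, fx$traj, fx$geom, theta = 9, rho = 15,
                          dual = TRUE)
    hbar <- attr(ev, "hbar"); g <- attr(ev, "gamma")
    # route 1: term / (2 gamma) over term / hbar
    expect_equal(ev$forward / ev$proposal, rep(hbar / (2 * g), nrow(ev)),
                 tolerance = 1e-12)
    # route 2: event-type decomposition over the proposal
    expect_equal(ev$forwardAlt / ev$proposal, rep(hbar / (2 * g), nrow(ev)),
                 tolerance = 1e-9)
    expect_equal(ev$forwardAlt, ev$forward, tolerance = 1e-12)
  }
})

test_that("compiled rates agree with the R reference", {
  fx <- makeRatesFixture()
  geom <- fx$geom; traj <- fx$traj
  fm <- sweepIS:::frequencyModel(traj, geom)
  cfg <- sampleConfig(list(codedHaplotype(1, 2, 8L), codedHaplotype(4, 4),
                           codedHaplotype(4, 5), founderHaplotype(geom)),
                      c(1L, 3L, 1L, 2L))
  for (v in c(1L, 4L)) {
    ev <- enumerateEvents(cfg, v, traj, geom, theta = 7, rho = 11)
    dbg <- sweepIS:::rates_debug_cpp(
      lapply(cfg@types, hapCode), cfg@mult, v, fm$invI, fm$X, fm$Ct,
      7, 11, fm$N0, geom$mL, geom$mR, geom$mutantCol, geom$gL, geom$gR,
      as.numeric(geom$bpL), as.numeric(geom$bpR), geom$gTot)
    expect_equal(dbg$hbar, attr(ev, "hbar"), tolerance = 1e-10)
    expect_equal(dbg$gamma, attr(ev, "gamma"), tolerance = 1e-10)
  }
})

test_that("the reachable recombination classes number (mL+1)(mR+1)", {
  u <- uniformMapM(7L, 1.1, 3L)
  geom <- u$geom
  traj <- fixedTrajectory(c(30L, 12L, 4L, 1L, 0L), 30)
  # breadth-first closure over single-coordinate extensions from (0, 0)
  seen <- new.env()
  frontier <- list(codedHaplotype(0, 0))
  assign("0|0", TRUE, envir = seen)
  while (length(frontier)) {
    nxt <- list()
    for (h in frontier) {
      tp <- recombTransitionProbs(h, 0L, traj, geom)
      for (q in seq_len(nrow(tp))) {
        h2 <- if (tp$side[q] == "left")
          codedHaplotype(tp$newR[q], h@R2) else codedHaplotype(h@R1, tp$newR[q])
        key <- paste(h2@R1, h2@R2, sep = "|")
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          nxt <- c(nxt, h2)
        }
      }
    }
    frontier <- nxt
  }
  # downward closure: every class reaches the founder, and every class is
  # reachable as a cut of a longer one; the state space is the full lattice
  expect_equal(length(ls(seen)), (geom$mL + 1) * (geom$mR + 1))
})
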