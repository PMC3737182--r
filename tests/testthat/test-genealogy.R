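# The sequential importance sampler over genealogical histories.

test_that("event times follow the geometric law under constant hazard", {
  # single founder pair, constant trajectory: waiting time is geometric
  twoN <- 40L
  traj <- fixedTrajectory(c(rep(20L, 200), 1L, 0L), twoN / 2)
  u <- uniformMapM(5L, 0.4, 3L)
  cfg <- sampleConfig(list(founderHaplotype(u$geom)), 2L)
  p <- choose(2, 2) / 20                 # pair hazard 1/I per generation
  set.seed(41)
  v <- replicate(4000, sampleEventTime(cfg, 0L, traj, u$geom, 0, 0))
  v <- v[!is.na(v)]
  expect_gt(length(v), 3500)
  expect_equal(mean(v), 1 / p, tolerance = 0.1)
})

test_that("zero hazard yields the beyond-trajectory signal", {
  traj <- fixedTrajectory(c(10L, 5L, 1L, 0L), 10)
  u <- uniformMapM(5L, 0.4, 3L)
  cfg <- sampleConfig(list(codedHaplotype(1, 1)), 1L)  # n = 1, rates 0
  expect_true(is.na(sampleEventTime(cfg, 0L, traj, u$geom, 0, 0)))
})

test_that("event-time pmf matches the product formula on a toy trajectory", {
  traj <- fixedTrajectory(c(8L, 6L, 5L, 3L, 2L, 1L, 0L), 5)
  u <- uniformMapM(5L, 0.4, 3L)
  cfg <- sampleConfig(list(founderHaplotype(u$geom)), 2L)
  hz <- pmin(1, 1 / traj@I[2:6])          # hazard at u = 1..5
  pmf <- hz * cumprod(c(1, 1 - hz))[1:5]
  set.seed(17)
  draws <- replicate(20000, sampleEventTime(cfg, 0L, traj, u$geom, 0, 0))
  for (vv in 1:5) {
    est <- mean(draws == vv, na.rm = FALSE)
    est[is.na(est)] <- 0
    x <- as.numeric(draws == vv); x[is.na(x)] <- 0
    expect_lt(abs(mean(x) - pmf[vv]), 3 * mcSE(x) + 1e-12)
  }
})

test_that("a doubled type coalesces with certainty when rates vanish", {
  traj <- fixedTrajectory(c(10L, 6L, 1L, 0L), 10)
  u <- uniformMapM(5L, 0.4, 3L)
  cfg <- sampleConfig(list(codedHaplotype(1, 1)), 2L)
  set.seed(3)
  out <- proposeEvent(cfg, 1L, traj, u$geom, 0, 0)
  expect_equal(out$event$kind, "coalescence")
  expect_equal(configSize(out$config), 1L)
})

test_that("mutation moves respect the infinitely-many-sites constraint", {
  u <- uniformMapM(9L, 0.9, 5L)
  traj <- fixedTrajectory(c(20L, 12L, 6L, 1L, 0L), 20)
  # singleton whose shifted code exists: only the merge move fires
  cfg <- sampleConfig(list(codedHaplotype(2, 2, 7L), codedHaplotype(2, 2)),
                      c(1L, 2L))
  ev <- enumerateEvents(cfg, 1L, traj, u$geom, theta = 5, rho = 0)
  expect_true("mutation_merge" %in% ev$kind)
  expect_false("mutation_shift" %in% ev$kind)
  # singleton whose shifted code is absent: only the shift move
  cfg2 <- sampleConfig(list(codedHaplotype(2, 2, 7L), codedHaplotype(4, 2)),
                       c(1L, 2L))
  ev2 <- enumerateEvents(cfg2, 1L, traj, u$geom, theta = 5, rho = 0)
  expect_true("mutation_shift" %in% ev2$kind)
  expect_false("mutation_merge" %in% ev2$kind)
  # non-singleton types never mutate
  cfg3 <- sampleConfig(list(codedHaplotype(2, 2, 7L)), 2L)
  ev3 <- enumerateEvents(cfg3, 1L, traj, u$geom, theta = 5, rho = 0)
  expect_false(any(grepl("mutation", ev3$kind)))
})

test_that("a founder-singleton start is absorbed immediately with weight 1", {
  u <- uniformMapM(7L, 0.7, 4L)
  traj <- fixedTrajectory(c(10L, 4L, 1L, 0L), 10)
  cfg <- sampleConfig(list(founderHaplotype(u$geom)), 1L)
  out <- runGenealogy(cfg, traj, u$geom, 3, 5)
  expect_equal(out$status, "absorbed")
  expect_equal(out$logWeight, 0)
  gw <- genealogyWeights(cfg, traj, u$geom, 3, 5, K = 5)
  expect_equal(gw$logWeight, rep(0, 5))
  expect_equal(gw$status, rep(0L, 5))
})

test_that("two identical founders coalesce with unit weight: hbar = 2 gamma
           and the founding hazard forces the event", {
  u <- uniformMapM(7L, 0.7, 4L)
  traj <- fixedTrajectory(c(9L, 7L, 4L, 2L, 1L, 0L), 12)
  cfg <- sampleConfig(list(founderHaplotype(u$geom)), 2L)
  # theta = rho = 0, both lineages identical: the compatible coalescence is
  # the only event of the target chain, so every step weight is exactly 1;
  # and the pair hazard reaches 1 at the founding generation (I = 1), so
  # the event always happens in time: the sampling probability is 1.
  hz <- pmin(1, 1 / traj@I[2:5])
  pEvent <- sum(hz * cumprod(c(1, 1 - hz))[1:4])
  expect_equal(pEvent, 1)
  set.seed(19)
  gw <- genealogyWeights(cfg, traj, u$geom, 0, 0, K = 2000)
  expect_true(all(gw$status == 0L))
  expect_equal(gw$logWeight, rep(0, 2000))
})

test_that("absorbed paths replayed forward regenerate the configuration", {
  u <- uniformMapM(9L, 1.2, 5L)
  set.seed(23)
  traj <- sampleTrajectory(60, selectionModel(0.2), constantDemography(40))
  cfg <- sampleConfig(list(codedHaplotype(1, 2, 8L), codedHaplotype(3, 1),
                           codedHaplotype(3, 4)), c(1L, 2L, 1L))
  got <- 0
  for (i in 1:50) {
    out <- runGenealogy(cfg, traj, u$geom, 6, 10, trace = TRUE,
                        checkWeights = TRUE)
    if (out$status != "absorbed") next
    got <- got + 1
    # replay: start from the founder singleton and invert events in reverse
    state <- sampleConfig(list(founderHaplotype(u$geom)), 1L)
    for (q in rev(seq_len(nrow(out$events)))) {
      state <- invertEvent(state, out$events[q, ], u$geom)
    }
    expect_equal(sort(vapply(state@types, hapKey, character(1))),
                 sort(vapply(cfg@types, hapKey, character(1))))
    expect_equal(state@mult[order(vapply(state@types, hapKey, character(1)))],
                 cfg@mult[order(vapply(cfg@types, hapKey, character(1)))])
    if (got >= 5) break
  }
  expect_gte(got, 1)
})

test_that("compiled and reference samplers estimate the same probability", {
  u <- uniformMapM(5L, 0.6, 3L)
  set.seed(29)
  traj <- sampleTrajectory(40, selectionModel(0.15), constantDemography(30))
  cfg <- sampleConfig(list(codedHaplotype(1, 1), codedHaplotype(2, 2)),
                      c(2L, 2L))
  gw <- genealogyWeights(cfg, traj, u$geom, 4, 8, K = 30000)
  wC <- exp(gw$logWeight); wC[!is.finite(gw$logWeight)] <- 0
  wR <- replicate(800, {
    o <- runGenealogy(cfg, traj, u$geom, 4, 8)
    if (o$status == "absorbed") exp(o$logWeight) else 0
  })
  expect_lt(abs(mean(wC) - mean(wR)), 3 * (mcSE(wC) + mcSE(wR)))
})

test_that("multilocus IS mean weight matches the two-locus oracle", {
  # n = 5 two-locus toy data: exact DP versus the full multilocus machinery
  map <- recombMap(c(1, 8e4), c(0, 0.15))
  geom <- haplotypeGeometry(map, 1L)
  set.seed(37)
  traj <- sampleTrajectory(90, selectionModel(0.12), constantDemography(75))
  cfg <- sampleConfig(list(codedHaplotype(0, 1), codedHaplotype(0, 0)),
                      c(3L, 2L))
  exact <- twoLocusOracle(3, 2, traj, 0.0015)
  gw <- genealogyWeights(cfg, traj, geom, 0, 4 * 75 * geom$gTot, K = 30000)
  w <- exp(gw$logWeight); w[!is.finite(gw$logWeight)] <- 0
  expect_lt(abs(mean(w) - exact), 3 * mcSE(w))
})
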