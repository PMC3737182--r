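# Backward Wright-Fisher trajectory sampler, forward probabilities and
# importance weights.

test_that("selection-map inversion inverts the forward map", {
  grid <- seq(0, 1, by = 0.01)
  for (sel in list(selectionModel(0.1), selectionModel(0.005),
                   selectionModel(0.3, "custom", s1 = 0.3, s2 = 0.05))) {
    y <- forwardSelectionMap(grid, sel)
    expect_lt(max(abs(selectionInverse(y, sel) - grid)), 1e-10)
  }
  # independent root-finding oracle at a single point
  sel <- selectionModel(0.1)
  yp <- selectionInverse(0.3, sel)
  oracle <- uniroot(function(x) oracleFwdMap(x, 0.1, 0.05) - 0.3,
                    c(0, 1), tol = 1e-13)$root
  expect_equal(yp, oracle, tolerance = 1e-9)
  # neutral: identity
  expect_equal(selectionInverse(0.37, selectionModel(0)), 0.37)
})

test_that("backward step is a plain neutral binomial when s = 0", {
  demog <- constantDemography(25)
  set.seed(2)
  draws <- replicate(3000, backwardStep(30, 1, selectionModel(0),
                                        demog)$I)
  expect_equal(mean(draws), 50 * 30 / 50, tolerance = 0.05)
  # boundary: frequency zero stays zero with certainty
  expect_equal(selectionInverse(0, selectionModel(0.2)), 0)
})

test_that("forward log-probability matches direct computation (2N = 4)", {
  # path I = (3, 2, 1, 0) backward: founding at T = 3, present count 3
  traj <- fixedTrajectory(c(3L, 2L, 1L, 0L), 2)
  sel <- selectionModel(0.1)
  direct <- dbinom(2, 4, oracleFwdMap(1 / 4, 0.1, 0.05), log = TRUE) +
    dbinom(3, 4, oracleFwdMap(2 / 4, 0.1, 0.05), log = TRUE)
  expect_equal(forwardLogProb(traj, sel), direct)
  # a path not founded by a single copy has zero forward probability
  bad <- fixedTrajectory(c(3L, 2L, 0L), 2)
  expect_identical(forwardLogProb(bad, sel), -Inf)
  # neutral: product of neutral binomials
  expect_equal(forwardLogProb(traj, selectionModel(0)),
               dbinom(2, 4, 1 / 4, log = TRUE) +
                 dbinom(3, 4, 2 / 4, log = TRUE))
})

test_that("compiled and R forward log-probabilities agree", {
  set.seed(5)
  demog <- constantDemography(40)
  sel <- selectionModel(0.08)
  for (i in 1:10) {
    traj <- sampleTrajectory(48, sel, demog)
    if (traj@status != "ok" || traj@I[traj@age] != 1L) next
    expect_equal(forwardLogProb(traj, sel),
                 sweepIS:::traj_forward_logprob_cpp(traj@I, sel@s1, sel@s2,
                                                    traj@N))
  }
})

test_that("importance-weighted age distribution matches exhaustive
           enumeration at 2N = 6", {
  twoN <- 6L; I0 <- 3L
  for (s in c(0, 0.5)) {
    sel <- selectionModel(s)
    demog <- constantDemography(twoN / 2)
    set.seed(31)
    R <- 30000
    w <- numeric(R); age <- integer(R)
    for (r in seq_len(R)) {
      tr <- sampleTrajectory(I0, sel, demog, tMax = 400)
      w[r] <- if (tr@status == "ok") exp(tr@logWeight) else 0
      age[r] <- tr@age
    }
    mass <- oracleAgeMass(I0, sel@s1, sel@s2, twoN, maxAge = 6L)
    for (a in 2:6) {
      x <- w * (age == a) / twoN        # estimates the forward path mass
      expect_lt(abs(mean(x) - mass[a]), 3 * mcSE(x) + 1e-12)
    }
  }
})

test_that("weighted mean age agrees with forward-conditioned simulation", {
  twoN <- 20L; I0 <- 12L
  sel <- selectionModel(0.1)
  demog <- constantDemography(twoN / 2)
  horizon <- 300L
  set.seed(77)
  # backward importance-sampling estimate of E[T | I_0 = I0]
  R <- 20000
  w <- numeric(R); age <- integer(R)
  for (r in seq_len(R)) {
    tr <- sampleTrajectory(I0, sel, demog, tMax = horizon)
    w[r] <- if (tr@status == "ok") exp(tr@logWeight) else 0
    age[r] <- tr@age
  }
  isMean <- sum(w * age) / sum(w)
  # forward oracle: visits of forward paths from one copy to state I0
  F <- sweepIS:::wf_forward_batch_cpp(40000, sel@s1, sel@s2,
                                      rep(twoN / 2, horizon + 1), horizon)
  hits <- F == I0
  num <- sum(t(hits) * seq(0, horizon))   # sum over visits of visit time
  den <- sum(hits)
  fwdMean <- num / den
  seIS <- sqrt(sum((w * (age - isMean))^2)) / sum(w)
  expect_lt(abs(isMean - fwdMean), 3 * seIS + 3)
})

test_that("paths exceeding the horizon are rejected with zero weight", {
  set.seed(8)
  sel <- selectionModel(0.001)
  demog <- constantDemography(500)
  tr <- NULL
  for (i in 1:200) {
    tr <- sampleTrajectory(600, sel, demog, tMax = 30)
    if (tr@status == "tmax") break
  }
  expect_equal(tr@status, "tmax")
  expect_identical(trajectoryWeight(tr), -Inf)
})

test_that("sampled trajectories carry a consistent importance weight", {
  set.seed(12)
  demog <- constantDemography(50)
  sel <- selectionModel(0.1)
  for (i in 1:20) {
    tr <- sampleTrajectory(60, sel, demog)
    if (!is.finite(tr@logWeight)) next
    expect_equal(tr@logWeight,
                 forwardLogProb(tr, sel) - tr@logPB +
                   log(2 * tr@N[length(tr@N)]))
    expect_equal(tr@I[length(tr@I)], 0L)
    expect_equal(tr@I[tr@age], 1L)
  }
})
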