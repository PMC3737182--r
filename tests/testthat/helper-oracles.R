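# Independent oracles used across tests.

# Forward one-generation selection map, written directly from the genotype
# frequencies (independent of the package implementation).
oracleFwdMap <- function(x, s1, s2) {
  x * (1 + s1 * x + s2 * (1 - x)) /
    (1 + s1 * x^2 + 2 * s2 * x * (1 - x))
}

# Exhaustive distribution of the allele age by matrix powering: the
# unnormalized mass of forward Wright-Fisher paths of exactly `age`
# generations from a single copy to I0 copies, never touching 0.
# Returns the vector over ages 1..maxAge (to be compared against
# E[w 1(T = age)] / (2N)).
oracleAgeMass <- function(I0, s1, s2, twoN, maxAge) {
  states <- 1:twoN
  M <- outer(states, states, function(i, j)
    dbinom(j, twoN, oracleFwdMap(i / twoN, s1, s2)))
  out <- numeric(maxAge)
  v <- as.numeric(states == 1L)
  out[1] <- if (I0 == 1L) 1 else 0     # age 1: I_{T-1} = I_0 = 1
  for (a in 2:maxAge) {
    v <- as.numeric(v %*% M)
    out[a] <- v[I0]
  }
  out
}

# Monte Carlo standard error of a mean, guarding degenerate cases.
mcSE <- function(x) stats::sd(x) / sqrt(length(x))

# Parse a haplotype key "R1|R2|M1,M2" back into a CodedHaplotype.
parseHapKey <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  M <- if (length(parts) < 3 || parts[3] == "") integer() else
    as.integer(strsplit(parts[3], ",", fixed = TRUE)[[1]])
  codedHaplotype(as.integer(parts[1]), as.integer(parts[2]), M)
}

# Forward-in-time inversion of one traced backward event: given the
# more-ancient configuration, produce the more-recent one.
invertEvent <- function(state, ev, geom) {
  keys <- vapply(state@types, hapKey, character(1))
  addOne <- function(st, h) {
    k <- match(hapKey(h), vapply(st@types, hapKey, character(1)))
    if (is.na(k)) sampleConfig(c(st@types, h), c(st@mult, 1L))
    else { m <- st@mult; m[k] <- m[k] + 1L; sampleConfig(st@types, m) }
  }
  dropOne <- function(st, h) {
    k <- match(hapKey(h), vapply(st@types, hapKey, character(1)))
    stopifnot(!is.na(k))
    m <- st@mult; m[k] <- m[k] - 1L
    keep <- m > 0L
    sampleConfig(st@types[keep], m[keep])
  }
  hI <- parseHapKey(ev$codeI)
  switch(ev$kind,
    coalescence = addOne(state, hI),
    mutation_shift = addOne(dropOne(state, shiftFirstMutation(hI)), hI),
    mutation_merge = addOne(dropOne(state, parseHapKey(ev$codeJ)), hI),
    recombination = {
      h2 <- coordinateChange(hI, ev$side, ev$newR, geom$mutantCol)
      addOne(dropOne(state, h2), hI)
    })
}
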