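# Fixtures built in code: a worked coding example (10 haplotypes, 25 SNPs,
# mutant at column 18, four groups), the G6PD coded configuration, and small
# helpers shared across tests.

# Ancestral haplotype pattern for the worked 25-SNP example.
ancestral25 <- rep(c(1L, 0L, 1L, 1L, 0L), 5)

# Build the 10 x 25 example matrix: groups coded (7,6) x4, (12,7,21) x2,
# (17,7) x3, (2,3) x1. Alleles inside each retained block follow the
# ancestral haplotype (with the single group-2 mutation at column 21);
# alleles outside the block are flipped so blocks are visually distinct.
codingExampleMatrix <- function() {
  j0 <- 18L
  specs <- list(list(R1 = 7L, R2 = 6L, M = integer(), n = 4L),
                list(R1 = 12L, R2 = 7L, M = 21L, n = 2L),
                list(R1 = 17L, R2 = 7L, M = integer(), n = 3L),
                list(R1 = 2L, R2 = 3L, M = integer(), n = 1L))
  alle <- matrix(0L, 10L, 25L)
  mask <- matrix(FALSE, 10L, 25L)
  r <- 1L
  for (sp in specs) {
    for (i in seq_len(sp$n)) {
      blk <- (j0 - sp$R1):(j0 + sp$R2)
      alle[r, ] <- 1L - ancestral25
      alle[r, blk] <- ancestral25[blk]
      if (length(sp$M)) alle[r, sp$M] <- 1L - ancestral25[sp$M]
      mask[r, blk] <- TRUE
      r <- r + 1L
    }
  }
  haplotypeMatrix(alle, mask, positions = seq(1000, by = 1000,
                                              length.out = 25L),
                  mutantPos = 18000)
}

# The G6PD coded sample configuration: {(11,7): 5, (4,7): 1, (12,7): 1,
# (17,7): 3}, n = 10, on 25 uniformly spaced markers over 440 kb at
# 1.4410 cM/Mb, mutant at column 18.
g6pdConfig <- function() {
  sampleConfig(list(codedHaplotype(11, 7), codedHaplotype(4, 7),
                    codedHaplotype(12, 7), codedHaplotype(17, 7)),
               c(5L, 1L, 1L, 3L))
}

g6pdGeometry <- function() {
  positions <- round(seq(1, 440000, length.out = 25))
  map <- uniformGeneticMap(positions, 1.4410)
  haplotypeGeometry(map, 18L)
}

# Uniform map over m SNPs with total length cM.
uniformMapM <- function(m, totalCM, mutantCol) {
  map <- recombMap(seq_len(m) * 1000, seq(0, totalCM, length.out = m))
  list(map = map, geom = haplotypeGeometry(map, mutantCol))
}

# A fixed small trajectory for deterministic tests.
fixedTrajectory <- function(I, N0) {
  new("SweepTrajectory", I = as.integer(I), N = rep(N0, length(I)),
      age = length(I) - 1L, logPB = 0, logPF = 0, logWeight = 0,
      status = "ok")
}

hapCode <- function(h) c(h@R1, h@R2, h@M)
configCodes <- function(cfg) lapply(cfg@types, hapCode)
hapKey <- sweepIS:::hapKey
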