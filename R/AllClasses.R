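#' @import methods
#' @importFrom stats dbinom rbinom runif sd quantile weighted.mean approx
#' @importFrom utils read.table write.table head tail
#' @useDynLib sweepIS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Coded selected haplotype
#'
#' A selected haplotype reduced to the extent of its retained ancestral
#' segment around the selected mutant: \code{R1} SNPs to the left and
#' \code{R2} SNPs to the right, plus the absolute column indices \code{M}
#' (1-based, most-recent mutation first) of SNPs inside the segment that
#' carry an allele differing from the ancestral haplotype.
#'
#' @slot R1 integer, number of retained SNPs left of the mutant.
#' @slot R2 integer, number of retained SNPs right of the mutant.
#' @slot M integer vector of mutation coordinates (absolute SNP columns).
#' @export
setClass("CodedHaplotype",
  representation(R1 = "integer", R2 = "integer", M = "integer"),
  validity = function(object) {
    if (length(object@R1) != 1L || length(object@R2) != 1L)
      return("R1 and R2 must be single integers")
    if (object@R1 < 0L || object@R2 < 0L)
      return("recombination coordinates must be non-negative")
    if (anyDuplicated(object@M)) return("mutation coordinates must be distinct")
    TRUE
  })

#' Sample configuration (T, n)
#'
#' The state of the backward Markov process over coded haplotypes: a list of
#' distinct \linkS4class{CodedHaplotype} types with multiplicities.
#'
#' @slot types list of distinct \linkS4class{CodedHaplotype}.
#' @slot mult integer multiplicities, all >= 1.
#' @export
setClass("SampleConfig",
  representation(types = "list", mult = "integer"),
  validity = function(object) {
    if (length(object@types) != length(object@mult))
      return("types and mult must have equal length")
    if (length(object@mult) && any(object@mult < 1L))
      return("zero-multiplicity types must be dropped")
    keys <- vapply(object@types, hapKey, character(1))
    if (anyDuplicated(keys)) return("types must be pairwise distinct")
    TRUE
  })

#' Selected haplotype matrix with ancestral-state mask
#'
#' Binary allele matrix for the haplotypes carrying the selected mutant, the
#' same-shape logical mask marking which alleles descend from the ancestral
#' haplotype, physical SNP positions and the column of the selected site.
#' Each row's masked entries must form one contiguous block containing the
#' mutant column (single retained segment; double cross-overs back into the
#' ancestral state are not modeled).
#'
#' @slot alleles n x m integer matrix of 0/1 alleles.
#' @slot mask n x m logical matrix; TRUE = descends from the ancestral
#'   haplotype.
#' @slot positions length-m numeric, physical bp coordinates, strictly
#'   increasing.
#' @slot mutantCol integer column index of the selected site.
#' @export
setClass("HaplotypeMatrix",
  representation(alleles = "matrix", mask = "matrix",
                 positions = "numeric", mutantCol = "integer"),
  validity = function(object) {
    a <- object@alleles; mk <- object@mask
    if (!all(dim(a) == dim(mk))) return("alleles and mask shapes differ")
    if (length(object@positions) != ncol(a))
      return("positions length must equal SNP count")
    if (is.unsorted(object@positions, strictly = TRUE))
      return("positions must be strictly increasing")
    j0 <- object@mutantCol
    if (j0 < 1L || j0 > ncol(a)) return("mutantCol out of range")
    if (!all(a %in% c(0L, 1L))) return("alleles must be 0/1")
    if (!all(mk[, j0])) return("mutant column must be ancestral in every row")
    for (i in seq_len(nrow(a))) {
      w <- which(mk[i, ])
      if (length(w) && !all(diff(w) == 1L))
        return(sprintf("ancestral mask of row %d is not one contiguous block", i))
    }
    TRUE
  })

#' Recombination map
#'
#' Physical SNP positions with cumulative genetic positions (cM). Interval
#' recombination fractions are taken proportional to cM distance (additive).
#'
#' @slot positions bp coordinates, strictly increasing.
#' @slot cM cumulative genetic position of each SNP, non-decreasing.
#' @export
setClass("RecombMap",
  representation(positions = "numeric", cM = "numeric"),
  validity = function(object) {
    if (length(object@positions) != length(object@cM))
      return("positions and cM lengths differ")
    if (is.unsorted(object@positions, strictly = TRUE))
      return("positions must be strictly increasing")
    if (is.unsorted(object@cM)) return("cM must be non-decreasing")
    TRUE
  })

#' Demographic model
#'
#' Diploid effective population size as a function of time, t = 0 at present
#' and increasing into the past. Piecewise-constant (breakpoint table) and
#' backward-exponential-shrink (forward growth) parameterizations.
#'
#' @slot N0 diploid size at present.
#' @slot type one of "constant", "piecewise", "exponential".
#' @slot table data.frame (t, N) of breakpoints for piecewise models.
#' @slot rate per-generation forward growth rate for exponential models.
#' @slot Nmin floor on the ancient size.
#' @export
setClass("Demography",
  representation(N0 = "numeric", type = "character", table = "data.frame",
                 rate = "numeric", Nmin = "numeric"),
  validity = function(object) {
    if (object@N0 < 1) return("N0 must be >= 1")
    if (!object@type %in% c("constant", "piecewise", "exponential"))
      return("unknown demography type")
    TRUE
  })

#' Selection model
#'
#' Genotype fitnesses 1, 1 + s2, 1 + s1 for genotypes aa, Aa, AA. The
#' additive constructor sets (1, 1 + s/2, 1 + s), i.e. s1 = s, s2 = s/2.
#'
#' @slot s nominal selection coefficient.
#' @slot s1 coefficient of the AA genotype.
#' @slot s2 coefficient of the Aa genotype.
#' @export
setClass("SelectionModel",
  representation(s = "numeric", s1 = "numeric", s2 = "numeric"),
  validity = function(object) {
    if (1 + object@s1 <= 0 || 1 + object@s2 <= 0)
      return("genotype fitnesses must be positive")
    TRUE
  })

#' Allele-frequency trajectory of the selected mutant
#'
#' Per-generation copy numbers I_t of the mutant, t = 0 (present) .. T (the
#' generation at which the allele is lost going backward, i.e. the allele
#' age), with the backward path log-probability, the forward log-probability
#' and the importance log-weight.
#'
#' @slot I integer vector of copy numbers, length T + 1, I[T+1] = 0.
#' @slot N numeric vector of diploid sizes N_t, t = 0..T.
#' @slot age the allele age T in generations.
#' @slot logPB backward (proposal) log-probability of the path.
#' @slot logPF forward (target) log-probability of the path.
#' @slot logWeight logPF - logPB + log(2 N_T).
#' @slot status "ok" or "tmax" (path exceeded the horizon and is rejected).
#' @export
setClass("SweepTrajectory",
  representation(I = "integer", N = "numeric", age = "integer",
                 logPB = "numeric", logPF = "numeric",
                 logWeight = "numeric", status = "character"))

#' Monte Carlo likelihood curve over a grid of selection coefficients
#'
#' @slot grid data.frame with columns s, loglik, se, smooth.
#' @slot sHat maximum-likelihood estimate (argmax of the smoothed curve).
#' @slot ci length-2 profile-likelihood interval.
#' @slot level confidence level of ci.
#' @slot M,K iteration counts (trajectories, genealogies per trajectory).
#' @slot seed seed used.
#' @slot bandwidth smoother bandwidth (fraction of grid span).
#' @export
setClass("LikelihoodCurve",
  representation(grid = "data.frame", sHat = "numeric", ci = "numeric",
                 level = "numeric", M = "integer", K = "integer",
                 seed = "integer", bandwidth = "numeric"))

#' Posterior distribution of the allele age
#'
#' Weighted allele-age samples at a fixed selection coefficient.
#'
#' @slot samples data.frame with columns age and weight (weights sum to 1).
#' @slot s selection coefficient at which the posterior was computed.
#' @export
setClass("AgePosterior",
  representation(samples = "data.frame", s = "numeric"),
  validity = function(object) {
    if (nrow(object@samples) &&
        abs(sum(object@samples$weight) - 1) > 1e-8)
      return("weights must sum to 1")
    if (any(object@samples$age < 1)) return("ages must be >= 1")
    TRUE
  })

#' Simulated sweep dataset with known truth
#'
#' @slot alleles full sample allele matrix (selected rows first).
#' @slot mask ancestral-state mask (FALSE everywhere on background rows).
#' @slot positions physical bp positions.
#' @slot mutantCol column of the selected site.
#' @slot nSelected number of selected rows.
#' @slot map \linkS4class{RecombMap} used.
#' @slot truth list: s, age, trajectory I, theta, rho, N, x0.
#' @export
setClass("SweepDataset",
  representation(alleles = "matrix", mask = "matrix", positions = "numeric",
                 mutantCol = "integer", nSelected = "integer",
                 map = "RecombMap", truth = "list"))
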