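---
title: "Estimating selection intensity and allele age from haplotype structure"
author: "sweepIS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating selection intensity and allele age from haplotype structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(sweepIS)
```

## The problem

A new mutation under positive selection rises in frequency quickly. While it
does, the chromosomes that carry it share long stretches of the haplotype on
which the mutation arose (the *ancestral haplotype*); recombination
progressively trims those stretches and new mutations accumulate on what
remains. The lengths of the retained ancestral segments around the selected
site, together with the mutations observed on them, therefore carry
information about two quantities of interest: the selection coefficient $s$
and the allele age $T$ (generations since the mutation arose).

sweepIS estimates both from a sample of phased selected haplotypes, given
the position of the selected site, a per-haplotype annotation of which
alleles descend from the ancestral haplotype (supplied by the user, e.g.
from an HMM-based annotation — it is an input here, not something the
package infers), a genetic map, and the population's demographic history.

## The model in outline

**Coding.** Each selected haplotype is reduced to a code
$h = (R_1, R_2, M_1, \dots, M_k)$: the number of SNPs left and right of the
selected site covered by its contiguous retained ancestral block, plus the
positions inside the block carrying non-ancestral alleles (new mutations),
most recent first. A sample becomes a configuration $(\mathcal T,
\mathbf n)$ of distinct codes with multiplicities. This reduces the state
space of the ancestral process from exponential in the number of SNPs to
$(m_L + 1)(m_R + 1)$ recombination classes, which is what makes regions of
hundreds of kilobases tractable.

**Trajectory.** The mutant's frequency path $\mathcal H = \{I_T, \dots,
I_0\}$ follows the Wright-Fisher model with genotype fitnesses
$(1,\, 1 + s_2,\, 1 + s_1)$ (additive: $s_1 = s$, $s_2 = s/2$) and
arbitrary $N_t$. Paths are proposed *backward* from the present count
$I_0 = \lfloor 2N_0 x_0 \rceil$: one step draws
$I_t \sim \mathrm{Binomial}(2N_t, Y')$ where $Y'$ inverts the deterministic
selection map at $I_{t-1}/(2N_{t-1})$, until loss at the age $T$. The
importance weight of a path is $\mathbb P_F / \mathbb P_B \cdot 2N_T$: the
forward Wright-Fisher probability of the same path (zero unless it starts
from a single copy), over the backward proposal probability, times the
chromosome count when the allele arose (the influx rate of new mutations is
proportional to it).

**Genealogy.** Conditional on a trajectory, the configuration evolves
backward as a structured-coalescent Markov chain inside the selected class:
same-type pairs coalesce at rate $1/(\lambda_v X_v)$ per pair (time in
units of $2N_0$ generations), singleton types lose their most recent
mutation at rate $\theta \beta / 2$, and a recombination event changes one
of a lineage's recombination coordinates — extending the segment past its
current breakpoint (undoing, backward in time, the crossover that created
it) or shrinking it to a new breakpoint, in which case mutation
coordinates outside the new region are shed into the ignored background
ancestry — weighted by the expected class frequency of the parent class at
that generation. $\beta$ is the genetic
length of the retained segment over the length of the whole analyzed
haplotype, so $\theta_i = \theta\beta_i$ and $\rho_i = \rho\beta_i$ scale
per haplotype. Waiting times are geometric with per-generation hazard
$\gamma(v, n)/(2N_0)$, where $\gamma = \binom n2 (\lambda_v X_v)^{-1} +
\sum_i \theta_i/2 + \sum_i \rho_i/2$.

The sampler proposes, at each event, one of the moves *compatible with the
data* with probability proportional to its term in the total compatible
rate $\hbar$; the per-step importance weight is then $\hbar/(2\gamma)$ for
every move kind, which the package verifies by computing each step weight
two independent ways. A history is accepted when it is absorbed at a single
lineage carrying the founder code $(m_L, m_R)$ with no mutations; paths
that run past the end of the trajectory, or reach a state with no
compatible move, get weight zero. If a single lineage remains that is not
yet the founder code, mutation and recombination moves continue on it until
it is (the founder of the sweep carries the intact ancestral haplotype by
construction).

**Likelihood.** With $M$ trajectories and $K$ genealogies each,
$$\hat{\mathcal L}(s) = \frac 1{MK} \sum_{m=1}^M \sum_{k=1}^K
w_{\mathrm{traj}}^{(m)} \, w_{\mathrm{gen}}^{(m,k)},$$
accumulated in log space. The log-likelihood is estimated on a grid of $s$,
smoothed by a tricube-weighted local-linear smoother, and the MLE is the
argmax of the smoothed curve on a fine interpolation grid. The posterior of
the allele age at a fixed $s$ weights each sampled trajectory's $T$ by its
trajectory weight times its mean genealogy weight.

## The expected class-frequency model

The recombination moves need $P_{[h]}(t)$, the expected frequency among
selected chromosomes at generation $t$ of the class whose retained segment
extends exactly $(R_1, R_2)$. The package models it through per-side
survival: a lineage in the selected class at $t$ retains at least $a$ SNPs
on one side iff no crossover with a background chromosome hit the span
$g(a)$ during the meioses between $t$ and the founding generation, so
$$S(a, t) = \exp\!\Big(-g(a) \sum_{u=t+1}^{T-1} (1 - X_u)\Big),$$
with exact-class probabilities by differencing adjacent extents and sides
treated as independent. This is the standard hitchhiking escape
probability; it satisfies $P_{[\mathrm{founder}]}(T-1) = 1$, sums to 1 over
the class partition, and matches direct forward simulation of marked
lineages (see the test suite). **It is the one model component constructed
by the package rather than transcribed from a published closed form**, and
results that depend on the fine shape of the class frequencies (rather
than on their qualitative decay) inherit that modeling choice. The
transition distribution out of a class normalizes the weights
$r(\text{interval crossed}) \cdot P_{[h']}(v) \cdot X_v$ over all
single-coordinate changes $h'$ (the interval crossed sits at the smaller
of the two coordinate values); crossovers with background chromosomes and
double cross-overs are excluded throughout (probability
$O(1/\log^2(2Ns))$ during a sweep).

## Parameters that matter

| parameter | meaning | default |
|---|---|---|
| `theta` | $4N_0\mu$ over the whole analyzed haplotype | data-dependent; 0 when no segment mutations are annotated |
| `rho` | $4N_0 c$; derived from the genetic map as $4N_0 \times$ map length (Morgans) | from the map |
| `x0` | present frequency of the selected allele | sample frequency |
| `M`, `K` | trajectories, genealogies per trajectory | 1000 each at full scale |
| `tMax` | trajectory horizon, generations | $4 \cdot 2N_0$; longer paths are rejected, not truncated |
| `bandwidth` | smoother window as a fraction of the grid span | 0.3 |
| `xLinked` | use $\tfrac34 N$ as the effective size | off |

Common random numbers (the same seed re-set at every grid point) are on by
default. Their main value here is reproducibility — any grid point can be
recomputed in isolation from the seed. The variance-reduction benefit is
modest for this estimator: the trajectory sampler draws one uniform per
generation (a quantile-transform binomial) so streams start out aligned
across grid points, but alignment degrades as path lengths diverge with
$s$, and the estimate is dominated by few heavy-weight trajectories.
Confidence intervals are profile-likelihood intervals at the
$\chi^2_1$ cutoff ($\Delta\log L = 1.92$ for 95%), since no interval
construction is prescribed for this class of estimate; the interval is
clamped (with a warning) when it reaches the grid edge, and a non-unimodal
smoothed curve yields the widest bracket.

## Numerical choices

All probabilities are accumulated in log space; binomial log-pmfs come from
the log-gamma function. The selection-map inversion uses the closed-form
quadratic under genic (additive) selection and monotone bisection to
$10^{-12}$ otherwise. Genetic distances are used directly as recombination
fractions (intervals here are far below 1 cM, where map functions are
indistinguishable and additivity is exact). Per-generation hazards are
capped at 1; the cap binds only in the last generations before founding,
where the chain forces the remaining coalescences. Event tie-breaks are by
construction order (types in configuration order, left targets before
right), so runs are reproducible by seed. Within one trajectory the
per-generation class-frequency columns are cached and shared across all
$K$ genealogy replicates; the per-type recombination terms are aggregated
through prefix/suffix sums of those columns, and the concrete extension or
shrink target of a chosen move is drawn exactly from the implied mixture
by binary search on the cached cumulative sums rather than by enumerating
all $(m_L + m_R)$ targets.

## The simulator and what it does not emulate

`simulateSweepDataset()` generates data with known truth: a conditioned
forward Wright-Fisher trajectory from one copy to the target frequency
(retry with a budget; tolerance one copy in $2N$), backward tracing of the
selected sample lineages along it (pair coalescence hazard $1/I_t$ per
generation, per-side segment escape at rate genetic-extent
$\times (1 - X_t)$, mutations on retained segments at rate $\mu\beta$,
each creating its own segregating site per the infinitely-many-sites
model), and i.i.d. background alleles at Uniform(0,1) per-site frequencies.
Base markers are uniform in genetic distance.

What it deliberately does not emulate: linkage structure among background
haplotypes (the method ignores it by assumption), double cross-overs that
re-import ancestral material (excluded by the model), gene conversion, and
ascertainment of markers. Passing tests on simulated data therefore
demonstrate internal consistency of the estimator under its own model
assumptions, not robustness to features of real data such as heterogeneous
recombination (hotspots), imperfect ancestral-state annotation, or
unphased genotypes.

Default study conditions for the simulation experiments follow the
published settings: $\theta = \rho = 500$, $N = 10{,}000$, present
frequency $0.60$, with $s = 0.05$ and $s = 0.005$. The sample size
(50 haplotypes, 30 selected) and the 41-marker base grid are this package's
choices of a realistic mid-2000s resequencing design. At desk scale the
package uses $M = 200$ trajectories and $K = 500$ genealogies each
($10^5$ iterations per grid point, $\approx$ 10-fold below the published
effort) and 7-8 point logarithmic $s$-grids; these sizes are the
package's reproducibility protocol and are what `scripts/acceptance.R`
runs.

## Validation design

Two independent oracles anchor correctness:

* an exact dynamic program over the two-locus ancestral process
  $(q_1, q_2)$ conditional on a trajectory (`twoLocusOracle()`), built on
  the same discrete-time chain the sampler targets — the importance
  sampler's mean weight must equal it within Monte Carlo error, which is
  checked for several sample configurations at $10^5$ paths;
* exhaustive enumeration of Wright-Fisher paths at $2N = 6$ by matrix
  powering — the trajectory sampler's weighted age distribution must match
  it bin by bin.

On top of these sit algebraic identity suites (proposal normalization,
event-type shares, the $\hbar/(2\gamma)$ step-weight identity computed two
ways, the $(m_L+1)(m_R+1)$ state count, byte-identical seeded reruns) and
the scaled-down reproduction of the published simulation study and G6PD
analysis.

## Known limitations

* The expected class-frequency model is a documented stand-in (above); the
  flatter the likelihood, the more the argmax can move under alternative
  class-frequency models. The G6PD worked example is exactly such a flat
  case: with ten selected haplotypes the profile is shallow above
  $s \approx 0.04$, and the point estimate is accordingly unstable between
  runs and model variants (the published interval spans a factor of five).
* The proposal follows the classical sample-in-proportion-to-rates scheme;
  more efficient proposal families exist and would reduce the Monte Carlo
  variance at weak selection, where trajectories are long and the effective
  sample size per $10^5$ iterations can be small.
* Mutation-coordinate order is recovered from data by a nesting convention
  (a mutation carried by a strict subset of another's carriers is more
  recent; ties by carrier count, then position); the true leaf-to-root
  order of the intra-allelic gene tree is not identifiable from a single
  configuration in general.
* Ancestral-state masks with non-contiguous blocks are rejected rather than
  repaired: under the model's assumptions a retained segment is one
  interval, and silently trimming real data that violates this would hide
  an annotation problem.

## A minimal session

```{r example, eval = FALSE}
ds <- simulateSweepDataset(s = 0.05, N = 10000, theta = 500, rho = 500,
                           x0 = 0.6, nSample = 50, mL = 20, mR = 20)
cfg <- encodeSample(selectedHaplotypes(ds), ancestral = ds@truth$ancestral)
geom <- haplotypeGeometry(ds@map, ds@mutantCol)
curve <- likelihoodCurve(exp(seq(log(0.02), log(0.1), length.out = 7)),
                         cfg, geom, theta = 500, constantDemography(10000),
                         x0 = 0.6, M = 200, K = 500, seed = 1)
sHat(curve)
post <- agePosterior(sHat(curve), cfg, geom, 500, constantDemography(10000),
                     x0 = 0.6, M = 500, K = 100)
ageSummary(post)
```
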