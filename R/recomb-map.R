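# Genetic maps and the per-haplotype geometry used by the ancestral process.

#' Construct a recombination map from cumulative genetic positions
#'
#' @param positions bp coordinates, strictly increasing.
#' @param cM cumulative genetic positions (cM), non-decreasing.
#' @return A \linkS4class{RecombMap}.
#' @export
recombMap <- function(positions, cM) {
  new("RecombMap", positions = as.numeric(positions), cM = as.numeric(cM))
}

#' Constant-rate genetic map
#'
#' A uniform map at a region-average rate, e.g. for a region where only the
#' averaged rate is known.
#'
#' @param positions bp coordinates.
#' @param rateCMperMb constant rate in cM/Mb.
#' @return A \linkS4class{RecombMap}.
#' @export
uniformGeneticMap <- function(positions, rateCMperMb) {
  cM <- (positions - positions[1]) / 1e6 * rateCMperMb
  recombMap(positions, cM)
}

#' @export
setMethod("show", "RecombMap", function(object) {
  cat(sprintf("RecombMap: %d SNPs, %.0f bp, %.4f cM\n",
              length(object@positions),
              diff(range(object@positions)),
              max(object@cM) - min(object@cM)))
})

#' Total genetic length of a map in Morgans
#' @param map a \linkS4class{RecombMap}.
#' @return length in Morgans (used as the haplotype recombination fraction).
#' @export
mapLengthMorgans <- function(map) (max(map@cM) - min(map@cM)) / 100

#' Haplotype geometry around the selected site
#'
#' Precomputes, from the genetic map and the mutant column, the quantities the
#' ancestral process needs: per-side cumulative genetic spans of a retained
#' extent of a SNPs (Morgans), the per-interval recombination fractions at
#' each possible breakpoint, and the total genetic length.
#'
#' @param map a \linkS4class{RecombMap} covering all SNPs.
#' @param mutantCol column index of the selected site.
#' @return A list with elements mutantCol, mL, mR, gL (length mL + 1,
#'   gL[a + 1] = span of a SNPs to the left), gR, bpL (length mL,
#'   bpL[a + 1] = interval from extent a to a + 1), bpR, gTot.
#' @export
haplotypeGeometry <- function(map, mutantCol) {
  stopifnot(is(map, "RecombMap"))
  validObject(map)
  M <- map@cM / 100
  m <- length(M); j0 <- as.integer(mutantCol)
  if (j0 < 1L || j0 > m) stop("mutant column outside the map")
  mL <- j0 - 1L; mR <- m - j0
  gL <- M[j0] - M[j0 - (0:mL)]
  gR <- M[j0 + (0:mR)] - M[j0]
  list(mutantCol = j0, mL = mL, mR = mR,
       gL = gL, gR = gR,
       bpL = if (mL > 0L) diff(gL) else numeric(),
       bpR = if (mR > 0L) diff(gR) else numeric(),
       gTot = M[m] - M[1])
}

#' The founder haplotype for a geometry
#'
#' The ancestral haplotype retains the whole analyzed region and carries no
#' mutations: code (m_L, m_R) with empty M.
#'
#' @param geom a geometry from \code{\link{haplotypeGeometry}}.
#' @return A \linkS4class{CodedHaplotype}.
#' @export
founderHaplotype <- function(geom) codedHaplotype(geom$mL, geom$mR)
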