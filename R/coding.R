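# Haplotype coding: reduction of selected haplotypes to recombination and
# mutation coordinates, and the configuration-editing operators.

hapKey <- function(h) paste(h@R1, h@R2, paste(h@M, collapse = ","), sep = "|")

#' Construct a coded haplotype
#'
#' @param R1,R2 retained SNP counts left/right of the mutant.
#' @param M integer vector of mutation coordinates (absolute 1-based SNP
#'   columns, most-recent first).
#' @return A \linkS4class{CodedHaplotype}.
#' @export
codedHaplotype <- function(R1, R2, M = integer()) {
  new("CodedHaplotype", R1 = as.integer(R1), R2 = as.integer(R2),
      M = as.integer(M))
}

#' Construct a sample configuration
#'
#' @param types list of \linkS4class{CodedHaplotype} (distinct).
#' @param mult integer multiplicities.
#' @return A \linkS4class{SampleConfig}.
#' @export
sampleConfig <- function(types, mult) {
  new("SampleConfig", types = types, mult = as.integer(mult))
}

#' @export
setMethod("show", "CodedHaplotype", function(object) {
  m <- if (length(object@M)) paste(",", paste(object@M, collapse = ", ")) else ""
  cat(sprintf("(%d, %d%s)\n", object@R1, object@R2, m))
})

#' @export
setMethod("show", "SampleConfig", function(object) {
  cat(sprintf("SampleConfig: %d types, n = %d\n",
              length(object@types), sum(object@mult)))
  for (i in seq_along(object@types)) {
    h <- object@types[[i]]
    m <- if (length(h@M)) paste(",", paste(h@M, collapse = ", ")) else ""
    cat(sprintf("  (%d, %d%s) x %d\n", h@R1, h@R2, m, object@mult[i]))
  }
})

#' @export
setMethod("show", "HaplotypeMatrix", function(object) {
  cat(sprintf("HaplotypeMatrix: %d haplotypes x %d SNPs, mutant at column %d\n",
              nrow(object@alleles), ncol(object@alleles), object@mutantCol))
})

#' Number of haplotypes in a configuration
#' @param cfg a \linkS4class{SampleConfig}.
#' @return total multiplicity.
#' @export
configSize <- function(cfg) sum(cfg@mult)

#' Construct a selected haplotype matrix
#'
#' @param alleles n x m 0/1 matrix, one row per selected haplotype.
#' @param mask n x m logical ancestral-descent mask.
#' @param positions physical bp positions of the m SNPs.
#' @param mutantPos physical position (or column index if
#'   \code{byIndex = TRUE}) of the selected site.
#' @param byIndex interpret \code{mutantPos} as a column index.
#' @return A \linkS4class{HaplotypeMatrix}.
#' @export
haplotypeMatrix <- function(alleles, mask, positions, mutantPos,
                            byIndex = FALSE) {
  alleles <- matrix(as.integer(alleles), nrow = nrow(alleles))
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  j0 <- if (byIndex) as.integer(mutantPos) else {
    j <- which(positions == mutantPos)
    if (length(j) != 1L)
      stop("mutant position ", mutantPos, " not found among SNP positions")
    j
  }
  new("HaplotypeMatrix", alleles = alleles, mask = mask,
      positions = as.numeric(positions), mutantCol = j0)
}

# Majority-vote ancestral allele per column over rows whose block covers it;
# ties broken toward the allele of the widest-block row.
consensusAncestral <- function(x) {
  m <- ncol(x@alleles)
  anc <- rep(NA_integer_, m)
  width <- rowSums(x@mask)
  for (j in seq_len(m)) {
    cover <- which(x@mask[, j])
    if (!length(cover)) next
    a <- x@alleles[cover, j]
    n1 <- sum(a == 1L)
    n0 <- length(a) - n1
    anc[j] <- if (n1 > n0) 1L else if (n0 > n1) 0L else
      x@alleles[cover[which.max(width[cover])], j]
  }
  anc
}

# Order mutation coordinates most-recent first by the nesting convention:
# a mutation carried by a strict subset of the carriers of another is more
# recent; ties broken by carrier count, then by SNP column.
orderMutations <- function(cols, carriers) {
  if (length(cols) <= 1L) return(cols)
  nc <- vapply(carriers, length, integer(1))
  ord <- order(nc, cols)
  cols[ord]
}

#' Encode a selected haplotype matrix into a sample configuration
#'
#' Each row is reduced to the SNP counts delimiting its contiguous ancestral
#' block left and right of the mutant, plus the absolute positions of alleles
#' inside the block that differ from the ancestral haplotype (mutation
#' coordinates, most-recent first by the nesting convention). Identical codes
#' are grouped with multiplicities in order of first occurrence.
#'
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @param ancestral optional integer vector of ancestral alleles per column;
#'   when NULL a majority consensus over covering rows is used.
#' @return A \linkS4class{SampleConfig}.
#' @export
encodeSample <- function(x, ancestral = NULL) {
  stopifnot(is(x, "HaplotypeMatrix"))
  validObject(x)
  if (is.null(ancestral)) ancestral <- consensusAncestral(x)
  n <- nrow(x@alleles); j0 <- x@mutantCol
  codes <- vector("list", n)
  mutcols <- integer()       # all mutation coordinates seen
  mutcarriers <- list()      # rows carrying each
  for (i in seq_len(n)) {
    w <- which(x@mask[i, ])
    R1 <- j0 - min(w); R2 <- max(w) - j0
    inblk <- setdiff(w, j0)
    mu <- inblk[x@alleles[i, inblk] != ancestral[inblk]]
    codes[[i]] <- list(R1 = R1, R2 = R2, M = mu)
    for (cc in mu) {
      k <- match(cc, mutcols)
      if (is.na(k)) { mutcols <- c(mutcols, cc); mutcarriers <- c(mutcarriers, list(i)) }
      else mutcarriers[[k]] <- c(mutcarriers[[k]], i)
    }
  }
  types <- list(); mult <- integer(); keys <- character()
  for (i in seq_len(n)) {
    cd <- codes[[i]]
    Mi <- cd$M
    if (length(Mi) > 1L) {
      carr <- mutcarriers[match(Mi, mutcols)]
      Mi <- orderMutations(Mi, carr)
    }
    h <- codedHaplotype(cd$R1, cd$R2, Mi)
    key <- hapKey(h)
    k <- match(key, keys)
    if (is.na(k)) { types <- c(types, h); mult <- c(mult, 1L); keys <- c(keys, key) }
    else mult[k] <- mult[k] + 1L
  }
  sampleConfig(types, mult)
}

#' Decode a configuration back to a haplotype matrix
#'
#' Inverse of \code{\link{encodeSample}} up to the arbitrary alleles outside
#' the ancestral blocks (set to \code{1 - ancestral}).
#'
#' @param cfg a \linkS4class{SampleConfig}.
#' @param positions SNP bp positions.
#' @param mutantCol column of the selected site.
#' @param ancestral ancestral allele per column (default all 1).
#' @return A \linkS4class{HaplotypeMatrix}.
#' @export
decodeConfig <- function(cfg, positions, mutantCol,
                         ancestral = rep(1L, length(positions))) {
  m <- length(positions); j0 <- mutantCol
  n <- configSize(cfg)
  alle <- matrix(0L, n, m); mask <- matrix(FALSE, n, m)
  r <- 1L
  for (k in seq_along(cfg@types)) {
    h <- cfg@types[[k]]
    for (rep_i in seq_len(cfg@mult[k])) {
      blk <- (j0 - h@R1):(j0 + h@R2)
      mask[r, blk] <- TRUE
      alle[r, ] <- 1L - ancestral
      alle[r, blk] <- ancestral[blk]
      if (length(h@M)) alle[r, h@M] <- 1L - ancestral[h@M]
      alle[r, j0] <- ancestral[j0]
      r <- r + 1L
    }
  }
  haplotypeMatrix(alle, mask, positions, j0, byIndex = TRUE)
}

#' Shift operator S: delete the first mutation coordinate
#'
#' @param h a \linkS4class{CodedHaplotype} with non-empty M.
#' @return The haplotype with M_1 removed; R1, R2 unchanged.
#' @export
shiftFirstMutation <- function(h) {
  if (!length(h@M)) stop("shift operator: haplotype has no mutation coordinate")
  codedHaplotype(h@R1, h@R2, h@M[-1L])
}

#' Coordinate-change operator C
#'
#' Replaces one recombination coordinate and eliminates all mutation
#' coordinates outside the new ancestral region.
#'
#' @param h a \linkS4class{CodedHaplotype}.
#' @param side "left" or "right".
#' @param newR new coordinate value (SNP count from the mutant).
#' @param mutantCol column index of the selected site (needed to filter M).
#' @return The changed haplotype.
#' @export
coordinateChange <- function(h, side = c("left", "right"), newR, mutantCol) {
  side <- match.arg(side)
  newR <- as.integer(newR)
  if (newR < 0L) stop("coordinate must be non-negative")
  R1 <- if (side == "left") newR else h@R1
  R2 <- if (side == "right") newR else h@R2
  lo <- mutantCol - R1; hi <- mutantCol + R2
  codedHaplotype(R1, R2, h@M[h@M >= lo & h@M <= hi])
}

#' Removal operator R_k: drop a type from a configuration
#'
#' @param cfg a \linkS4class{SampleConfig}.
#' @param k index of the type to remove.
#' @return The configuration without type k.
#' @export
removeType <- function(cfg, k) {
  if (k < 1L || k > length(cfg@types)) stop("type index out of range")
  sampleConfig(cfg@types[-k], cfg@mult[-k])
}

#' Ancestral fraction beta of a coded haplotype
#'
#' Genetic length of the retained ancestral segment divided by the genetic
#' length of the whole analyzed haplotype. Scales the per-haplotype mutation
#' and recombination rates (theta_i = theta * beta_i, rho_i = rho * beta_i).
#'
#' @param h a \linkS4class{CodedHaplotype}.
#' @param geom a geometry from \code{\link{haplotypeGeometry}}.
#' @return beta in [0, 1].
#' @export
ancestralFraction <- function(h, geom) {
  if (geom$gTot <= 0) stop("zero-length genetic map")
  (geom$gL[h@R1 + 1L] + geom$gR[h@R2 + 1L]) / geom$gTot
}
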