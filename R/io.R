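# Readers and writers: haplotype/mask TSV, phased VCF, genetic maps,
# demography tables, and run outputs. File coordinates are 1-based; all
# errors name the offending file.

#' Read a haplotype TSV
#'
#' One row per haplotype, columns = 0/1 alleles, header = physical bp
#' positions.
#'
#' @param file path.
#' @return list(alleles, positions).
#' @export
readHaplotypes <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  pos <- suppressWarnings(as.numeric(names(d)))
  if (anyNA(pos))
    stop("haplotype file ", file, ": header must be numeric bp positions")
  a <- as.matrix(d)
  if (!all(a %in% c(0, 1)))
    stop("haplotype file ", file, ": alleles must be 0/1")
  list(alleles = matrix(as.integer(a), nrow(a)), positions = pos)
}

#' Read an ancestral-state mask TSV
#'
#' Same shape as the haplotype file; 1 marks alleles descending from the
#' ancestral haplotype.
#'
#' @param file path.
#' @return logical matrix.
#' @export
readAncestralMask <- function(file) {
  d <- as.matrix(read.table(file, header = TRUE, sep = "\t",
                            check.names = FALSE))
  if (!all(d %in% c(0, 1)))
    stop("mask file ", file, ": entries must be 0/1")
  matrix(d == 1, nrow(d))
}

#' Read phased haplotypes from a VCF
#'
#' Phased GT fields are split into one row per haplotype (two per diploid
#' sample, one per haploid sample).
#'
#' @param file path to a VCF (requires the vcfR package).
#' @return list(alleles, positions).
#' @export
readHaplotypesVCF <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  pos <- as.numeric(vcfR::getPOS(v))
  haps <- list()
  for (j in seq_len(ncol(gt))) {
    g <- gt[, j]
    if (any(grepl("/", g, fixed = TRUE)))
      stop("VCF ", file, ": sample ", colnames(gt)[j], " is not phased")
    parts <- strsplit(g, "|", fixed = TRUE)
    nal <- unique(lengths(parts))
    if (length(nal) != 1)
      stop("VCF ", file, ": inconsistent ploidy in sample ", colnames(gt)[j])
    for (k in seq_len(nal))
      haps[[length(haps) + 1L]] <- as.integer(vapply(parts, `[`, "", k))
  }
  list(alleles = do.call(rbind, haps), positions = pos)
}

#' Read a genetic map file
#'
#' Whitespace table with columns (bp, rate cM/Mb, cumulative cM); a leading
#' chromosome column (HapMap dialect) is dropped. Cumulative positions must
#' be non-decreasing.
#'
#' @param file path.
#' @return data.frame(bp, rate, cM).
#' @export
readGeneticMap <- function(file) {
  d <- read.table(file, header = TRUE)
  num <- vapply(d, is.numeric, logical(1))
  if (sum(num) < 3) stop("map file ", file, ": need bp, rate and cM columns")
  d <- d[num][, seq_len(3)]
  names(d) <- c("bp", "rate", "cM")
  if (is.unsorted(d$bp, strictly = TRUE))
    stop("map file ", file, ": bp positions must be strictly increasing")
  if (is.unsorted(d$cM))
    stop("map file ", file, ": cumulative cM must be non-decreasing")
  d
}

#' Interpolate a genetic map at SNP positions
#'
#' @param mapTable data.frame from \code{\link{readGeneticMap}}.
#' @param positions SNP bp positions.
#' @return A \linkS4class{RecombMap}.
#' @export
mapAtPositions <- function(mapTable, positions) {
  cM <- approx(mapTable$bp, mapTable$cM, xout = positions, rule = 2)$y
  recombMap(positions, cM)
}

#' Read a demography table
#'
#' Two columns: epoch start generation (first row 0) and diploid size.
#'
#' @param file path.
#' @return A \linkS4class{Demography}.
#' @export
readDemography <- function(file) {
  d <- read.table(file, header = TRUE)
  if (ncol(d) < 2) stop("demography file ", file, ": need (t, N) columns")
  piecewiseDemography(d[, 1:2])
}

#' Load and cross-validate all inference inputs
#'
#' @param haplotypes path to the haplotype TSV or VCF (by extension).
#' @param mask path to the mask TSV.
#' @param mutantPos physical position of the selected site.
#' @param map optional path to a genetic-map file.
#' @param rateCMperMb constant-rate fallback when no map file is given.
#' @param demography optional path to a demography table.
#' @param N constant size used when no demography file is given.
#' @return list(haplotypes = \linkS4class{HaplotypeMatrix},
#'   map = \linkS4class{RecombMap}, demography =
#'   \linkS4class{Demography}).
#' @export
loadInputs <- function(haplotypes, mask, mutantPos, map = NULL,
                       rateCMperMb = NULL, demography = NULL, N = NULL) {
  hp <- if (grepl("\\.vcf(\\.gz)?$", haplotypes))
    readHaplotypesVCF(haplotypes) else readHaplotypes(haplotypes)
  mk <- readAncestralMask(mask)
  if (!all(dim(mk) == dim(hp$alleles)))
    stop("mask file ", mask, ": shape ", paste(dim(mk), collapse = "x"),
         " does not match haplotypes ",
         paste(dim(hp$alleles), collapse = "x"))
  if (!mutantPos %in% hp$positions)
    stop("haplotype file ", haplotypes, ": mutant position ", mutantPos,
         " is not among the SNP positions")
  rm <- if (!is.null(map)) {
    mt <- readGeneticMap(map)
    if (min(hp$positions) < min(mt$bp) || max(hp$positions) > max(mt$bp))
      warning("map file ", map, " does not span all SNPs; edge rates held")
    mapAtPositions(mt, hp$positions)
  } else if (!is.null(rateCMperMb)) {
    uniformGeneticMap(hp$positions, rateCMperMb)
  } else stop("either a map file or a constant rate must be supplied")
  dm <- if (!is.null(demography)) readDemography(demography)
  else if (!is.null(N)) constantDemography(N)
  else stop("either a demography file or a constant N must be supplied")
  # inference uses the selected haplotypes: rows carrying the mutant
  j0 <- match(mutantPos, hp$positions)
  sel <- hp$alleles[, j0] == 1L
  if (!any(sel))
    stop("haplotype file ", haplotypes,
         ": no row carries the selected allele at ", mutantPos)
  if (!all(sel))
    message(sum(!sel), " background haplotype(s) without the selected ",
            "allele dropped")
  hm <- haplotypeMatrix(hp$alleles[sel, , drop = FALSE],
                        mk[sel, , drop = FALSE], hp$positions, mutantPos)
  validObject(hm)
  list(haplotypes = hm, map = rm, demography = dm)
}

#' Write a likelihood curve as TSV
#' @param curve a \linkS4class{LikelihoodCurve}.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeLikelihoodCurve <- function(curve, file) {
  write.table(curve@grid, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a JSON run summary
#' @param curve a \linkS4class{LikelihoodCurve}.
#' @param file output path.
#' @param extra named list merged into the summary.
#' @return invisibly, the file path.
#' @export
writeRunSummary <- function(curve, file, extra = list()) {
  out <- c(list(sHat = curve@sHat, ciLower = curve@ci[1],
                ciUpper = curve@ci[2], level = curve@level,
                M = curve@M, K = curve@K, seed = curve@seed,
                bandwidth = curve@bandwidth), extra)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Write an age posterior as TSV
#' @param post an \linkS4class{AgePosterior}.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeAgePosterior <- function(post, file) {
  write.table(post@samples, file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' Write a trajectory as two-column TSV (t, I_t)
#' @param traj a \linkS4class{SweepTrajectory}.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeTrajectory <- function(traj, file) {
  write.table(data.frame(t = seq_along(traj@I) - 1L, I = traj@I), file,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a simulated dataset (haplotypes, mask, truth)
#'
#' Emits <prefix>_haplotypes.tsv, <prefix>_mask.tsv and
#' <prefix>_truth.json.
#'
#' @param ds a \linkS4class{SweepDataset}.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
writeDataset <- function(ds, prefix) {
  hf <- paste0(prefix, "_haplotypes.tsv")
  mf <- paste0(prefix, "_mask.tsv")
  tf <- paste0(prefix, "_truth.json")
  a <- as.data.frame(ds@alleles)
  names(a) <- ds@positions
  write.table(a, hf, sep = "\t", row.names = FALSE, quote = FALSE)
  mk <- as.data.frame(ds@mask * 1L)
  names(mk) <- ds@positions
  write.table(mk, mf, sep = "\t", row.names = FALSE, quote = FALSE)
  tr <- ds@truth
  tr$I <- NULL
  tr <- c(tr, list(mutantPos = ds@positions[ds@mutantCol],
                   nSelected = ds@nSelected))
  jsonlite::write_json(tr, tf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(hf, mf, tf))
}
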