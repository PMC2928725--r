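## S4 classes for the central data objects. Configuration bundles are plain
## validated lists (see simConfig(), phenotypeConfig(), experimentConfig()).

#' Two-locus table of genotypic means
#'
#' A centered 3 x 3 table of genotypic means for a two-locus biallelic
#' system. Rows index the genotype at locus A (AA, Aa, aa = 0, 1, 2 copies
#' of the minor allele), columns the genotype at locus B (BB, Bb, bb). The
#' table carries the epistasis pattern code it was built under and the fixed
#' phenotypic range (difference between the largest and smallest mean, in
#' residual-SD units).
#'
#' @slot theta 3 x 3 numeric matrix of genotypic means, unweighted sum 0.
#' @slot pattern single character, one of \code{"a"}-\code{"f"}.
#' @slot rangeTarget positive numeric, \code{max(theta) - min(theta)}.
#'
#' @seealso [makePatternTable()], [checkPatternConstraints()]
#' @export
setClass("GenotypeMeansTable",
  representation(theta = "matrix", pattern = "character",
                 rangeTarget = "numeric"))

setValidity("GenotypeMeansTable", function(object) {
  msg <- character()
  th <- object@theta
  if (!is.numeric(th) || !identical(dim(th), c(3L, 3L)))
    msg <- c(msg, "theta must be a numeric 3 x 3 matrix")
  if (length(object@pattern) != 1L ||
      !object@pattern %in% c("a", "b", "c", "d", "e", "f"))
    msg <- c(msg, "pattern must be one of 'a'..'f'")
  if (length(object@rangeTarget) != 1L || object@rangeTarget <= 0)
    msg <- c(msg, "rangeTarget must be a positive scalar")
  if (!length(msg) && is.numeric(th) && identical(dim(th), c(3L, 3L))) {
    if (abs(sum(th)) > 1e-9)
      msg <- c(msg, "theta must be centered (unweighted sum 0)")
    if (abs((max(th) - min(th)) - object@rangeTarget) >
        1e-9 * max(1, object@rangeTarget))
      msg <- c(msg, "max(theta) - min(theta) must equal rangeTarget")
    if (!checkPatternConstraints(th, object@pattern))
      msg <- c(msg, sprintf("theta violates the pattern-%s equality constraints",
                            object@pattern))
  }
  if (length(msg)) msg else TRUE
})

#' Sum-to-zero factor-effects decomposition of a means table
#'
#' Result of [decomposeEffects()]: grand mean, main effects and interaction
#' effects under the usual sum-to-zero identifiability constraints, with
#' \code{mu + alpha[i] + beta[j] + gamma[i, j]} reconstructing the cell means
#' exactly.
#'
#' @slot mu numeric grand mean (unweighted).
#' @slot alpha,beta numeric 3-vectors of row/column main effects, sum 0.
#' @slot gamma 3 x 3 interaction matrix, all row and column sums 0.
#' @export
setClass("FactorEffects",
  representation(mu = "numeric", alpha = "numeric", beta = "numeric",
                 gamma = "matrix"))

setValidity("FactorEffects", function(object) {
  msg <- character()
  if (length(object@alpha) != 3L || length(object@beta) != 3L ||
      !identical(dim(object@gamma), c(3L, 3L)))
    return("alpha/beta must have length 3 and gamma be 3 x 3")
  tol <- 1e-9
  if (abs(sum(object@alpha)) > tol) msg <- c(msg, "alpha must sum to 0")
  if (abs(sum(object@beta)) > tol) msg <- c(msg, "beta must sum to 0")
  if (max(abs(rowSums(object@gamma))) > tol ||
      max(abs(colSums(object@gamma))) > tol)
    msg <- c(msg, "gamma rows and columns must sum to 0")
  if (length(msg)) msg else TRUE
})

#' Expected sums of squares for the balanced two-way cell-means model
#'
#' @slot essA,essB,essEpistasis non-negative expected sums of squares for
#'   the locus-A, locus-B and interaction sources (squared phenotype units;
#'   the error-variance term common to all sources is omitted).
#' @slot dfA,dfB,dfEpistasis integer degrees of freedom (2, 2, 4 for 3 x 3).
#' @slot totalEss sum of the three components.
#' @seealso [expectedSS()]
#' @export
setClass("EssTable",
  representation(essA = "numeric", essB = "numeric", essEpistasis = "numeric",
                 dfA = "integer", dfB = "integer", dfEpistasis = "integer",
                 totalEss = "numeric"))

setValidity("EssTable", function(object) {
  msg <- character()
  ess <- c(object@essA, object@essB, object@essEpistasis)
  if (any(ess < -1e-9)) msg <- c(msg, "ESS components must be non-negative")
  if (abs(object@totalEss - sum(ess)) > 1e-9 * max(1, sum(ess)))
    msg <- c(msg, "totalEss must equal essA + essB + essEpistasis")
  if (length(msg)) msg else TRUE
})

#' Panel of simulated binary haplotypes
#'
#' Binary haplotype matrix (2n haplotypes x M markers) with the marker map:
#' chromosome assignment, 1-based position (marker index within its
#' chromosome) and QTL flags. Haplotypes 2k-1 and 2k belong to diploid
#' individual k.
#'
#' @slot haplotypes integer 0/1 matrix, rows = haplotypes, cols = markers.
#' @slot chrom integer chromosome of each marker.
#' @slot pos integer 1-based marker index within its chromosome.
#' @slot qtl logical QTL flag per marker.
#' @seealso [simulatePanel()], [assembleDiploids()]
#' @export
setClass("HaplotypePanel",
  representation(haplotypes = "matrix", chrom = "integer", pos = "integer",
                 qtl = "logical"))

.validMarkerMap <- function(object, nmarkers) {
  msg <- character()
  if (length(object@chrom) != nmarkers || length(object@pos) != nmarkers ||
      length(object@qtl) != nmarkers)
    msg <- c(msg, "chrom, pos and qtl must have one entry per marker column")
  msg
}

setValidity("HaplotypePanel", function(object) {
  h <- object@haplotypes
  msg <- character()
  if (!all(h %in% c(0L, 1L))) msg <- c(msg, "haplotypes must be 0/1")
  if (nrow(h) %% 2L != 0L) msg <- c(msg, "haplotype count must be even")
  msg <- c(msg, .validMarkerMap(object, ncol(h)))
  if (length(msg)) msg else TRUE
})

#' Diploid genotype dosage matrix
#'
#' Integer matrix (n individuals x M markers) of minor/derived allele counts
#' in \{0, 1, 2\}, with the same marker map as [HaplotypePanel-class].
#'
#' @slot genotypes integer matrix with entries in 0..2.
#' @slot chrom,pos,qtl marker map as in [HaplotypePanel-class].
#' @export
setClass("GenotypeMatrix",
  representation(genotypes = "matrix", chrom = "integer", pos = "integer",
                 qtl = "logical"))

setValidity("GenotypeMatrix", function(object) {
  g <- object@genotypes
  msg <- character()
  if (anyNA(g) || !all(g %in% 0:2))
    msg <- c(msg, "genotypes must be complete with entries in {0, 1, 2}")
  msg <- c(msg, .validMarkerMap(object, ncol(g)))
  if (length(msg)) msg else TRUE
})

#' Fit of one full (cell-means) marker model
#'
#' One mean is fit per observed multi-locus genotype class, i.e. main
#' effects and all interactions jointly; empty cells simply reduce the model
#' degrees of freedom.
#'
#' @slot markers character ids of the markers in the model.
#' @slot nClasses integer count g of distinct observed genotype classes.
#' @slot rss,tss residual and total (centered) sums of squares.
#' @slot dfModel,dfError integer, g - 1 and n - g.
#' @slot fStat,pValue overall F statistic and its central-F p-value.
#' @slot r2 coefficient of determination, 1 - rss/tss.
#' @slot bic Bayesian Information Criterion (see [bicScore()]); -Inf when
#'   the fit is exact (rss = 0).
#' @seealso [fitFullModel()]
#' @export
setClass("ModelFit",
  representation(markers = "character", nClasses = "integer", rss = "numeric",
                 tss = "numeric", dfModel = "integer", dfError = "integer",
                 fStat = "numeric", pValue = "numeric", r2 = "numeric",
                 bic = "numeric"))

setValidity("ModelFit", function(object) {
  msg <- character()
  if (object@rss > object@tss + 1e-9 * max(1, object@tss))
    msg <- c(msg, "rss cannot exceed tss")
  if (object@r2 < -1e-9 || object@r2 > 1 + 1e-9)
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Outcome of the two-step BIC model selection scan
#'
#' @slot reducedSet marker ids surviving the block-wise step-1 reduction.
#' @slot bestModel marker ids of the minimum-BIC model from step 2 (empty
#'   when the intercept-only model wins).
#' @slot bestBIC the winning BIC value.
#' @slot audit list with the per-block step-1 winners and a (size-capped)
#'   step-2 candidate table.
#' @seealso [step1Reduce()], [step2Select()]
#' @export
setClass("SelectionResult",
  representation(reducedSet = "character", bestModel = "character",
                 bestBIC = "numeric", audit = "list"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (length(object@bestModel) > 3L)
    msg <- c(msg, "bestModel may contain at most 3 markers")
  if (!all(object@bestModel %in% object@reducedSet))
    msg <- c(msg, "bestModel must be a subset of reducedSet")
  if (length(msg)) msg else TRUE
})
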