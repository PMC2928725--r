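## Two-locus genetic models: the additive model and five patterns of
## molecular epistasis, expressed as equality constraints among the nine
## genotypic means of a 3 x 3 Punnett square.

# additive base: theta_ij = a*(1 - i) + a*(1 - j) with a = 1, i/j = minor
# allele count
.patternBase <- function() {
  u <- c(1, 0, -1)
  outer(u, u, `+`)
}

# equality groups as linear (column-major) indices into the 3 x 3 table.
# row aa = {3, 6, 9}; column bb = {7, 8, 9}.
.patternGroups <- list(
  a = list(),
  # recessive epistasis: bb masks the A locus
  b = list(c(7L, 8L, 9L)),
  # recessive epistasis plus dominance of A (AA = Aa) in non-masked columns
  c = list(c(7L, 8L, 9L), c(1L, 2L), c(4L, 5L)),
  # both aa and bb are masking; the shared corner ties all five cells
  d = list(c(3L, 6L, 7L, 8L, 9L)),
  # d plus dominance at A: only two distinct values remain
  e = list(c(3L, 6L, 7L, 8L, 9L), c(1L, 2L, 4L, 5L))
)

.PATTERN_CODES <- c("a", "b", "c", "d", "e", "f")

#' Construct the canonical means table for a two-locus genetic model
#'
#' Builds the centered 3 x 3 table of genotypic means for one of six
#' two-locus models: \code{"a"} additive (no epistasis); \code{"b"}
#' recessive epistasis (the bb genotype masks the A locus); \code{"c"}
#' recessive epistasis combined with dominance of the A allele; \code{"d"}
#' recessive epistasis at both loci; \code{"e"} recessive epistasis at both
#' loci plus dominance at A, leaving only two distinct mean values;
#' \code{"f"} additive-by-additive epistasis,
#' \eqn{\theta_{ij} = \delta u_i u_j} with \eqn{u = (+1, 0, -1)}, which has
#' no main effects at equal genotype weights.
#'
#' Patterns b-e are realized canonically: starting from the additive base
#' \eqn{\theta_{ij} = (1-i) + (1-j)}, each constrained cell group is replaced
#' by the unweighted mean of the base values it merges, the table is
#' recentered to sum zero, and rescaled so that the difference between the
#' largest and smallest mean equals \code{rangeTarget}. Holding this
#' phenotypic range fixed (1.6 residual SD by default) is what makes the six
#' models comparable in a power study: effect size is constant, only the
#' pattern of masking differs.
#'
#' @param pattern model code, one of \code{"a"}-\code{"f"}.
#' @param rangeTarget positive phenotypic range of the means, in units of
#'   the residual standard deviation (default 1.6).
#' @return A [GenotypeMeansTable-class].
#' @examples
#' makePatternTable("a")
#' theta(makePatternTable("f", 1.6))
#' @export
makePatternTable <- function(pattern, rangeTarget = 1.6) {
  if (!(is.character(pattern) && length(pattern) == 1L &&
        pattern %in% .PATTERN_CODES))
    stop("unknown pattern code; must be one of ",
         paste(.PATTERN_CODES, collapse = ", "))
  if (!is.numeric(rangeTarget) || length(rangeTarget) != 1L || rangeTarget <= 0)
    stop("rangeTarget must be a positive scalar")

  if (pattern == "f") {
    u <- c(1, 0, -1)
    th <- outer(u, u) * (rangeTarget / 2)
  } else {
    base <- .patternBase()
    th <- base
    for (grp in .patternGroups[[pattern]]) th[grp] <- mean(base[grp])
    th <- th - mean(th)
    th <- th * (rangeTarget / (max(th) - min(th)))
  }
  dimnames(th) <- list(.ROW_LABELS, .COL_LABELS)
  new("GenotypeMeansTable", theta = th, pattern = pattern,
      rangeTarget = rangeTarget)
}

#' Check the equality constraints of an epistasis pattern
#'
#' Tests whether a 3 x 3 means table satisfies the masking (equality)
#' constraints of a given pattern within tolerance. Pattern \code{"a"} is
#' unconstrained and always passes; pattern \code{"f"} requires the
#' additive-by-additive form \eqn{\theta_{ij} = \delta u_i u_j}.
#'
#' @param table a [GenotypeMeansTable-class] (checked against its own
#'   pattern) or a bare 3 x 3 numeric matrix.
#' @param pattern pattern code; required when \code{table} is a bare matrix.
#' @param tol absolute tolerance in phenotype units.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
checkPatternConstraints <- function(table, pattern = NULL, tol = 1e-9) {
  if (is(table, "GenotypeMeansTable")) {
    if (is.null(pattern)) pattern <- table@pattern
    th <- table@theta
  } else {
    th <- table
  }
  if (is.null(pattern)) stop("pattern must be given for a bare matrix")
  stopifnot(is.numeric(th), identical(dim(th), c(3L, 3L)))

  if (pattern == "f") {
    u <- c(1, 0, -1)
    delta <- th[1, 1]
    return(max(abs(th - delta * outer(u, u))) <= tol)
  }
  for (grp in .patternGroups[[pattern]]) {
    if (max(th[grp]) - min(th[grp]) > tol) return(FALSE)
  }
  TRUE
}

#' Per-locus genotype frequencies
#'
#' Bundles the genotype class frequencies at the two loci. The joint
#' frequency of cell (i, j) is the product \code{locusA[i] * locusB[j]}
#' (unlinked, independent loci).
#'
#' @param locusA,locusB numeric 3-vectors of genotype frequencies in the
#'   order 0, 1, 2 copies of the minor allele; each must be non-negative and
#'   sum to 1.
#' @return A list with elements \code{locusA} and \code{locusB}.
#' @seealso [hwGenotypeFrequencies()] for Hardy-Weinberg proportions,
#'   [equalGenotypeFrequencies()] for uniform 1/3 weights.
#' @export
genotypeFrequencies <- function(locusA, locusB = locusA) {
  check <- function(p, nm) {
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(nm, " must be 3 non-negative frequencies summing to 1")
    p
  }
  list(locusA = check(locusA, "locusA"), locusB = check(locusB, "locusB"))
}

#' @rdname genotypeFrequencies
#' @param maf,mafA,mafB minor allele frequency (0 < maf <= 0.5).
#' @export
hwGenotypeFrequencies <- function(mafA, mafB = mafA) {
  hw <- function(m) {
    stopifnot(m > 0, m <= 0.5)
    c((1 - m)^2, 2 * m * (1 - m), m^2)
  }
  genotypeFrequencies(hw(mafA), hw(mafB))
}

#' @rdname genotypeFrequencies
#' @export
equalGenotypeFrequencies <- function() {
  genotypeFrequencies(rep(1 / 3, 3))
}

#' Marginal (frequency-weighted) effects of a two-locus means table
#'
#' Row marginal i is the genotype-frequency-weighted average of row i over
#' the locus-B classes, and analogously for columns. With equal weights
#' these are the unweighted row/column means; with unequal allele
#' frequencies the weighting can create marginal effects even for the purely
#' interactive pattern f, which is how epistatic loci become visible to
#' single-locus scans in natural populations.
#'
#' @param table a [GenotypeMeansTable-class].
#' @param freqs genotype frequencies from [genotypeFrequencies()].
#' @return list with numeric 3-vectors \code{rowMeans} and \code{colMeans}.
#' @export
marginalEffects <- function(table, freqs = equalGenotypeFrequencies()) {
  th <- theta(table)
  rm <- as.vector(th %*% freqs$locusB)
  cm <- as.vector(freqs$locusA %*% th)
  list(rowMeans = stats::setNames(rm, .ROW_LABELS),
       colMeans = stats::setNames(cm, .COL_LABELS))
}

#' Expected proportion of phenotypic variance explained by the QTL pair
#'
#' Computes \eqn{Var_G / (Var_G + \sigma^2)} where the genetic variance is
#' \eqn{Var_G = \sum_{ij} p_i q_j (\theta_{ij} - \bar\theta_w)^2} with
#' \eqn{\bar\theta_w} the frequency-weighted mean: the population value the
#' full-model \eqn{r^2} of the correct two-QTL model converges to.
#'
#' @inheritParams marginalEffects
#' @param errorSd residual standard deviation (> 0).
#' @return scalar in \[0, 1).
#' @export
expectedR2 <- function(table, freqs, errorSd = 1) {
  stopifnot(errorSd > 0)
  th <- theta(table)
  w <- outer(freqs$locusA, freqs$locusB)
  mu <- sum(w * th)
  varG <- sum(w * (th - mu)^2)
  varG / (varG + errorSd^2)
}
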