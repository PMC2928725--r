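## Cell-means / factor-effects two-way model: exact expected sums of
## squares, analytic noncentral-F power, full-model fits and BIC scoring.

#' Sum-to-zero factor-effects decomposition
#'
#' Decomposes a 3 x 3 means table into grand mean, main effects and
#' interaction effects with unweighted sum-to-zero constraints:
#' \eqn{\mu} = grand mean, \eqn{\alpha_i} = row mean - \eqn{\mu},
#' \eqn{\beta_j} = column mean - \eqn{\mu},
#' \eqn{\gamma_{ij} = \theta_{ij} - \mu - \alpha_i - \beta_j}.
#' The reconstruction is exact. An additive table yields \eqn{\gamma = 0};
#' the additive-by-additive pattern f yields \eqn{\alpha = \beta = 0} and
#' \eqn{\gamma = \theta}.
#'
#' @param table a [GenotypeMeansTable-class] or bare 3 x 3 numeric matrix.
#' @return A [FactorEffects-class].
#' @export
decomposeEffects <- function(table) {
  th <- if (is(table, "GenotypeMeansTable")) theta(table) else table
  stopifnot(is.numeric(th), identical(dim(th), c(3L, 3L)))
  mu <- mean(th)
  alpha <- rowMeans(th) - mu
  beta <- colMeans(th) - mu
  gamma <- th - mu - outer(alpha, rep(1, 3)) - outer(rep(1, 3), beta)
  new("FactorEffects", mu = mu, alpha = unname(alpha), beta = unname(beta),
      gamma = unname(gamma))
}

#' Expected sums of squares for the balanced two-way design
#'
#' For a balanced 3 x 3 design with \code{nPerCell} observations per cell,
#' the expected sums of squares (error term omitted, as it is common to all
#' sources) are
#' \deqn{ESS_A = 3 n \sum_i \alpha_i^2, \quad ESS_B = 3 n \sum_j \beta_j^2,
#'   \quad ESS_{epi} = n \sum_{ij} \gamma_{ij}^2}
#' with degrees of freedom 2, 2 and 4. Each ESS is proportional to the
#' noncentrality parameter of the corresponding F test, so larger ESS means
#' larger power; the total over the three sources equals
#' \eqn{n \sum_{ij} (\theta_{ij} - \bar\theta)^2}.
#'
#' @param effects a [FactorEffects-class] (or a [GenotypeMeansTable-class],
#'   which is decomposed first).
#' @param nPerCell observations per cell, at least 1.
#' @return An [EssTable-class].
#' @export
expectedSS <- function(effects, nPerCell = 1L) {
  if (is(effects, "GenotypeMeansTable")) effects <- decomposeEffects(effects)
  stopifnot(is(effects, "FactorEffects"))
  if (!is.numeric(nPerCell) || length(nPerCell) != 1L || nPerCell < 1)
    stop("nPerCell must be at least 1")
  essA <- 3 * nPerCell * sum(effects@alpha^2)
  essB <- 3 * nPerCell * sum(effects@beta^2)
  essE <- nPerCell * sum(effects@gamma^2)
  new("EssTable", essA = essA, essB = essB, essEpistasis = essE,
      dfA = 2L, dfB = 2L, dfEpistasis = 4L, totalEss = essA + essB + essE)
}

#' Analytic power of an F test from its expected sum of squares
#'
#' The F statistic of a fixed-effects source follows a noncentral F
#' distribution with noncentrality \eqn{\lambda = ESS / \sigma^2}; because
#' the noncentral F family has monotone likelihood ratio in \eqn{\lambda},
#' power is strictly increasing in the ESS. This returns
#' \eqn{P(F' > F_{crit})} where \eqn{F_{crit}} is the central-F upper
#' \eqn{\alpha} quantile.
#'
#' @param ess expected sum of squares of the tested source (>= 0).
#' @param dfNum,dfErr numerator and denominator degrees of freedom.
#' @param errorVar residual variance (> 0).
#' @param alphaLevel test size in (0, 1).
#' @return power in \[alphaLevel, 1\].
#' @examples
#' analyticPower(0, 8, 91)                  # null: power equals alpha
#' analyticPower(1.92 * 500 / 9, 8, 491)    # balanced n = 500, additive table
#' @export
analyticPower <- function(ess, dfNum, dfErr, errorVar = 1,
                          alphaLevel = 0.05) {
  stopifnot(dfNum >= 1, dfErr >= 1, errorVar > 0,
            alphaLevel > 0, alphaLevel < 1, ess >= 0)
  fcrit <- qf(1 - alphaLevel, dfNum, dfErr)
  pf(fcrit, dfNum, dfErr, ncp = ess / errorVar, lower.tail = FALSE)
}

# fast internal kernel: class-means fit from a phenotype and an integer
# class id vector (values in 1..nbins). Returns g, rss, tss.
.fastFit <- function(y, cls, nbins = max(cls)) {
  n <- length(y)
  y <- y - sum(y) / n  # center for numerical stability
  cnt <- tabulate(cls, nbins)
  S <- rowsum(y, cls, reorder = TRUE)  # sums over sorted unique classes
  nz <- cnt > 0L
  g <- sum(nz)
  tss <- sum(y * y)
  between <- sum(S * S / cnt[nz])
  list(g = g, rss = max(tss - between, 0), tss = tss)
}

# class ids (1-based) from a 0/1/2 genotype matrix restricted to `markers`
.classIds <- function(gmat) {
  k <- ncol(gmat)
  if (k <= 8L) {
    cls <- gmat[, 1L]
    if (k > 1L) for (j in 2:k) cls <- cls * 3L + gmat[, j]
    cls + 1L
  } else {
    as.integer(interaction(as.data.frame(gmat), drop = TRUE))
  }
}

#' Fit the full (cell-means) model for a marker set
#'
#' Fits one mean per *observed* multi-locus genotype class -- the full
#' factorial model with main effects and all interactions -- so empty cells
#' reduce the model degrees of freedom automatically, as required for
#' unbalanced population samples. The overall test is
#' \deqn{F = \frac{(TSS - RSS)/(g - 1)}{RSS/(n - g)}}
#' with g the number of observed classes, and the p-value is taken from the
#' central F distribution.
#'
#' @param genotypes a [GenotypeMatrix-class] or bare integer 0/1/2 matrix.
#' @param phenotype numeric trait vector, one entry per individual.
#' @param markers marker ids (or column indices) to include; default all
#'   columns of \code{genotypes}.
#' @return A [ModelFit-class]. A perfect fit (rss = 0) is reported with
#'   p-value 0 and BIC \code{-Inf} (with a warning).
#' @section Errors: a marker set with a single observed class is
#'   unfittable; \code{n <= g} leaves no error degrees of freedom. Both stop
#'   with an informative message; the search functions screen candidates
#'   first.
#' @export
fitFullModel <- function(genotypes, phenotype, markers = NULL) {
  gmat <- if (is(genotypes, "GenotypeMatrix")) slot(genotypes, "genotypes")
          else genotypes
  if (!is.null(markers)) gmat <- gmat[, markers, drop = FALSE]
  if (is.null(dim(gmat))) gmat <- matrix(gmat, ncol = 1L)
  n <- nrow(gmat)
  if (length(phenotype) != n)
    stop("phenotype length must match the number of individuals")
  if (anyNA(gmat) || anyNA(phenotype))
    stop("missing genotype or phenotype values are not supported")

  cls <- .classIds(gmat)
  fit <- .fastFit(phenotype, cls)
  g <- fit$g
  if (g < 2L) stop("monomorphic marker combination: single genotype class")
  if (n <= g) stop("n <= number of genotype classes: no error df")
  if (fit$tss <= 0) stop("constant phenotype: total sum of squares is zero")

  dfm <- g - 1L
  dfe <- n - g
  if (fit$rss == 0) {
    f <- Inf; p <- 0; r2 <- 1
  } else {
    f <- ((fit$tss - fit$rss) / dfm) / (fit$rss / dfe)
    p <- pf(f, dfm, dfe, lower.tail = FALSE)
    r2 <- 1 - fit$rss / fit$tss
  }
  ids <- colnames(gmat)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(gmat)))
  new("ModelFit", markers = ids, nClasses = as.integer(g), rss = fit$rss,
      tss = fit$tss, dfModel = as.integer(dfm), dfError = as.integer(dfe),
      fStat = f, pValue = p, r2 = r2, bic = bicScore(fit$rss, g, n))
}

#' BIC of a class-means model
#'
#' \deqn{BIC = n \log(RSS/n) + (g + 1) \log n}
#' where g is the number of fitted class means and the +1 counts the error
#' variance. Only differences matter: models are comparable when fit to the
#' same n observations. Lower is better.
#'
#' @param x residual sum of squares, or a [ModelFit-class].
#' @param g number of fitted class means (ignored when \code{x} is a
#'   [ModelFit-class]).
#' @param n number of observations.
#' @return scalar BIC; \code{-Inf} (with a warning) when rss is 0.
#' @export
bicScore <- function(x, g, n) {
  if (is(x, "ModelFit")) {
    g <- x@nClasses
    x <- x@rss
  }
  stopifnot(n > 0, g >= 1)
  if (x <= 0) {
    warning("rss = 0: returning -Inf (saturated model wins)")
    return(-Inf)
  }
  n * log(x / n) + (g + 1) * log(n)
}
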