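## Phenotype generation: cell mean of the two-QTL genotype plus iid
## standard-normal error, so the fixed 1.6 range of the means is expressed
## in residual-SD units.

#' Phenotype generation configuration
#'
#' @param table a [GenotypeMeansTable-class] giving the genotypic means.
#' @param qtlA,qtlB marker ids (or column indices) of the two trait loci;
#'   locus A indexes the table rows, locus B the columns.
#' @param errorSd residual standard deviation (default 1, the scale on which
#'   the table's range is expressed).
#' @param seed integer seed for the error draws.
#' @return a validated list of class \code{"PhenotypeConfig"}.
#' @export
phenotypeConfig <- function(table, qtlA, qtlB, errorSd = 1, seed = 1L) {
  stopifnot(is(table, "GenotypeMeansTable"), errorSd >= 0)
  structure(list(table = table, qtlA = qtlA, qtlB = qtlB,
                 errorSd = errorSd, seed = as.integer(seed)),
            class = "PhenotypeConfig")
}

#' Generate phenotypes from two QTL genotypes
#'
#' \deqn{y_k = \theta[g_k(A), g_k(B)] + \epsilon_k, \qquad
#'       \epsilon_k \sim N(0, \sigma^2)}
#' where \eqn{g_k} are the 0/1/2 minor-allele dosages at the two QTL. With
#' \code{errorSd = 0} the phenotypes equal the cell means exactly (at most 9
#' distinct values; 2 for pattern e).
#'
#' @param genotypes a [GenotypeMatrix-class] (or bare 0/1/2 matrix with
#'   column names).
#' @param config a [phenotypeConfig()] object; its seed is applied here.
#' @return numeric vector of length n (named by individual when the
#'   genotype matrix has row names).
#' @export
generatePhenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "PhenotypeConfig"))
  gmat <- if (is(genotypes, "GenotypeMatrix")) slot(genotypes, "genotypes")
          else genotypes
  ga <- gmat[, config$qtlA]
  gb <- gmat[, config$qtlB]
  if (anyNA(ga) || anyNA(gb))
    stop("missing genotype entries at the QTL markers")
  if (!all(ga %in% 0:2) || !all(gb %in% 0:2))
    stop("QTL genotypes must be 0/1/2 dosages")
  th <- theta(config$table)
  set.seed(config$seed)
  y <- th[cbind(ga + 1L, gb + 1L)] +
    rnorm(length(ga), mean = 0, sd = config$errorSd)
  names(y) <- rownames(gmat)
  y
}
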