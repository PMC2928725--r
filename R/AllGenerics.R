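#' @name accessors
#' @title Accessors for epiqtl classes
#'
#' @description Slot accessors: \code{theta()} and \code{patternCode()} /
#' \code{rangeTarget()} for [GenotypeMeansTable-class]; \code{haplotypes()} /
#' \code{genotypes()} for the panel classes; \code{markerInfo()} returns the
#' marker map (id, chromosome, position, QTL flag) as a data.frame;
#' \code{qtlMarkers()} the ids of the flagged QTL markers; \code{nMarkers()}
#' and \code{nIndividuals()} the panel dimensions; \code{reducedSet()},
#' \code{bestModel()} and \code{bestBIC()} the components of a
#' [SelectionResult-class].
#'
#' @param x an epiqtl object.
#' @return The corresponding slot (or derived summary) of \code{x}.
NULL

#' @rdname accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))
#' @rdname accessors
#' @export
setMethod("theta", "GenotypeMeansTable", function(x) x@theta)

#' @rdname accessors
#' @export
setGeneric("patternCode", function(x) standardGeneric("patternCode"))
#' @rdname accessors
#' @export
setMethod("patternCode", "GenotypeMeansTable", function(x) x@pattern)

#' @rdname accessors
#' @export
setGeneric("rangeTarget", function(x) standardGeneric("rangeTarget"))
#' @rdname accessors
#' @export
setMethod("rangeTarget", "GenotypeMeansTable", function(x) x@rangeTarget)

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@genotypes)

#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

.markerInfoFrame <- function(x, mat) {
  data.frame(marker = colnames(mat), chrom = x@chrom, pos = x@pos,
             qtl = x@qtl, row.names = NULL, stringsAsFactors = FALSE)
}
#' @rdname accessors
#' @export
setMethod("markerInfo", "HaplotypePanel",
          function(x) .markerInfoFrame(x, x@haplotypes))
#' @rdname accessors
#' @export
setMethod("markerInfo", "GenotypeMatrix",
          function(x) .markerInfoFrame(x, x@genotypes))

#' @rdname accessors
#' @export
setGeneric("qtlMarkers", function(x) standardGeneric("qtlMarkers"))
#' @rdname accessors
#' @export
setMethod("qtlMarkers", "HaplotypePanel",
          function(x) colnames(x@haplotypes)[x@qtl])
#' @rdname accessors
#' @export
setMethod("qtlMarkers", "GenotypeMatrix",
          function(x) colnames(x@genotypes)[x@qtl])

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname accessors
#' @export
setMethod("nMarkers", "HaplotypePanel", function(x) ncol(x@haplotypes))
#' @rdname accessors
#' @export
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@genotypes))

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setMethod("nIndividuals", "HaplotypePanel", function(x) nrow(x@haplotypes) %/% 2L)
#' @rdname accessors
#' @export
setMethod("nIndividuals", "GenotypeMatrix", function(x) nrow(x@genotypes))

#' @rdname accessors
#' @export
setGeneric("reducedSet", function(x) standardGeneric("reducedSet"))
#' @rdname accessors
#' @export
setMethod("reducedSet", "SelectionResult", function(x) x@reducedSet)

#' @rdname accessors
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))
#' @rdname accessors
#' @export
setMethod("bestModel", "SelectionResult", function(x) x@bestModel)

#' @rdname accessors
#' @export
setGeneric("bestBIC", function(x) standardGeneric("bestBIC"))
#' @rdname accessors
#' @export
setMethod("bestBIC", "SelectionResult", function(x) x@bestBIC)

## show methods -------------------------------------------------------------

setMethod("show", "GenotypeMeansTable", function(object) {
  cat(sprintf("GenotypeMeansTable (pattern %s, range %.4g)\n",
              object@pattern, object@rangeTarget))
  print(round(object@theta, 4))
})

setMethod("show", "FactorEffects", function(object) {
  cat(sprintf("FactorEffects: mu = %.4g\n", object@mu))
  cat("alpha:", signif(object@alpha, 4), "\n")
  cat("beta: ", signif(object@beta, 4), "\n")
  cat("gamma:\n")
  print(round(object@gamma, 4))
})

setMethod("show", "EssTable", function(object) {
  cat("Expected sums of squares (balanced cell-means model)\n")
  df <- data.frame(source = c("A", "B", "Epistasis"),
                   df = c(object@dfA, object@dfB, object@dfEpistasis),
                   ESS = c(object@essA, object@essB, object@essEpistasis))
  print(df, row.names = FALSE)
  cat(sprintf("total ESS: %.6g\n", object@totalEss))
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d haplotypes (%d diploids) x %d markers on %d chromosome(s); %d QTL\n",
              nrow(object@haplotypes), nrow(object@haplotypes) %/% 2L,
              ncol(object@haplotypes), length(unique(object@chrom)),
              sum(object@qtl)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d markers on %d chromosome(s); %d QTL\n",
              nrow(object@genotypes), ncol(object@genotypes),
              length(unique(object@chrom)), sum(object@qtl)))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit [%s]: g = %d classes, F(%d, %d) = %.4g, p = %.3g, r2 = %.4g, BIC = %.4g\n",
              paste(object@markers, collapse = ";"), object@nClasses,
              object@dfModel, object@dfError, object@fStat, object@pValue,
              object@r2, object@bic))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d markers after step 1; best model {%s} (BIC %.4g)\n",
              length(object@reducedSet),
              paste(object@bestModel, collapse = ", "), object@bestBIC))
})
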