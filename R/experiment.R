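## Replicated experiment runner and metrics: detection power of the true
## two-QTL model, type-I error of the exhaustive scan on null markers,
## selection accuracy, loci-count distributions and false discovery rate.

#' Experiment configuration
#'
#' The factorial study design: sample size x minor-allele-frequency window x
#' genetic model, with a fixed number of replicates per setting. Within a
#' replicate index the genealogy seed is shared across settings (genealogies
#' held constant; only mutations, frequencies and models vary), the
#' variance-reduction device of the design.
#'
#' @param sampleSizes diploid sample sizes (default 100, 500, 1000).
#' @param mafWindows named list of \code{c(low, high)} QTL frequency
#'   windows (default \code{low = c(0.01, 0.10)}, \code{high = c(0.20,
#'   0.30)}).
#' @param patterns genetic model codes (default \code{"a"}-\code{"f"}).
#' @param nReplicates replicates per setting (default 50).
#' @param alphaLevel test size for power estimation (default 0.05).
#' @param errorSd residual SD (default 1).
#' @param rangeTarget phenotypic range of the means (default 1.6).
#' @param baseSeed integer from which all replicate seeds derive.
#' @param nChromosomes,markersPerChromosome,rhoAdjacent genome settings
#'   passed to [simConfig()].
#' @return a list of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(sampleSizes = c(100L, 500L, 1000L),
                             mafWindows = list(low = c(0.01, 0.10),
                                               high = c(0.20, 0.30)),
                             patterns = c("a", "b", "c", "d", "e", "f"),
                             nReplicates = 50L, alphaLevel = 0.05,
                             errorSd = 1, rangeTarget = 1.6, baseSeed = 1L,
                             nChromosomes = 5L, markersPerChromosome = 100L,
                             rhoAdjacent = 1) {
  stopifnot(nReplicates >= 1, alphaLevel > 0, alphaLevel < 1)
  structure(list(sampleSizes = as.integer(sampleSizes),
                 mafWindows = mafWindows, patterns = patterns,
                 nReplicates = as.integer(nReplicates),
                 alphaLevel = alphaLevel, errorSd = errorSd,
                 rangeTarget = rangeTarget, baseSeed = as.integer(baseSeed),
                 nChromosomes = as.integer(nChromosomes),
                 markersPerChromosome = as.integer(markersPerChromosome),
                 rhoAdjacent = rhoAdjacent),
            class = "ExperimentConfig")
}

# deterministic sub-seeds: genealogy seed depends only on (baseSeed,
# replicate); mutation/phenotype seeds also on the setting
.replicateSeeds <- function(baseSeed, repIndex, settingKey) {
  h <- sum(utf8ToInt(settingKey)) %% 99991L
  mod <- .Machine$integer.max - 1L
  list(genealogy = as.integer((as.double(baseSeed) * 2971 + 7919 * repIndex) %% mod) + 1L,
       mutation = as.integer((as.double(baseSeed) * 4297 + 104729 * repIndex +
                                131 * h) %% mod) + 1L,
       phenotype = as.integer((as.double(baseSeed) * 6113 + 15485863 * repIndex +
                                 257 * h) %% mod) + 1L)
}

#' Run one replicate of one experimental setting
#'
#' Simulates a genome sample with the two conditioned QTL markers, generates
#' the phenotype under the requested genetic model, fits the true two-QTL
#' full model, and (optionally) runs the two-step selection scan.
#'
#' @param n diploid sample size.
#' @param pattern genetic model code \code{"a"}-\code{"f"}.
#' @param mafWindow \code{c(low, high)} QTL frequency window.
#' @param repIndex replicate index (1-based); together with \code{baseSeed}
#'   it determines all seeds. The genealogy seed does not depend on the
#'   setting, so genealogies are shared across settings within a replicate.
#' @param baseSeed integer base seed.
#' @param scan run the two-step selection scan (default TRUE; power-only
#'   studies can skip it).
#' @param searchSpace passed to [step2Select()].
#' @param errorSd,rangeTarget trait parameters.
#' @param nChromosomes,markersPerChromosome,rhoAdjacent genome settings.
#' @param qtlPositions QTL placement passed to [simConfig()]; the default
#'   puts one QTL mid-chromosome on each of chromosomes 1 and 2 (marker 50
#'   under the default 100-marker chromosomes).
#' @return list of class \code{"ReplicateRecord"}: setting descriptors, the
#'   true-model [ModelFit-class] (\code{trueFit}), \code{pValue} and
#'   \code{r2} shortcuts, the [SelectionResult-class] (\code{selection}, or
#'   NULL), \code{trueQtl} and \code{bestModel} marker ids, and
#'   \code{resampleCounts}.
#' @export
runReplicate <- function(n, pattern, mafWindow, repIndex, baseSeed = 1L,
                         scan = TRUE, searchSpace = "full", errorSd = 1,
                         rangeTarget = 1.6, nChromosomes = 5L,
                         markersPerChromosome = 100L, rhoAdjacent = 1,
                         qtlPositions = NULL) {
  key <- paste(pattern, n, mafWindow[1], mafWindow[2], sep = "|")
  seeds <- .replicateSeeds(baseSeed, repIndex, key)
  if (is.null(qtlPositions)) {
    mid <- as.integer((markersPerChromosome + 1L) %/% 2L)
    qtlPositions <- list(c(1L, mid), c(2L, mid))
  }
  cfg <- simConfig(n, nChromosomes = nChromosomes,
                   markersPerChromosome = markersPerChromosome,
                   rhoAdjacent = rhoAdjacent, mafWindow = mafWindow,
                   qtlPositions = qtlPositions,
                   genealogySeed = seeds$genealogy,
                   mutationSeed = seeds$mutation)
  sim <- simulatePanel(cfg)
  qtl <- qtlMarkers(sim$genotypes)
  tab <- makePatternTable(pattern, rangeTarget)
  pcfg <- phenotypeConfig(tab, qtl[1], qtl[2], errorSd = errorSd,
                          seed = seeds$phenotype)
  y <- generatePhenotypes(sim$genotypes, pcfg)
  trueFit <- fitFullModel(sim$genotypes, y, markers = qtl)
  selection <- if (scan)
    selectModel(sim$panel, sim$genotypes, y, searchSpace = searchSpace)
  else NULL
  structure(list(n = n, pattern = pattern, mafWindow = mafWindow,
                 repIndex = repIndex, trueFit = trueFit,
                 pValue = trueFit@pValue, r2 = trueFit@r2,
                 selection = selection, trueQtl = qtl,
                 bestModel = if (scan) bestModel(selection) else NULL,
                 resampleCounts = sim$resampleCounts),
            class = "ReplicateRecord")
}

#' Detection power over replicates
#'
#' Proportion of replicates in which the true-model F test has a p-value
#' below \code{alphaLevel}.
#'
#' @param records list of replicate records (anything with a \code{pValue}
#'   element).
#' @param alphaLevel test size (default 0.05).
#' @return proportion in \[0, 1\].
#' @export
estimatePower <- function(records, alphaLevel = 0.05) {
  stopifnot(length(records) >= 1)
  p <- vapply(records, function(r) r$pValue, numeric(1))
  mean(p < alphaLevel)
}

#' Model-selection performance metrics over replicates
#'
#' Computes, over a list of replicate records carrying \code{bestModel} and
#' \code{trueQtl} marker ids: \code{accuracy}, the proportion of replicates
#' whose selected model is *exactly* the true QTL pair (no over- or
#' under-fitting); the distribution of the number of selected loci (0-3);
#' the distribution of the number of correctly selected QTL (0-2); and the
#' false discovery rate, the mean over replicates of the proportion of
#' selected loci that are not true QTL (replicates selecting no loci
#' contribute 0; their count is reported). Only exact QTL-marker hits count
#' as correct -- a linked neighbour is a false discovery -- so these are
#' lower bounds on detection performance.
#'
#' @param records list of replicate records.
#' @return list with \code{accuracy}, \code{lociCountDist} (named
#'   proportions over "0".."3"), \code{correctCountDist} (over "0".."2"),
#'   \code{fdr}, \code{meanR2} (NA when records carry no r2) and
#'   \code{nZeroSelected}.
#' @export
selectionMetrics <- function(records) {
  stopifnot(length(records) >= 1)
  nSel <- vapply(records, function(r) length(r$bestModel), integer(1))
  nCor <- vapply(records, function(r)
    length(intersect(r$bestModel, r$trueQtl)), integer(1))
  exact <- vapply(records, function(r)
    setequal(r$bestModel, r$trueQtl) && length(r$bestModel) ==
      length(r$trueQtl), logical(1))
  fdrRep <- ifelse(nSel > 0, (nSel - nCor) / nSel, 0)
  r2s <- vapply(records, function(r)
    if (is.null(r$r2)) NA_real_ else r$r2, numeric(1))
  list(accuracy = mean(exact),
       lociCountDist = prop.table(table(factor(nSel, levels = 0:3))),
       correctCountDist = prop.table(table(factor(nCor, levels = 0:2))),
       fdr = mean(fdrRep),
       meanR2 = if (all(is.na(r2s))) NA_real_ else mean(r2s, na.rm = TRUE),
       nZeroSelected = sum(nSel == 0))
}

#' Type-I error of the exhaustive scan on null markers
#'
#' Selects ten evenly spaced markers on each chromosome that carries no QTL
#' (indices \code{round(1 + k*(m-1)/9)}, k = 0..9), fits every 1-, 2- and
#' 3-marker full model constructible from them (4525 models for 30 markers),
#' and returns the proportion of models whose overall F test has p <
#' \code{alphaLevel}. With the trait generated on other chromosomes these
#' markers are independent of the phenotype, so the proportion estimates the
#' per-model type-I error. Monomorphic picks are replaced by the nearest
#' fittable marker on the same chromosome.
#'
#' @param genotypes a [GenotypeMatrix-class] with QTL flags.
#' @param phenotype numeric trait vector.
#' @param alphaLevel test size (default 0.05).
#' @param markersPerChromosome markers drawn per null chromosome (default
#'   10).
#' @return proportion of rejecting models, with attributes \code{nModels}
#'   and \code{markers}.
#' @export
type1Scan <- function(genotypes, phenotype, alphaLevel = 0.05,
                      markersPerChromosome = 10L) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  gmat <- slot(genotypes, "genotypes")
  n <- nrow(gmat)
  info <- markerInfo(genotypes)
  qtlChrom <- unique(info$chrom[info$qtl])
  nullChrom <- setdiff(unique(info$chrom), qtlChrom)
  if (length(nullChrom) == 0L) stop("no chromosome without a QTL")

  pick <- unlist(lapply(nullChrom, function(cc) {
    idx <- which(info$chrom == cc)
    idx <- idx[order(info$pos[idx])]
    m <- length(idx)
    sel <- idx[unique(round(1 + (seq_len(markersPerChromosome) - 1) *
                              (m - 1) / (markersPerChromosome - 1)))]
    # nearest fittable neighbour for monomorphic picks
    vapply(sel, function(j) {
      if (length(unique(gmat[, j])) >= 2L) return(j)
      others <- idx[order(abs(idx - j))]
      fit <- others[vapply(others, function(o)
        length(unique(gmat[, o])) >= 2L, logical(1))]
      if (length(fit) == 0L) stop("chromosome has no polymorphic marker")
      fit[1]
    }, integer(1))
  }))
  ids <- colnames(gmat)[pick]

  models <- list()
  for (k in 1:3) models <- c(models, utils::combn(ids, k, simplify = FALSE))
  pvals <- vapply(models, function(mm) {
    sub <- gmat[, mm, drop = FALSE]
    cls <- .classIds(sub)
    fit <- .fastFit(phenotype, cls)
    g <- fit$g
    if (g < 2L || n <= g) return(NA_real_)
    if (fit$rss <= 0) return(0)
    f <- ((fit$tss - fit$rss) / (g - 1)) / (fit$rss / (n - g))
    pf(f, g - 1, n - g, lower.tail = FALSE)
  }, numeric(1))
  ok <- !is.na(pvals)
  out <- mean(pvals[ok] < alphaLevel)
  attr(out, "nModels") <- sum(ok)
  attr(out, "markers") <- ids
  out
}

#' Replicated type-I error experiment on null markers
#'
#' Repeats the null-marker scan of [type1Scan()] over independent simulated
#' replicates of the default design: a genome simulated by [simulatePanel()]
#' with two frequency-conditioned QTL, a trait generated at those QTL, and
#' the exhaustive 1-/2-/3-marker scan restricted to the chromosomes carrying
#' no QTL (30 markers, 4525 models, under the default genome). The returned
#' per-replicate rejection proportions estimate the per-model type-I error.
#'
#' @param nReplicates number of simulated replicates (>= 10 recommended).
#' @param baseSeed integer from which all replicate seeds derive.
#' @param n diploid sample size (default 100).
#' @param pattern genetic model generating the trait (default \code{"a"};
#'   the scanned markers are unlinked to the trait, so any pattern gives a
#'   null scan).
#' @param mafWindow QTL frequency window (default the high window).
#' @param alphaLevel test size (default 0.05).
#' @param ... further genome settings passed to [simConfig()].
#' @return numeric vector of per-replicate rejection proportions, with a
#'   \code{"nModels"} attribute (models fitted per replicate).
#' @export
type1Experiment <- function(nReplicates, baseSeed = 1L, n = 100L,
                            pattern = "a", mafWindow = c(0.20, 0.30),
                            alphaLevel = 0.05, ...) {
  stopifnot(nReplicates >= 1)
  mod <- .Machine$integer.max - 1L
  sub <- function(k) as.integer((as.double(baseSeed) + k) %% mod) + 1L
  tab <- makePatternTable(pattern)
  nModels <- NA_integer_
  props <- vapply(seq_len(nReplicates), function(i) {
    cfg <- simConfig(n, mafWindow = mafWindow,
                     genealogySeed = sub(7919 * i),
                     mutationSeed = sub(104729 * i), ...)
    sim <- simulatePanel(cfg)
    qtl <- qtlMarkers(sim$genotypes)
    y <- generatePhenotypes(sim$genotypes,
                            phenotypeConfig(tab, qtl[1], qtl[2],
                                            seed = sub(15485863 * i)))
    out <- type1Scan(sim$genotypes, y, alphaLevel = alphaLevel)
    nModels <<- attr(out, "nModels")
    as.numeric(out)
  }, numeric(1))
  attr(props, "nModels") <- nModels
  props
}

#' Run the full factorial experiment
#'
#' Loops over sample sizes x frequency windows x genetic models, runs
#' \code{nReplicates} replicates of each setting via [runReplicate()], and
#' summarises power ([estimatePower()]) and selection performance
#' ([selectionMetrics()]) per setting.
#'
#' @param config an [experimentConfig()] object.
#' @param scan run the selection scan in each replicate (default TRUE).
#' @param verbose print a line per setting.
#' @return list with \code{summary} (one data.frame row per setting) and
#'   \code{records} (nested list of replicate records).
#' @export
runExperiment <- function(config, scan = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "ExperimentConfig"))
  grid <- expand.grid(n = config$sampleSizes,
                      window = names(config$mafWindows),
                      pattern = config$patterns,
                      stringsAsFactors = FALSE)
  records <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; pat <- grid$pattern[i]
    win <- config$mafWindows[[grid$window[i]]]
    recs <- lapply(seq_len(config$nReplicates), function(r)
      runReplicate(n, pat, win, r, baseSeed = config$baseSeed, scan = scan,
                   errorSd = config$errorSd,
                   rangeTarget = config$rangeTarget,
                   nChromosomes = config$nChromosomes,
                   markersPerChromosome = config$markersPerChromosome,
                   rhoAdjacent = config$rhoAdjacent))
    pw <- estimatePower(recs, config$alphaLevel)
    sm <- if (scan) selectionMetrics(recs) else NULL
    rows[[i]] <- data.frame(
      n = n, window = grid$window[i], pattern = pat, power = pw,
      meanR2 = mean(vapply(recs, `[[`, numeric(1), "r2")),
      accuracy = if (scan) sm$accuracy else NA_real_,
      fdr = if (scan) sm$fdr else NA_real_,
      stringsAsFactors = FALSE)
    records[[i]] <- recs
    if (verbose)
      message(sprintf("n=%d %s pattern %s: power %.2f", n,
                      grid$window[i], pat, pw))
  }
  list(summary = do.call(rbind, rows), records = records)
}
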