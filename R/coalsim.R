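## Coalescent-with-recombination simulation of SNP haplotype panels at
## fixed marker positions, with minor-allele-frequency-conditioned mutation
## placement at designated QTL markers.

#' Simulation configuration
#'
#' Describes one simulated genome sample: a set of independent linkage
#' groups ("chromosomes") of biallelic SNP markers at fixed recombination
#' distances, with two designated trait loci on distinct chromosomes. Each
#' marker receives exactly one mutation on its marginal genealogy (so every
#' column is a SNP); the QTL markers are conditioned to a minor-allele
#' frequency window.
#'
#' @param nIndividuals number of diploid individuals (2n haplotypes).
#' @param nChromosomes number of independent linkage groups (default 5).
#' @param markersPerChromosome SNP markers per linkage group (default 100).
#' @param rhoAdjacent population recombination rate 2Nr between adjacent
#'   markers (default 1).
#' @param qtlPositions list of \code{c(chromosome, marker)} integer pairs
#'   (1-based within chromosome) designating the trait loci; they must lie
#'   on distinct chromosomes so the QTLs are unlinked. Default: marker 50 on
#'   chromosome 1 and marker 50 on chromosome 2 (global positions 50 and
#'   150 when chromosomes are concatenated).
#' @param mafWindow length-2 numeric, inclusive minor-allele-frequency
#'   bounds for the QTL markers; default the "high" window \code{c(0.20,
#'   0.30)} (the "low" window of the study design is \code{c(0.01, 0.10)}).
#' @param genealogySeed,mutationSeed integer seeds. Holding
#'   \code{genealogySeed} fixed while varying \code{mutationSeed} keeps the
#'   underlying genealogies constant across settings, the variance-reduction
#'   device of the study design.
#' @param maxResample bound on genealogy regenerations per chromosome when
#'   no branch satisfies the QTL frequency window (default 100).
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nIndividuals, nChromosomes = 5L,
                      markersPerChromosome = 100L, rhoAdjacent = 1,
                      qtlPositions = list(c(1L, 50L), c(2L, 50L)),
                      mafWindow = c(0.20, 0.30),
                      genealogySeed = 1L, mutationSeed = 2L,
                      maxResample = 100L) {
  stopifnot(nIndividuals >= 2, nChromosomes >= 1, markersPerChromosome >= 1,
            rhoAdjacent >= 0, length(mafWindow) == 2L,
            mafWindow[1] > 0, mafWindow[1] < mafWindow[2], mafWindow[2] <= 0.5,
            maxResample >= 1)
  qtl <- lapply(qtlPositions, function(p) {
    stopifnot(length(p) == 2L, p[1] >= 1, p[1] <= nChromosomes,
              p[2] >= 1, p[2] <= markersPerChromosome)
    as.integer(p)
  })
  chroms <- vapply(qtl, `[`, integer(1), 1L)
  if (anyDuplicated(chroms))
    stop("QTL positions must lie on distinct chromosomes (unlinked QTLs)")
  structure(list(nIndividuals = as.integer(nIndividuals),
                 nChromosomes = as.integer(nChromosomes),
                 markersPerChromosome = as.integer(markersPerChromosome),
                 rhoAdjacent = rhoAdjacent, qtlPositions = qtl,
                 mafWindow = as.numeric(mafWindow),
                 genealogySeed = as.integer(genealogySeed),
                 mutationSeed = as.integer(mutationSeed),
                 maxResample = as.integer(maxResample)),
            class = "SimConfig")
}

.subSeed <- function(seed, chrom, attempt = 0L) {
  as.integer((as.double(seed) + 1000003 * chrom + 7919 * attempt) %%
               (.Machine$integer.max - 1L)) + 1L
}

.simChromosome <- function(nh, L, rho) {
  g <- .simulate_arg_cpp(nh, L, rho)
  class(g) <- "Genealogy"
  g
}

#' Simulate per-chromosome genealogies
#'
#' Runs the ancestral recombination process over the 2n sampled haplotypes
#' for each chromosome independently: lineages coalesce at the standard rate
#' and recombine between adjacent markers at rate \code{rhoAdjacent} per
#' interval (multiple recombinations per interval allowed), until every
#' marker has reached its grand most recent common ancestor. Time is in
#' coalescent units (pairwise coalescence rate 1).
#'
#' @param config a [simConfig()] object. The genealogy seed is applied here.
#' @return list with one \code{"Genealogy"} per chromosome; each holds a
#'   \code{parent} matrix and node-\code{time} matrix with one column per
#'   marker (the marker's marginal tree: 2n leaves at time 0, 2n - 1
#'   internal nodes, root parent -1).
#' @export
simulateGenealogies <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  nh <- 2L * config$nIndividuals
  set.seed(config$genealogySeed)
  lapply(seq_len(config$nChromosomes), function(chrom)
    .simChromosome(nh, config$markersPerChromosome, config$rhoAdjacent))
}

#' Place one neutral mutation per marker on its marginal tree
#'
#' For every (non-conditioned) marker of one chromosome, drops a single
#' mutation on a branch of that marker's marginal tree, chosen with
#' probability proportional to branch length; all leaves below the branch
#' carry the derived allele 1. This yields the neutral site-frequency
#' spectrum (derived-count probability proportional to 1/k) and guarantees
#' every column is polymorphic.
#'
#' @param genealogy one chromosome's \code{"Genealogy"} from
#'   [simulateGenealogies()].
#' @param markers marker indices to mutate (default all).
#' @return integer 0/1 matrix, haplotypes x markers.
#' @export
placeMutations <- function(genealogy, markers = NULL) {
  stopifnot(inherits(genealogy, "Genealogy"))
  nh <- genealogy$n_leaves
  L <- ncol(genealogy$parent)
  if (is.null(markers)) markers <- seq_len(L)
  out <- matrix(0L, nh, length(markers))
  for (k in seq_along(markers)) {
    m <- markers[k]
    out[, k] <- .place_mutation_cpp(genealogy$parent[, m],
                                    genealogy$time[, m], nh, 0, 0.5)
  }
  out
}

#' Place a frequency-conditioned mutation at one marker
#'
#' Samples among the branches of the marker's marginal tree whose descendant
#' clade gives a minor-allele frequency inside \code{mafWindow}, with
#' probability proportional to branch length (restrict-then-sample). When no
#' branch is eligible the condition \code{"epiqtl_resample"} is signalled,
#' telling the caller to regenerate the chromosome's genealogy.
#'
#' @inheritParams placeMutations
#' @param marker marker index on the chromosome.
#' @param mafWindow inclusive \code{c(low, high)} frequency bounds.
#' @return integer 0/1 haplotype column.
#' @export
placeConditionedMutation <- function(genealogy, marker, mafWindow) {
  stopifnot(inherits(genealogy, "Genealogy"), length(mafWindow) == 2L)
  nh <- genealogy$n_leaves
  col <- .place_mutation_cpp(genealogy$parent[, marker],
                             genealogy$time[, marker], nh,
                             mafWindow[1], mafWindow[2])
  if (length(col) == 0L) {
    cond <- structure(
      class = c("epiqtl_resample", "error", "condition"),
      list(message = sprintf(
             "no branch with minor-allele frequency in [%g, %g]",
             mafWindow[1], mafWindow[2]),
           call = sys.call(-1)))
    stop(cond)
  }
  col
}

#' Assemble diploid genotypes from a haplotype panel
#'
#' Haplotypes 2k-1 and 2k form individual k; each genotype entry is the sum
#' of the two constituent haplotype alleles (0/1/2 derived-allele dosage).
#'
#' @param panel a [HaplotypePanel-class].
#' @return A [GenotypeMatrix-class] sharing the panel's marker map.
#' @export
assembleDiploids <- function(panel) {
  stopifnot(is(panel, "HaplotypePanel"))
  h <- haplotypes(panel)
  if (nrow(h) %% 2L != 0L) stop("odd number of haplotypes")
  odd <- seq(1L, nrow(h), by = 2L)
  g <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  storage.mode(g) <- "integer"
  rownames(g) <- paste0("ind_", seq_len(nrow(g)))
  new("GenotypeMatrix", genotypes = g, chrom = panel@chrom, pos = panel@pos,
      qtl = panel@qtl)
}

#' Simulate a complete SNP panel with conditioned QTL markers
#'
#' End-to-end generator: simulates the per-chromosome genealogies (genealogy
#' seed), then superimposes one mutation per marker (mutation seed), using
#' frequency-conditioned placement at the designated QTL markers. If a QTL
#' marker's marginal tree has no branch inside the frequency window, that
#' chromosome's genealogy is regenerated with a fresh sub-seed (up to
#' \code{maxResample} times, counts reported).
#'
#' @param config a [simConfig()] object.
#' @return list with elements \code{panel} (a [HaplotypePanel-class]),
#'   \code{genotypes} (a [GenotypeMatrix-class]) and \code{resampleCounts}
#'   (integer genealogy regenerations per chromosome).
#' @examples
#' \donttest{
#' sim <- simulatePanel(simConfig(100, genealogySeed = 1, mutationSeed = 2))
#' sim$genotypes
#' qtlMarkers(sim$genotypes)
#' }
#' @export
simulatePanel <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  nh <- 2L * config$nIndividuals
  L <- config$markersPerChromosome
  nChrom <- config$nChromosomes
  genealogies <- simulateGenealogies(config)

  qtlChrom <- vapply(config$qtlPositions, `[`, integer(1), 1L)
  qtlMarker <- vapply(config$qtlPositions, `[`, integer(1), 2L)
  resampleCounts <- integer(nChrom)
  cols <- vector("list", nChrom)

  set.seed(config$mutationSeed)
  for (chrom in seq_len(nChrom)) {
    qidx <- qtlMarker[match(chrom, qtlChrom)]  # NA when no QTL here
    attempt <- 0L
    repeat {
      res <- tryCatch({
        mat <- matrix(0L, nh, L)
        if (!is.na(qidx))
          mat[, qidx] <- placeConditionedMutation(genealogies[[chrom]],
                                                  qidx, config$mafWindow)
        rest <- setdiff(seq_len(L), qidx)
        mat[, rest] <- placeMutations(genealogies[[chrom]], rest)
        mat
      }, epiqtl_resample = function(e) NULL)
      if (!is.null(res)) break
      attempt <- attempt + 1L
      if (attempt > config$maxResample)
        stop(sprintf("chromosome %d: no eligible QTL branch after %d genealogy resamples",
                     chrom, config$maxResample))
      set.seed(.subSeed(config$genealogySeed, chrom, attempt))
      genealogies[[chrom]] <- .simChromosome(nh, L, config$rhoAdjacent)
      set.seed(.subSeed(config$mutationSeed, chrom, attempt))
    }
    resampleCounts[chrom] <- attempt
    cols[[chrom]] <- res
  }

  hap <- do.call(cbind, cols)
  chromMap <- rep(seq_len(nChrom), each = L)
  posMap <- rep(seq_len(L), nChrom)
  qtlFlag <- rep(FALSE, nChrom * L)
  qtlFlag[(qtlChrom - 1L) * L + qtlMarker] <- TRUE
  colnames(hap) <- paste0("chr", chromMap, "_", posMap)
  rownames(hap) <- paste0("hap_", seq_len(nh))

  panel <- new("HaplotypePanel", haplotypes = hap,
               chrom = as.integer(chromMap), pos = as.integer(posMap),
               qtl = qtlFlag)
  list(panel = panel, genotypes = assembleDiploids(panel),
       resampleCounts = resampleCounts)
}
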