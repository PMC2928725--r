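## Two-step BIC model selection: parse chromosomes into phylogenetically
## compatible blocks (four-gamete test), reduce markers block-wise, then
## exhaustively score all 1-/2-/3-marker full models.

#' Four-gamete compatibility of two haplotype columns
#'
#' Under infinite-sites mutation, two biallelic markers descending from a
#' single genealogy cannot show all four gametic types 00, 01, 10, 11;
#' observing all four proves a recombination event between them. Returns
#' \code{TRUE} when at most three gametic types are present.
#'
#' @param colX,colY 0/1 haplotype vectors over the same haplotypes.
#' @return logical.
#' @export
fourGameteCompatible <- function(colX, colY) {
  stopifnot(length(colX) == length(colY))
  x <- colX == 1L
  y <- colY == 1L
  (any(x & y) + any(x & !y) + any(!x & y) + any(!x & !y)) <= 3L
}

#' Parse a chromosome into phylogenetically compatible blocks
#'
#' Greedy left-to-right partition: the current block is extended while the
#' incoming marker passes the four-gamete test against *every* marker
#' already in the block (so a single genealogy without recombination could
#' explain the whole block); otherwise a new block starts. Blocks tile the
#' chromosome. With no recombination every chromosome is one block.
#'
#' @param panel a [HaplotypePanel-class].
#' @param chromosome chromosome id to parse; \code{NULL} (default) parses
#'   all chromosomes.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive marker positions), \code{nMarkers} and a list column
#'   \code{markers} of member marker ids.
#' @export
parseBlocks <- function(panel, chromosome = NULL) {
  stopifnot(is(panel, "HaplotypePanel"))
  h <- haplotypes(panel)
  chroms <- if (is.null(chromosome)) sort(unique(panel@chrom))
            else as.integer(chromosome)

  res <- lapply(chroms, function(cc) {
    idx <- which(panel@chrom == cc)
    idx <- idx[order(panel@pos[idx])]
    starts <- integer(0)
    ends <- integer(0)
    bstart <- 1L
    for (k in seq_along(idx)[-1]) {
      newcol <- h[, idx[k]]
      ok <- TRUE
      for (m in bstart:(k - 1L)) {
        if (!fourGameteCompatible(h[, idx[m]], newcol)) { ok <- FALSE; break }
      }
      if (!ok) {
        starts <- c(starts, bstart); ends <- c(ends, k - 1L)
        bstart <- k
      }
    }
    starts <- c(starts, bstart); ends <- c(ends, length(idx))
    data.frame(chrom = cc, start = panel@pos[idx[starts]],
               end = panel@pos[idx[ends]], nMarkers = ends - starts + 1L,
               markers = I(mapply(function(s, e) colnames(h)[idx[s:e]],
                                  starts, ends, SIMPLIFY = FALSE)))
  })
  do.call(rbind, res)
}

# screen markers that admit a full-model fit: >= 2 observed genotype
# classes and at least 1 error df for the single-marker model
.fittableMarkers <- function(gmat, markers) {
  n <- nrow(gmat)
  keep <- vapply(markers, function(m) {
    g <- length(unique(gmat[, m]))
    g >= 2L && n > g
  }, logical(1))
  markers[keep]
}

# BIC of the full model for a marker subset; +Inf when unfittable
.candidateBic <- function(gmat, y, markers, n, searchSpace = "full") {
  sub <- gmat[, markers, drop = FALSE]
  if (searchSpace == "full") {
    cls <- .classIds(sub)
    fit <- .fastFit(y, cls)
    if (fit$g < 2L || n <= fit$g) return(Inf)
    if (fit$rss <= 0) return(-Inf)
    n * log(fit$rss / n) + (fit$g + 1) * log(n)
  } else {
    X <- cbind(1, sub)
    storage.mode(X) <- "double"
    fit <- stats::.lm.fit(X, y)
    p <- fit$rank
    if (n <= p) return(Inf)
    rss <- sum(fit$residuals^2)
    if (rss <= 0) return(-Inf)
    n * log(rss / n) + (p + 1) * log(n)
  }
}

#' Step 1: block-wise marker reduction
#'
#' Within every compatible block, all one- and two-marker full models among
#' the block's fittable markers are scored by BIC; the marker(s) of the
#' minimum-BIC model survive. The union over blocks is the reduced set. No
#' block is eliminated: this step only thins physically linked, correlated
#' markers to keep the step-2 exhaustive search tractable.
#'
#' @param panel a [HaplotypePanel-class] (blocks are parsed on haplotypes).
#' @param genotypes the matching [GenotypeMatrix-class].
#' @param phenotype numeric trait vector.
#' @return character vector of surviving marker ids, with a
#'   \code{"blockWinners"} attribute listing each block's winning model.
#' @export
step1Reduce <- function(panel, genotypes, phenotype) {
  stopifnot(is(panel, "HaplotypePanel"), is(genotypes, "GenotypeMatrix"))
  gmat <- slot(genotypes, "genotypes")
  n <- nrow(gmat)
  blocks <- parseBlocks(panel)

  winners <- vector("list", nrow(blocks))
  nCands <- integer(nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    mk <- .fittableMarkers(gmat, blocks$markers[[b]])
    if (length(mk) == 0L) { winners[[b]] <- character(0); next }
    cands <- c(as.list(mk),
               if (length(mk) >= 2L)
                 utils::combn(mk, 2L, simplify = FALSE))
    nCands[b] <- length(cands)
    bics <- vapply(cands, function(mm)
      .candidateBic(gmat, phenotype, mm, n), numeric(1))
    winners[[b]] <- cands[[which.min(bics)]]
  }
  reduced <- unique(unlist(winners))
  attr(reduced, "blockWinners") <- winners
  attr(reduced, "nCandidates") <- nCands
  reduced
}

#' Step 2: exhaustive 1-/2-/3-marker BIC search
#'
#' Scores the intercept-only model plus every subset of one to three markers
#' from the reduced set and returns the minimum-BIC model. With
#' \code{searchSpace = "full"} each candidate is the cell-means full model
#' (all interactions); with \code{"main_effects"} markers enter additively
#' as 0/1/2 dosages without interactions. Ties are broken toward fewer
#' markers, then lexicographic marker order.
#'
#' @param reduced character vector of marker ids from [step1Reduce()].
#' @param genotypes a [GenotypeMatrix-class] or bare 0/1/2 matrix with
#'   column names.
#' @param phenotype numeric trait vector.
#' @param searchSpace \code{"full"} (default) or \code{"main_effects"}.
#' @param auditMax cap on the number of candidate rows kept in the audit
#'   table (default 5000; the count of candidates is always recorded).
#' @return A [SelectionResult-class]. \code{bestModel} is empty when the
#'   intercept-only model wins.
#' @export
step2Select <- function(reduced, genotypes, phenotype,
                        searchSpace = c("full", "main_effects"),
                        auditMax = 5000L) {
  searchSpace <- match.arg(searchSpace)
  if (length(reduced) == 0L) stop("reduced marker set is empty")
  gmat <- if (is(genotypes, "GenotypeMatrix")) slot(genotypes, "genotypes")
          else genotypes
  n <- nrow(gmat)
  y <- phenotype
  reduced <- sort(unique(as.character(reduced)))

  cands <- list(character(0))  # the intercept-only (null) model first
  for (k in 1:min(3L, length(reduced)))
    cands <- c(cands, utils::combn(reduced, k, simplify = FALSE))

  tssBic <- {  # null model: one grand mean + error variance
    tss <- sum((y - mean(y))^2)
    if (tss <= 0) -Inf else n * log(tss / n) + 2 * log(n)
  }
  bics <- vapply(cands, function(mm) {
    if (length(mm) == 0L) tssBic
    else .candidateBic(gmat, y, mm, n, searchSpace)
  }, numeric(1))

  best <- which.min(bics)  # enumeration order encodes the tie-break
  audit <- list(searchSpace = searchSpace, nCandidates = length(cands))
  if (length(cands) <= auditMax)
    audit$candidates <- data.frame(
      model = vapply(cands, paste, character(1), collapse = ";"),
      size = lengths(cands), bic = bics, stringsAsFactors = FALSE)
  new("SelectionResult", reducedSet = reduced,
      bestModel = cands[[best]], bestBIC = bics[best], audit = audit)
}

#' Number of marker models in the exhaustive step-2 search
#'
#' \code{choose(r, 1) + choose(r, 2) + choose(r, 3)}: all one-, two- and
#' three-marker models constructible from r reduced markers (the null model
#' is scored in addition). For r = 30 this is 4525.
#'
#' @param r number of markers in the reduced set.
#' @return integer count.
#' @export
countCandidateModels <- function(r) {
  choose(r, 1) + choose(r, 2) + choose(r, 3)
}

#' Run the complete two-step selection scan
#'
#' Convenience wrapper: [step1Reduce()] then [step2Select()].
#'
#' @inheritParams step1Reduce
#' @inheritParams step2Select
#' @return A [SelectionResult-class] whose audit also carries the step-1
#'   block winners.
#' @export
selectModel <- function(panel, genotypes, phenotype,
                        searchSpace = c("full", "main_effects")) {
  searchSpace <- match.arg(searchSpace)
  reduced <- step1Reduce(panel, genotypes, phenotype)
  res <- step2Select(reduced, genotypes, phenotype, searchSpace)
  res@audit$blockWinners <- attr(reduced, "blockWinners")
  res
}
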