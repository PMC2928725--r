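test_that("the four-gamete test separates compatible from incompatible pairs", {
  expect_true(fourGameteCompatible(c(1, 1, 0, 0), c(1, 1, 1, 0)))
  expect_false(fourGameteCompatible(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  # identical and complementary columns are always compatible
  expect_true(fourGameteCompatible(c(0, 1, 0, 1), c(0, 1, 0, 1)))
  expect_true(fourGameteCompatible(c(0, 1, 0, 1), c(1, 0, 1, 0)))
  expect_error(fourGameteCompatible(c(0, 1), c(0, 1, 1)))
})

test_that("block parsing matches the hand-worked example", {
  # m1/m2 and m2/m3 are compatible but m1/m3 shows all four gametes, so the
  # greedy all-pairs rule closes the first block after m2
  h <- cbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 1L, 0L), c(1L, 0L, 1L, 0L))
  blocks <- parseBlocks(toyPanel(h))
  expect_identical(nrow(blocks), 2L)
  expect_identical(blocks$start, c(1L, 3L))
  expect_identical(blocks$end, c(2L, 3L))
  expect_identical(blocks$nMarkers, c(2L, 1L))
  expect_identical(blocks$markers[[1]], c("chr1_1", "chr1_2"))
  expect_identical(blocks$markers[[2]], "chr1_3")
  expect_true(blocksAreValid(toyPanel(h), blocks))
})

test_that("without recombination each chromosome parses into a single block", {
  sim <- simulatePanel(simConfig(40, nChromosomes = 2L,
                                 markersPerChromosome = 15L,
                                 rhoAdjacent = 0,
                                 qtlPositions = list(c(1L, 8L), c(2L, 8L)),
                                 genealogySeed = 51L, mutationSeed = 52L))
  blocks <- parseBlocks(sim$panel)
  expect_identical(nrow(blocks), 2L)
  expect_identical(blocks$nMarkers, c(15L, 15L))
})

test_that("parsed blocks are valid and their number grows with recombination", {
  nBlocks <- vapply(c(0, 1, 10), function(rho) {
    sim <- simulatePanel(simConfig(40, nChromosomes = 1L,
                                   markersPerChromosome = 20L,
                                   rhoAdjacent = rho,
                                   qtlPositions = list(c(1L, 10L)),
                                   genealogySeed = 61L, mutationSeed = 62L))
    blocks <- parseBlocks(sim$panel)
    expect_true(blocksAreValid(sim$panel, blocks))
    nrow(blocks)
  }, integer(1))
  expect_identical(nBlocks[1], 1L)
  expect_gt(nBlocks[2], 1L)
  expect_gte(nBlocks[3], nBlocks[2])
})

test_that("step 1 scores all one- and two-marker models per block and keeps the signal", {
  sim <- simulatePanel(simConfig(80, nChromosomes = 2L,
                                 markersPerChromosome = 12L,
                                 rhoAdjacent = 0,  # one block per chromosome
                                 qtlPositions = list(c(1L, 6L), c(2L, 6L)),
                                 genealogySeed = 71L, mutationSeed = 72L))
  qtl <- qtlMarkers(sim$genotypes)
  y <- generatePhenotypes(sim$genotypes,
                          phenotypeConfig(makePatternTable("a"), qtl[1],
                                          qtl[2], errorSd = 0.05,
                                          seed = 73L))
  reduced <- step1Reduce(sim$panel, sim$genotypes, y)
  expect_true(all(reduced %in% colnames(genotypes(sim$genotypes))))
  # per-block candidate counts: k fittable markers give k + choose(k, 2)
  blocks <- parseBlocks(sim$panel)
  gmat <- genotypes(sim$genotypes)
  for (b in seq_len(nrow(blocks))) {
    k <- length(epiqtl:::.fittableMarkers(gmat, blocks$markers[[b]]))
    expect_identical(attr(reduced, "nCandidates")[b],
                     as.integer(k + choose(k, 2)))
  }
  # with a near-noise-free additive trait, each block's winner carries a
  # marker highly correlated with its QTL
  winners <- attr(reduced, "blockWinners")
  for (b in 1:2) {
    r2 <- stats::cor(gmat[, winners[[b]]], gmat[, qtl[b]])^2
    expect_gt(max(r2), 0.8)
  }
  expect_lte(length(reduced), 4L)  # at most two markers per block
})

test_that("step 2 enumerates the advertised model count and honours the audit", {
  set.seed(81)
  g <- matrix(sample(0:2, 70 * 6, replace = TRUE), 70, 6,
              dimnames = list(NULL, paste0("m", 1:6)))
  y <- rnorm(70) + g[, 2]
  res <- step2Select(colnames(g), g, y)
  expect_identical(res@audit$nCandidates,
                   as.integer(1 + countCandidateModels(6)))
  expect_identical(nrow(res@audit$candidates), 42L)
  # the recorded best equals the audit's minimum
  expect_equal(res@bestBIC, min(res@audit$candidates$bic))
  expect_identical(paste(res@bestModel, collapse = ";"),
                   res@audit$candidates$model[
                     which.min(res@audit$candidates$bic)])
  expect_true("m2" %in% res@bestModel)
  expect_equal(countCandidateModels(30), 4525)
})

test_that("step 2 ties break toward fewer markers, then lexicographic order", {
  set.seed(91)
  col <- sample(0:2, 80, replace = TRUE)
  g <- cbind(a = col, b = col)  # duplicate columns: identical partitions
  y <- col + rnorm(80, sd = 0.5)
  res <- step2Select(c("b", "a"), g, y)
  # {a}, {b} and {a,b} all induce the same genotype classes, hence the same
  # BIC; the winner must be the single lexicographically first marker
  expect_identical(res@bestModel, "a")
  cand <- res@audit$candidates
  expect_equal(cand$bic[cand$model == "a"], cand$bic[cand$model == "b"])
  expect_equal(cand$bic[cand$model == "a"], cand$bic[cand$model == "a;b"])
})

test_that("step 2 is invariant to genotype column order", {
  set.seed(101)
  g <- matrix(sample(0:2, 90 * 5, replace = TRUE), 90, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  y <- g[, 1] - g[, 4] + rnorm(90, sd = 0.8)
  r1 <- step2Select(colnames(g), g, y)
  r2 <- step2Select(rev(colnames(g)), g[, 5:1], y)
  expect_identical(r1@bestModel, r2@bestModel)
  expect_equal(r1@bestBIC, r2@bestBIC)
})

test_that("the main-effects search space matches a least-squares oracle", {
  set.seed(111)
  g <- matrix(sample(0:2, 60 * 3, replace = TRUE), 60, 3,
              dimnames = list(NULL, c("x", "y", "z")))
  tr <- 0.7 * g[, 1] + rnorm(60)
  res <- step2Select(colnames(g), g, tr, searchSpace = "main_effects")
  cand <- res@audit$candidates
  for (model in c("x", "x;z", "x;y;z")) {
    mk <- strsplit(model, ";")[[1]]
    fit <- stats::lm(tr ~ g[, mk, drop = FALSE])
    rss <- sum(residuals(fit)^2)
    p <- length(coef(fit)) - sum(is.na(coef(fit)))
    expect_equal(cand$bic[cand$model == model],
                 60 * log(rss / 60) + (p + 1) * log(60))
  }
  expect_true("x" %in% res@bestModel)
})

test_that("on null phenotypes step 2 rarely selects any marker", {
  set.seed(121)
  sizes <- vapply(seq_len(30), function(i) {
    g <- matrix(sample(0:2, 100 * 5, replace = TRUE), 100, 5,
                dimnames = list(NULL, paste0("m", 1:5)))
    length(step2Select(colnames(g), g, rnorm(100))@bestModel)
  }, integer(1))
  expect_gte(sum(sizes == 0L), 25L)
  expect_true(all(sizes <= 1L))
})

test_that("the combined scan recovers a strong planted two-QTL signal", {
  sim <- simulatePanel(simConfig(120, nChromosomes = 3L,
                                 markersPerChromosome = 10L,
                                 rhoAdjacent = 5,
                                 qtlPositions = list(c(1L, 5L), c(2L, 5L)),
                                 genealogySeed = 131L, mutationSeed = 132L))
  qtl <- qtlMarkers(sim$genotypes)
  y <- generatePhenotypes(sim$genotypes,
                          phenotypeConfig(makePatternTable("a"), qtl[1],
                                          qtl[2], errorSd = 0.05,
                                          seed = 133L))
  res <- selectModel(sim$panel, sim$genotypes, y)
  expect_true(is(res, "SelectionResult"))
  expect_true(all(bestModel(res) %in% reducedSet(res)))
  # near-noise-free: every selected marker tags a QTL tightly
  gmat <- genotypes(sim$genotypes)
  for (m in bestModel(res))
    expect_gt(max(stats::cor(gmat[, m], gmat[, qtl])^2), 0.8)
  expect_gte(length(bestModel(res)), 2L)
})

test_that("degenerate inputs to the search are rejected", {
  expect_error(step2Select(character(0), matrix(0L, 4, 1), rnorm(4)),
               "empty")
})
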