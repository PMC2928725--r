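test_that("simConfig validates its arguments", {
  cfg <- simConfig(100)
  expect_s3_class(cfg, "SimConfig")
  expect_identical(cfg$nChromosomes, 5L)
  expect_identical(cfg$markersPerChromosome, 100L)
  expect_equal(cfg$mafWindow, c(0.20, 0.30))
  expect_error(simConfig(100, qtlPositions = list(c(1L, 10L), c(1L, 90L))),
               "distinct chromosomes")
  expect_error(simConfig(100, mafWindow = c(0.3, 0.2)))
  expect_error(simConfig(1))
})

test_that("with no recombination every marker shares one marginal tree", {
  g <- simulateGenealogies(simConfig(10, nChromosomes = 1L,
                                     markersPerChromosome = 25L,
                                     rhoAdjacent = 0,
                                     qtlPositions = list(c(1L, 12L)),
                                     genealogySeed = 101L))[[1]]
  expect_identical(ncol(g$parent), 25L)
  expect_true(all(g$parent == g$parent[, 1]))
  expect_true(all(g$time == g$time[, 1]))
  # tree shape sanity: 2n - 1 internal nodes, leaves at time 0, root last
  nh <- g$n_leaves
  expect_identical(nrow(g$parent), as.integer(2 * nh - 1))
  expect_true(all(g$time[seq_len(nh), 1] == 0))
  expect_identical(g$parent[2 * nh - 1, 1], -1L)
  expect_true(all(diff(g$time[(nh + 1):(2 * nh - 1), 1]) > 0))
})

test_that("recombination introduces distinct marginal trees, monotonically in rho", {
  nTrees <- vapply(c(0, 1, 10), function(rho) {
    g <- simulateGenealogies(simConfig(10, nChromosomes = 1L,
                                       markersPerChromosome = 20L,
                                       rhoAdjacent = rho,
                                       qtlPositions = list(c(1L, 10L)),
                                       genealogySeed = 202L))[[1]]
    keys <- apply(rbind(g$parent, round(g$time, 12)), 2, paste,
                  collapse = ",")
    length(unique(keys))
  }, integer(1))
  expect_identical(nTrees[1], 1L)
  expect_gt(nTrees[2], 1)
  expect_gte(nTrees[3], nTrees[2])
})

test_that("time to the most recent common ancestor matches the coalescent expectation", {
  nh <- 20L
  reps <- 500L
  set.seed(303)
  tm <- vapply(seq_len(reps), function(i) {
    g <- epiqtl:::.simChromosome(nh, 1L, 0)
    g$time[2L * nh - 1L, 1]
  }, numeric(1))
  expected <- 2 * (1 - 1 / nh)
  expect_lt(abs(mean(tm) - expected), 3 * stats::sd(tm) / sqrt(reps))
})

test_that("mutation placement on a fixed tree is branch-length proportional", {
  # caterpillar of 4 leaves: branch lengths by derived-allele count are
  # 1-leaf branches 1+1+2+3 = 7, 2-leaf branch 1, 3-leaf branch 1; total 9
  g <- caterpillarGenealogy()
  set.seed(404)
  reps <- 3000L
  counts <- vapply(seq_len(reps),
                   function(i) as.integer(sum(placeMutations(g))),
                   integer(1))
  tab <- tabulate(counts, 3L)
  chi <- stats::chisq.test(tab, p = c(7, 1, 1) / 9)
  expect_gt(chi$p.value, 0.001)
  # placement never produces a monomorphic column
  expect_true(all(counts >= 1L & counts <= 3L))
})

test_that("unconditioned mutations reproduce the one-mutation-per-marker frequency spectrum", {
  # oracle: pure-R Kingman Monte Carlo estimate of E[l_k / L]
  nh <- 10L
  set.seed(505)
  oracle <- kingmanSpectrum(nh, 800L)
  reps <- 400L
  counts <- integer(0)
  set.seed(606)
  for (i in seq_len(reps)) {
    g <- epiqtl:::.simChromosome(nh, 5L, 0)
    counts <- c(counts, colSums(placeMutations(g)))
  }
  observed <- tabulate(counts, nh - 1L) / length(counts)
  # total-variation distance against the independent oracle
  expect_lt(sum(abs(observed - oracle)) / 2, 0.05)
  # and the spectrum is decreasing in k, like the 1/k neutral shape
  expect_true(all(diff(observed[1:4]) < 0))
})

test_that("conditioned placement respects the frequency window on a fixed tree", {
  g <- caterpillarGenealogy()
  # window [0.2, 0.3]: the 1-leaf and 3-leaf branches (maf 0.25) qualify,
  # the 2-leaf branch (maf 0.5) does not
  set.seed(707)
  for (i in 1:25) {
    col <- placeConditionedMutation(g, 1L, c(0.2, 0.3))
    expect_true(sum(col) %in% c(1, 3))
  }
  # window [0.4, 0.5]: only the 2-leaf branch (maf 0.5) qualifies
  for (i in 1:25)
    expect_equal(sum(placeConditionedMutation(g, 1L, c(0.4, 0.5))), 2)
  # window (0.3, 0.4): no branch is eligible -> resample condition
  expect_error(placeConditionedMutation(g, 1L, c(0.31, 0.40)),
               class = "epiqtl_resample")
})

test_that("simulated panels are reproducible and place QTL frequencies inside the window", {
  cfg <- simConfig(100, nChromosomes = 3L, markersPerChromosome = 20L,
                   qtlPositions = list(c(1L, 10L), c(2L, 10L)),
                   genealogySeed = 11L, mutationSeed = 22L)
  s1 <- simulatePanel(cfg)
  s2 <- simulatePanel(cfg)
  expect_identical(haplotypes(s1$panel), haplotypes(s2$panel))
  expect_identical(genotypes(s1$genotypes), genotypes(s2$genotypes))

  h <- haplotypes(s1$panel)
  expect_identical(dim(h), c(200L, 60L))
  expect_true(all(h %in% 0:1))
  # every marker is a SNP
  mafs <- pmin(colMeans(h), 1 - colMeans(h))
  expect_true(all(mafs > 0))
  # QTL markers obey the high window; with 200 haplotypes that is 40..60
  qids <- qtlMarkers(s1$panel)
  expect_identical(length(qids), 2L)
  expect_true(all(mafs[qids] >= 0.20 & mafs[qids] <= 0.30))

  low <- simulatePanel(simConfig(100, nChromosomes = 3L,
                                 markersPerChromosome = 20L,
                                 qtlPositions = list(c(1L, 10L), c(2L, 10L)),
                                 mafWindow = c(0.01, 0.10),
                                 genealogySeed = 11L, mutationSeed = 22L))
  hl <- haplotypes(low$panel)
  ml <- pmin(colMeans(hl), 1 - colMeans(hl))
  ql <- qtlMarkers(low$panel)
  expect_true(all(ml[ql] >= 0.01 & ml[ql] <= 0.10))
  # the shared genealogy seed yields identical genealogies across windows
  gHigh <- simulateGenealogies(cfg)
  gLow <- simulateGenealogies(simConfig(100, nChromosomes = 3L,
                                        markersPerChromosome = 20L,
                                        qtlPositions = list(c(1L, 10L),
                                                            c(2L, 10L)),
                                        mafWindow = c(0.01, 0.10),
                                        genealogySeed = 11L,
                                        mutationSeed = 99L))
  expect_identical(gHigh[[3]]$parent, gLow[[3]]$parent)
  expect_identical(gHigh[[3]]$time, gLow[[3]]$time)
})

test_that("markers on different chromosomes are essentially uncorrelated", {
  sim <- simulatePanel(simConfig(250, nChromosomes = 2L,
                                 markersPerChromosome = 10L,
                                 qtlPositions = list(c(1L, 5L), c(2L, 5L)),
                                 genealogySeed = 33L, mutationSeed = 44L))
  h <- haplotypes(sim$panel)
  r2 <- stats::cor(h[, 1:10], h[, 11:20])^2
  # under independence E[r2] = 1/(nh - 1); allow a generous margin
  expect_lt(mean(r2), 5 / (nrow(h) - 1))
})

test_that("diploid assembly pairs consecutive haplotypes", {
  h <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 0L), c(0L, 1L))
  gm <- assembleDiploids(toyPanel(h))
  expect_identical(unname(genotypes(gm)), rbind(c(2L, 1L), c(0L, 1L)))
  expect_identical(rownames(genotypes(gm)), c("ind_1", "ind_2"))
  # class validity already forbids odd haplotype counts
  expect_error(toyPanel(h[1:3, , drop = FALSE]), "even")
})
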