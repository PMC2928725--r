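---
title: "Methods: epistatic QTL power and BIC model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epistatic QTL power and BIC model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiqtl)
```

# The question

Two unlinked quantitative trait loci (QTL) jointly determine a trait through
a 3 x 3 table of genotypic means. When the loci interact -- in the
*molecular* sense that one locus masks the other, expressed as equality
constraints among cells of the table -- how does that interaction change (a)
the power to detect the pair with a full (cell-means) ANOVA model, and (b)
the behaviour of an exhaustive BIC model search over a genome of SNP
markers, including its type-I error on markers unlinked to the trait?

`epiqtl` provides every ingredient of that study: constrained mean tables,
exact ANOVA power theory, a coalescent simulator with frequency-conditioned
QTL, phenotype generation, the two-step BIC scan, and a replicated
experiment runner.

# Genotypic-means models

Six canonical patterns are supported. Pattern `a` is purely additive;
`b`-`e` impose masking constraints (whole rows/columns of the table forced
equal); `f` is the additive-by-additive interaction `theta[i, j] =
delta * u[i] * u[j]` with `u = (1, 0, -1)`, which has interaction variance
but no marginal effects at equal class weights.

Each canonical table is built the same way: start from the additive base
`theta[i, j] = (1 - i) + (1 - j)`, average the base values over each
constrained cell group, recenter the table to sum zero, and rescale so that
`max - min` equals the fixed phenotypic range (default 1.6). Holding the
range fixed across patterns makes the patterns comparable: they differ in
*structure*, not in scale. With a residual standard deviation of 1 the range
is expressed in residual-SD units.

```{r tables}
theta(makePatternTable("e"))
theta(makePatternTable("f"))
```

`checkPatternConstraints()` verifies the equality (or product) structure of
any table against a declared pattern.

# Exact power theory

For a balanced two-locus layout (`nPerCell` observations per cell),
`decomposeEffects()` gives the sum-to-zero factor-effects decomposition and
`expectedSS()` the expected sums of squares of the A, B and interaction
sources (df 2, 2 and 4). The full-model F test of the 9-cell model has a
noncentral-F distribution with noncentrality `totalESS / sigma^2`;
`analyticPower()` evaluates it exactly.

```{r power}
ess <- expectedSS(makePatternTable("e"), nPerCell = 5)
ess
analyticPower(ess@essA + ess@essB + ess@essEpistasis,
              dfNum = 8, dfErr = 45 - 9)
```

At fixed range and equal class weights, every epistatic pattern (`b`-`f`)
has total expected SS, and expected full-model r-squared
(`expectedR2()`), at least as large as the additive pattern -- the
mechanism by which molecular epistasis *increases* full-model detection
power.

# Simulating SNP panels

`simulatePanel()` generates a panel of `2n` haplotypes over independent
chromosomes (default 5 chromosomes x 100 markers). Within a chromosome, the
ancestral process runs coalescence at the standard pairwise rate and
recombination between adjacent markers at population rate `rhoAdjacent`
(default `2Nr = 1`), yielding one marginal genealogy per marker. Each marker
then receives exactly one mutation, placed on a branch of its marginal tree
with probability proportional to branch length, so every column is a
polymorphic SNP and derived-allele counts follow the one-mutation-per-marker
frequency spectrum.

The two QTL (default: the mid-chromosome marker on chromosomes 1 and 2, so
they are unlinked) are *conditioned* to a minor-allele-frequency window --
default the common window `c(0.20, 0.30)`; the rare window of the factorial
design is `c(0.01, 0.10)`. Conditioning is restrict-then-sample: only
branches whose clade frequency falls inside the window are eligible, sampled
proportionally to length. If a tree has no eligible branch (common for the
rare window at small `n`), the chromosome's genealogy is regenerated from a
fresh sub-seed; the number of regenerations is reported per chromosome. This
conditions the genealogy on containing such a branch, which is the natural
interpretation of "QTL frequency restricted to a window" for a simulation
design, at the cost of a slight ascertainment tilt of the genealogy.

```{r simulate}
sim <- simulatePanel(simConfig(100, genealogySeed = 1, mutationSeed = 2))
sim$genotypes
qtlMarkers(sim$genotypes)
```

Two seeds control the two stochastic layers separately: holding
`genealogySeed` fixed while varying `mutationSeed` keeps the genealogies
constant across experimental settings, a variance-reduction device used by
`runReplicate()` (its genealogy seed depends only on the replicate index,
not on the setting).

# Phenotypes and the true-model fit

`generatePhenotypes()` draws `y = theta[gA, gB] + N(0, sigma^2)` at the two
QTL dosages. `fitFullModel()` fits one mean per *observed* multi-locus
genotype class -- not per theoretical cell -- so empty cells cost no
degrees of freedom: for g observed classes the overall F test has
`(g - 1, n - g)` df. A saturated fit (`rss = 0`) is flagged and its BIC is
`-Inf` by convention.

# The two-step BIC scan

Scoring all 1-3-marker subsets of 500 markers is both expensive and
dominated by redundant, tightly linked markers. Step 1
(`step1Reduce()`) therefore parses each chromosome into phylogenetically
compatible blocks with the four-gamete test (`parseBlocks()`; a block is
extended only while the incoming marker is compatible with *every* marker
already in the block), then keeps from each block the marker(s) of the
minimum-BIC one- or two-marker full model. Step 1 never consults the null
model: its job is only to thin linked markers, never to drop a region.

Step 2 (`step2Select()`) exhaustively scores the intercept-only model plus
every 1-, 2- and 3-marker model from the reduced set -- for 30 markers,
`countCandidateModels(30)` = 4525 marker models -- and returns the
minimum-BIC model. BIC is `n * log(rss / n) + (g + 1) * log(n)` with one
parameter per genotype class plus the error variance. Ties break toward
fewer markers, then lexicographic marker order. Besides the default
cell-means (`"full"`) space, `searchSpace = "main_effects"` scores additive
dosage regressions, for contrasting interaction-aware and additive-only
search.

```{r scan}
y <- generatePhenotypes(sim$genotypes,
                        phenotypeConfig(makePatternTable("e"), "chr1_50",
                                        "chr2_50", seed = 3))
selectModel(sim$panel, sim$genotypes, y)
```

# Replicated experiments

`runReplicate()` bundles simulate-generate-fit-scan for one replicate of one
setting; `runExperiment()` loops the factorial design (n in {100, 500,
1000} x {rare, common} window x patterns a-f, 50 replicates).
`estimatePower()` is the proportion of replicates whose true-model F test
rejects. `selectionMetrics()` reports exact-recovery accuracy, the
distributions of selected and correctly selected loci, and the false
discovery rate, where only the exact QTL markers count as true discoveries
(a linked neighbour counts as false, so the metrics are conservative) and
replicates selecting nothing contribute an FDR of 0 (their count is
reported separately).

`type1Scan()` measures the scan's type-I error: on the chromosomes carrying
no QTL it takes 10 evenly spaced markers each (indices
`round(1 + k * (m - 1) / 9)`, unambiguous and spanning the chromosome;
monomorphic picks fall back to the nearest polymorphic marker), fits all
4525 models, and reports the rejection proportion at the 0.05 level.
`type1Experiment()` repeats that over independent replicates;
`scripts/acceptance.R` in the source tree runs it end to end.

# Numerical and scope notes

* Class-means fits use a `rowsum`/`tabulate` kernel on centered responses
  (`y - mean(y)` before accumulating squares) for numerical stability;
  results match `lm()` to machine precision and are fast enough for the
  4500-model scans.
* Genotype classes are encoded in base 3 for up to 8 markers, beyond which
  a generic interaction coding takes over.
* All seeds are kept below 2^31 via modular sub-seed derivation, so any
  integer base seed is safe.
* Unit tests run on scaled-down genomes (fewer chromosomes/markers, reduced
  replicate counts with binomial-error-aware checks); the package defaults
  are the full study design.
* Non-goals: only two QTL, biallelic markers, complete data, and
  homoscedastic normal errors are supported; the simulator is a fixed-marker
  Hudson-style ancestral recombination graph, not a general-purpose
  population-genetics engine.
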