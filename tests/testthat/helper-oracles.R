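# Independent oracles used across tests; these deliberately avoid the
# package's own code paths.

# One draw of the normalized branch-length spectrum l_k / L of a Kingman
# coalescent tree with nh leaves, where l_k is the total length of branches
# subtending k leaves. Pure-R reference, no recombination.
kingmanSpectrumDraw <- function(nh) {
  sizes <- rep(1L, nh)
  lk <- numeric(nh - 1)
  while (length(sizes) > 1L) {
    k <- length(sizes)
    dt <- stats::rexp(1, k * (k - 1) / 2)
    lk <- lk + tabulate(sizes, nh - 1) * dt
    pick <- sample.int(k, 2L)
    sizes <- c(sizes[-pick], sum(sizes[pick]))
  }
  lk / sum(lk)
}

# Monte-Carlo estimate of E[l_k / L]: the exact law of the derived-allele
# count when each marker receives exactly one mutation placed proportional
# to branch length.
kingmanSpectrum <- function(nh, nTrees) {
  rowMeans(replicate(nTrees, kingmanSpectrumDraw(nh)))
}

# brute-force block check: every within-block marker pair must pass the
# four-gamete test, and the marker starting the next block must conflict
# with at least one member of the block it follows
blocksAreValid <- function(panel, blocks) {
  h <- haplotypes(panel)
  info <- markerInfo(panel)
  for (b in seq_len(nrow(blocks))) {
    ids <- blocks$markers[[b]]
    if (length(ids) > 1L) {
      prs <- utils::combn(ids, 2L)
      for (q in seq_len(ncol(prs)))
        if (!fourGameteCompatible(h[, prs[1, q]], h[, prs[2, q]]))
          return(FALSE)
    }
    nxt <- if (b < nrow(blocks) && blocks$chrom[b + 1] == blocks$chrom[b])
      blocks$markers[[b + 1]][1] else NULL
    if (!is.null(nxt)) {
      conflict <- any(vapply(ids, function(m)
        !fourGameteCompatible(h[, m], h[, nxt]), logical(1)))
      if (!conflict) return(FALSE)
    }
  }
  # blocks tile each chromosome
  for (cc in unique(blocks$chrom)) {
    bb <- blocks[blocks$chrom == cc, ]
    m <- sum(info$chrom == cc)
    if (bb$start[1] != 1L || bb$end[nrow(bb)] != m) return(FALSE)
    if (nrow(bb) > 1L && any(bb$start[-1] != bb$end[-nrow(bb)] + 1L))
      return(FALSE)
  }
  TRUE
}

# hand-built 4-leaf caterpillar genealogy (single marker): leaves 0..3,
# internal nodes 4 = (0,1), 5 = (4,2), 6 = root (5,3)
caterpillarGenealogy <- function() {
  structure(list(parent = matrix(c(4L, 4L, 5L, 6L, 5L, 6L, -1L), ncol = 1),
                 time = matrix(c(0, 0, 0, 0, 1, 2, 3), ncol = 1),
                 n_leaves = 4L),
            class = "Genealogy")
}

# small hand-built haplotype panel
toyPanel <- function(h, chrom = rep(1L, ncol(h)),
                     pos = stats::ave(seq_len(ncol(h)), chrom,
                                      FUN = seq_along)) {
  colnames(h) <- paste0("chr", chrom, "_", as.integer(pos))
  rownames(h) <- paste0("hap_", seq_len(nrow(h)))
  new("HaplotypePanel", haplotypes = h, chrom = as.integer(chrom),
      pos = as.integer(pos), qtl = rep(FALSE, ncol(h)))
}
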