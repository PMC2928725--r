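## Readers and writers: VCF (via vcfR for parsing), plain TSV matrices,
## means-table text blocks and run manifests.

#' Write a genotype matrix as VCF
#'
#' One record per marker: contig \code{chr<k>}, 1-based POS = marker index
#' within its chromosome, placeholder alleles REF = A (ancestral) / ALT = T
#' (derived), INFO flag \code{QTL} on designated trait loci, and unphased GT
#' dosage fields (0/0, 0/1, 1/1) per individual.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeVcf <- function(genotypes, path) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  gmat <- slot(genotypes, "genotypes")
  info <- markerInfo(genotypes)
  gtStrings <- c("0/0", "0/1", "1/1")

  header <- c("##fileformat=VCFv4.2",
              "##source=epiqtl",
              sprintf("##contig=<ID=chr%d>", sort(unique(info$chrom))),
              "##INFO=<ID=QTL,Number=0,Type=Flag,Description=\"Designated trait locus\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(gmat)), collapse = "\t"))
  body <- vapply(seq_len(ncol(gmat)), function(j) {
    paste(c(paste0("chr", info$chrom[j]), info$pos[j], info$marker[j],
            "A", "T", ".", "PASS", if (info$qtl[j]) "QTL" else ".",
            "GT", gtStrings[gmat[, j] + 1L]), collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a biallelic, complete-data VCF (such as one written by
#' [writeVcf()]) through \pkg{vcfR}. Multi-allelic records and missing
#' genotypes are rejected: the study design assumes complete biallelic data.
#'
#' @param path VCF file path.
#' @return A [GenotypeMatrix-class]; QTL flags are recovered from the
#'   \code{QTL} INFO flag when present.
#' @export
readVcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic records are not supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (anyNA(gt)) stop("missing genotypes are not supported")
  dosage <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dosage[] <- vapply(strsplit(gt, "[/|]"), function(a)
    sum(as.integer(a)), integer(1))
  if (any(dosage < 0 | dosage > 2)) stop("genotypes must be biallelic 0/1/2")

  chrom <- as.integer(sub("^chr", "", fix[, "CHROM"]))
  pos <- as.integer(fix[, "POS"])
  infoCol <- if ("INFO" %in% colnames(fix)) fix[, "INFO"] else
    rep(".", nrow(fix))
  qtl <- grepl("(^|;)QTL(;|$)", infoCol)
  ids <- fix[, "ID"]
  g <- t(dosage)
  colnames(g) <- ifelse(is.na(ids) | ids == ".",
                        paste0("chr", chrom, "_", pos), ids)
  new("GenotypeMatrix", genotypes = g, chrom = chrom, pos = pos, qtl = qtl)
}

#' Write/read a genotype dosage matrix as TSV
#'
#' Tab-separated, '#'-prefixed header of marker ids, one row per individual
#' with the individual id in the first column. Marker ids of the form
#' \code{chr<k>_<pos>} recover the chromosome map on reading; other ids are
#' placed on a single chromosome in column order.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path file path.
#' @return \code{writeGenotypesTsv}: \code{path} invisibly;
#'   \code{readGenotypesTsv}: a [GenotypeMatrix-class] (QTL flags all FALSE;
#'   the TSV does not carry them).
#' @export
writeGenotypesTsv <- function(genotypes, path) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  gmat <- slot(genotypes, "genotypes")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#id", colnames(gmat)), collapse = "\t"), con)
  utils::write.table(cbind(rownames(gmat), gmat), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypesTsv
#' @export
readGenotypesTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#")) stop("expected a '#'-prefixed header line")
  fields <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)[[1]]
  dat <- utils::read.table(path, sep = "\t", skip = 1L,
                           stringsAsFactors = FALSE)
  ids <- dat[[1]]
  g <- as.matrix(dat[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- ids
  colnames(g) <- fields[-1]
  if (anyNA(g)) stop("missing genotypes are not supported")

  m <- regmatches(fields[-1], regexec("^chr([0-9]+)_([0-9]+)$", fields[-1]))
  parsed <- lengths(m) == 3L
  if (all(parsed)) {
    chrom <- vapply(m, function(x) as.integer(x[2]), integer(1))
    pos <- vapply(m, function(x) as.integer(x[3]), integer(1))
  } else {
    chrom <- rep(1L, ncol(g))
    pos <- seq_len(ncol(g))
  }
  new("GenotypeMatrix", genotypes = g, chrom = chrom, pos = pos,
      qtl = rep(FALSE, ncol(g)))
}

#' Write/read a phenotype vector as TSV
#'
#' Two tab-separated columns under a '#'-prefixed header: individual id and
#' trait value.
#'
#' @param phenotype named numeric vector (names = individual ids).
#' @param path file path.
#' @return \code{writePhenotypeTsv}: \code{path} invisibly;
#'   \code{readPhenotypeTsv}: a named numeric vector.
#' @export
writePhenotypeTsv <- function(phenotype, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#id\ttrait", con)
  ids <- names(phenotype)
  if (is.null(ids)) ids <- paste0("ind_", seq_along(phenotype))
  utils::write.table(data.frame(ids, unname(phenotype)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypeTsv
#' @export
readPhenotypeTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dat <- utils::read.table(path, sep = "\t", skip = 1L,
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(dat[[2]]), dat[[1]])
}

#' Read aligned genotype and phenotype inputs
#'
#' Loads a genotype file (VCF, detected from a \code{##fileformat} first
#' line or a \code{.vcf} extension, otherwise TSV) and a phenotype TSV, and
#' aligns them by individual id. Any id mismatch is an error: the study
#' assumes complete data.
#'
#' @param genotypePath VCF or TSV genotype file.
#' @param phenotypePath phenotype TSV.
#' @return list with \code{genotypes} (a [GenotypeMatrix-class]) and
#'   \code{phenotype} (numeric vector aligned to its rows).
#' @export
readInputs <- function(genotypePath, phenotypePath) {
  isVcf <- grepl("\\.vcf(\\.gz)?$", genotypePath) ||
    startsWith(readLines(genotypePath, n = 1L), "##fileformat")
  genotypes <- if (isVcf) readVcf(genotypePath)
               else readGenotypesTsv(genotypePath)
  phenotype <- readPhenotypeTsv(phenotypePath)
  ids <- rownames(slot(genotypes, "genotypes"))
  if (!setequal(ids, names(phenotype)) || length(phenotype) != length(ids))
    stop("individual ids differ between genotype and phenotype files")
  list(genotypes = genotypes, phenotype = phenotype[ids])
}

#' Serialize a means table to/from a structured text block
#'
#' A small key: value text format recording the pattern code, the range and
#' the nine cell values (rows AA, Aa, aa by columns BB, Bb, bb).
#'
#' @param table a [GenotypeMeansTable-class].
#' @param path file path.
#' @return \code{writeMeansTable}: \code{path} invisibly;
#'   \code{readMeansTable}: a [GenotypeMeansTable-class].
#' @export
writeMeansTable <- function(table, path) {
  stopifnot(is(table, "GenotypeMeansTable"))
  th <- theta(table)
  lines <- c(paste0("pattern: ", patternCode(table)),
             paste0("range: ", format(rangeTarget(table), digits = 17)),
             "theta:",
             vapply(1:3, function(i)
               paste0("  - [", paste(format(th[i, ], digits = 17),
                                     collapse = ", "), "]"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeMeansTable
#' @export
readMeansTable <- function(path) {
  lines <- readLines(path)
  pat <- sub("^pattern:\\s*", "", grep("^pattern:", lines, value = TRUE))
  rng <- as.numeric(sub("^range:\\s*", "",
                        grep("^range:", lines, value = TRUE)))
  rows <- grep("^\\s*-\\s*\\[", lines, value = TRUE)
  if (length(rows) != 3L) stop("expected 3 theta rows")
  th <- t(vapply(rows, function(r) {
    as.numeric(strsplit(gsub("^\\s*-\\s*\\[|\\]\\s*$", "", r), ",")[[1]])
  }, numeric(3)))
  dimnames(th) <- list(.ROW_LABELS, .COL_LABELS)
  new("GenotypeMeansTable", theta = th, pattern = pat, rangeTarget = rng)
}

#' Write a run manifest
#'
#' JSON snapshot of a simulation/scan run: configuration, seeds, package
#' version and md5 checksums of every output file, sufficient to re-run any
#' replicate.
#'
#' @param path output JSON path.
#' @param config configuration list (e.g. a [simConfig()]).
#' @param files character vector of output file paths to checksum.
#' @param extra optional named list merged into the manifest.
#' @return \code{path}, invisibly.
#' @export
writeRunManifest <- function(path, config, files = character(0),
                             extra = list()) {
  manifest <- c(list(
    package = "epiqtl",
    version = as.character(utils::packageVersion("epiqtl")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    outputs = if (length(files))
      data.frame(file = files, md5 = unname(tools::md5sum(files)),
                 stringsAsFactors = FALSE)
    else NULL), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
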