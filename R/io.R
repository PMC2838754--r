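# Plain-text readers/writers for the pipeline's file dialects:
# pedigree CSV, genotype TSV matrix, PLINK-style map TSV, phenotype
# TSV, split TSV, and VCF (through vcfR).

#' @importClassesFrom vcfR vcfR
NULL

#' @rdname Pedigree
#' @param path file path
#' @export
writePedigree <- function(ped, path) {
  df <- ped@records
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname Pedigree
#' @export
readPedigree <- function(path) {
  Pedigree(read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(id = "character", sire = "character",
                                   dam = "character")))
}

#' Write/read the SNP map (PLINK-style TSV: chrom, id, cM, bp)
#'
#' @param map data.frame with columns chrom, id, cM, bp.
#' @param path file path.
#' @export
writeSnpMap <- function(map, path) {
  write.table(map[, c("chrom", "id", "cM", "bp")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSnpMap
#' @export
readSnpMap <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(id = "character"))
}

#' Write/read a genotype matrix TSV
#'
#' Rows are individuals, columns SNP ids, cells 0/1/2 or NA.
#'
#' @param gd a [GenotypeData-class].
#' @param path file path.
#' @export
writeGenotypesTsv <- function(gd, path) {
  g <- genotypes(gd)
  write.table(data.frame(id = rownames(g), g, check.names = FALSE),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGenotypesTsv
#' @param map SNP map data.frame (chrom, id, cM, bp, optionally par).
#' @param sex named character vector of sexes.
#' @export
readGenotypesTsv <- function(path, map, sex) {
  tab <- read.delim(path, check.names = FALSE,
                    colClasses = c(id = "character"))
  g <- as.matrix(tab[, -1, drop = FALSE])
  rownames(g) <- tab$id
  g <- g[, map$id, drop = FALSE]
  GenotypeData(g, map, unname(sex[tab$id]))
}

#' Write/read phenotypes TSV (id, trait, dyd, n_daughters, weight, tbv)
#'
#' @param pheno phenotype data.frame from [simulatePhenotypes()].
#' @param path file path.
#' @export
writePhenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(id = "character"))
}

#' Write/read splits TSV (replicate, role, id)
#'
#' @param splits list of [Split-class] objects.
#' @param path file path.
#' @export
writeSplits <- function(splits, path) {
  rows <- lapply(splits, function(s) data.frame(
    replicate = s@replicate,
    role = rep(c("train", "val", "excluded"),
               c(length(s@train), length(s@validation),
                 length(s@excluded))),
    id = c(s@train, s@validation, s@excluded),
    aMax = s@aMax, stringsAsFactors = FALSE))
  write.table(do.call(rbind, rows), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSplits
#' @export
readSplits <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(id = "character"))
  lapply(split(tab, tab$replicate), function(d) {
    tr <- d$id[d$role == "train"]; va <- d$id[d$role == "val"]
    new("Split", replicate = as.integer(d$replicate[1]), train = tr,
        validation = va, excluded = d$id[d$role == "excluded"],
        aMax = d$aMax[1], realizedMax = NA_real_)
  })
}

#' Write genotypes as VCF
#'
#' Emits a minimal VCF with per-sample GT fields; when a
#' [HaplotypeSet-class] is supplied the genotypes are phased
#' (`0|1` separators), for a [GenotypeData-class] they are unphased.
#' Written through vcfR, so `.gz` output is supported transparently.
#'
#' @param x a [HaplotypeSet-class] or [GenotypeData-class].
#' @param path output path (vcfR appends `.gz` if not present).
#' @export
writeGenotypesVcf <- function(x, path) {
  if (is(x, "HaplotypeSet")) {
    map <- x@map
    n <- length(x@ids)
    a1 <- x@alleles[seq(1L, 2L * n, 2L), , drop = FALSE]
    a2 <- x@alleles[seq(2L, 2L * n, 2L), , drop = FALSE]
    gtmat <- matrix(paste0(t(a1), "|", t(a2)), nrow(map), n)
    samples <- x@ids
  } else {
    map <- snpMap(x)
    g <- assay(x, "geno")
    code <- c("0/0", "0/1", "1/1")
    gtmat <- matrix(ifelse(is.na(g), "./.", code[g + 1L]),
                    nrow(g), ncol(g))
    samples <- colnames(g)
  }
  fix <- cbind(CHROM = as.character(map$chrom),
               POS = as.character(map$bp), ID = map$id,
               REF = "A", ALT = "G", QUAL = ".", FILTER = "PASS",
               INFO = ".")
  gt <- cbind(FORMAT = "GT", gtmat)
  colnames(gt) <- c("FORMAT", samples)
  v <- new("vcfR",
           meta = c("##fileformat=VCFv4.2",
                    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, path)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses GT fields into 0/1/2 allele counts (count of ALT alleles);
#' half-missing or missing calls become NA.
#'
#' @param path VCF path (.vcf or .vcf.gz).
#' @param sex named character vector of sexes (default: all male, the
#'   typical bull panel).
#' @param par logical vector flagging pseudo-autosomal SNPs (default
#'   FALSE).
#' @return a [GenotypeData-class].
#' @export
readGenotypesVcf <- function(path, sex = NULL, par = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count <- function(s) {
    al <- strsplit(s, "[|/]")
    vapply(al, function(x) {
      x <- suppressWarnings(as.integer(x))
      if (length(x) != 2 || anyNA(x)) NA_integer_ else sum(x)
    }, integer(1))
  }
  g <- apply(gt, 2L, count)
  rownames(g) <- rownames(gt)
  fix <- vcfR::getFIX(v)
  map <- data.frame(chrom = fix[, "CHROM"], id = fix[, "ID"],
                    bp = as.integer(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  map$cM <- map$bp / 1e6
  map$par <- rep_len(par, nrow(map))
  samples <- colnames(gt)
  if (is.null(sex)) sex <- setNames(rep("male", length(samples)), samples)
  GenotypeData(t(g), map, unname(sex[samples]))
}
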