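## Readers and writers for the plain-text interchange formats: 0/1/2 TSV
## genotype matrices, VCF (written directly, read back through vcfR),
## population CSV and trait CSV.

#' Write a genotype matrix as 0/1/2 TSV
#'
#' Rows are loci, columns individuals, missing genotypes written as `NA`.
#' @param g a [genotype_matrix] or plain matrix.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(g, path) {
  geno <- if (inherits(g, "genotype_matrix")) g$geno else g
  df <- data.frame(locus = rownames(geno), geno, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a 0/1/2 TSV genotype matrix
#' @param path file written by [write_genotypes_tsv()].
#' @return loci x individuals integer matrix.
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   na.strings = "NA", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a genotype matrix as VCF
#'
#' Minimal biallelic VCF 4.2 with a GT field; phased `|` separators when
#' the object carries haplotypes, unphased `/` otherwise. Missing
#' genotypes become `./.`.
#'
#' @param g a [genotype_matrix].
#' @param path output file (uncompressed `.vcf`).
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  geno <- g$geno
  phased <- !is.null(g$hapA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hzmove",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(geno)), collapse = "\t")),
             con)
  sep <- if (phased) "|" else "/"
  for (i in seq_len(nrow(geno))) {
    if (phased) {
      gt <- paste(g$hapA[i, ], g$hapB[i, ], sep = sep)
      gt[is.na(g$hapA[i, ]) | is.na(g$hapB[i, ])] <- "./."
    } else {
      gt <- c("0/0", "0/1", "1/1")[geno[i, ] + 1L]
      gt[is.na(geno[i, ])] <- "./."
    }
    writeLines(paste(c("1", i, rownames(geno)[i], "A", "T", ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses with vcfR; biallelic records only. Phased records populate the
#' haplotype matrices.
#'
#' @param path VCF file.
#' @param ind optional individual table (`ind_id`, `pop_id`, `group`) to
#'   attach.
#' @return a [genotype_matrix] (without `loci` ground-truth columns).
#' @export
read_vcf <- function(path, ind = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- suppressWarnings(matrix(as.integer(substr(gt, 1, 1)), nrow(gt),
                                dimnames = dimnames(gt)))
  a2 <- suppressWarnings(matrix(as.integer(substr(gt, 3, 3)), nrow(gt),
                                dimnames = dimnames(gt)))
  phased <- all(substr(gt[!is.na(gt)], 2, 2) == "|")
  geno <- a1 + a2
  out <- list(geno = geno,
              hapA = if (phased) a1 else NULL,
              hapB = if (phased) a2 else NULL,
              ind = ind,
              loci = data.frame(locus_id = rownames(gt), stringsAsFactors = FALSE))
  structure(out, class = "genotype_matrix")
}

#' Write / read the population table
#' @param pops population table (`pop_id`, `lat`, `lon`, `group`, ...).
#' @param path CSV file.
#' @export
write_populations_csv <- function(pops, path) {
  write.csv(pops, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_populations_csv
#' @export
read_populations_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the per-population trait summary table
#' @param traits trait table (`pop_id`, `distance_km`, `trait`, `mean`,
#'   `sd`, `n`).
#' @param path CSV file.
#' @export
write_traits_csv <- function(traits, path) {
  write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traits_csv
#' @export
read_traits_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# per-locus per-population allele count table for frequency cline fits
freq_cline_data <- function(g, pops, locus) {
  li <- match(locus, rownames(g$geno))
  dose <- g$geno[li, ]
  cnt <- tapply(dose, g$ind$pop_id, sum, na.rm = TRUE)
  tot <- tapply(!is.na(dose), g$ind$pop_id, sum) * 2
  data.frame(pop_id = names(cnt),
             distance_km = pops$distance_km[match(names(cnt), pops$pop_id)],
             count = as.numeric(cnt), total = as.numeric(tot),
             stringsAsFactors = FALSE)
}
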