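## Readers and writers for the package's plain-text interchange formats:
## VCF (one pseudo-contig per chromosome), a PLINK-like genotype TSV +
## map TSV, long-format phenotype TSV, and the QTL truth-registry TSV.

#' Write a GenotypePanel to VCF
#'
#' One pseudo-contig per chromosome, 1-based positions, a single
#' \code{GT} FORMAT field with inbred calls (\code{0/0}, \code{1/1} or
#' \code{./.}).  Family labels are preserved in
#' \code{##LINEFAMILY=<line>,<family>} header lines so the panel
#' round-trips through [readVCFPanel()].
#'
#' @param panel a [GenotypePanel-class].
#' @param file output path (uncompressed \code{.vcf}).
#' @return \code{file}, invisibly.
#' @export
writeVCF <- function(panel, file) {
  g <- genoMatrix(panel)
  map <- markerMap(panel)
  fams <- lineFamilies(panel)
  chrom_len <- tapply(map$pos, map$chrom, max)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=plastGWAS",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_len),
            as.integer(chrom_len)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##LINEFAMILY=%s,%s", names(fams), unname(fams)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  gt <- matrix("./.", nrow(g), ncol(g))
  gt[!is.na(g) & g == 0] <- "0/0"
  gt[!is.na(g) & g == 2] <- "1/1"
  body <- paste(map$chrom, map$pos, map$marker, "A", "T", ".", "PASS",
                ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read a GenotypePanel from VCF
#'
#' Accepts biallelic VCFs with GT calls; heterozygous calls are rejected
#' (the container models inbred material).  Family labels are taken from
#' \code{##LINEFAMILY} header lines when present, otherwise from the
#' \code{families} argument.
#'
#' @param file VCF path.
#' @param families optional family label(s) per sample.
#' @return A [GenotypePanel-class].
#' @export
readVCFPanel <- function(file, families = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  num <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  num[gt %in% c("0/0", "0|0")] <- 0
  num[gt %in% c("1/1", "1|1")] <- 2
  if (any(gt %in% c("0/1", "1/0", "0|1", "1|0")))
    stop("heterozygous calls found: panel must be inbred-coded")
  geno <- t(num)
  fix <- vcfR::getFIX(v)
  map <- data.frame(marker = fix[, "ID"], chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]))
  colnames(geno) <- map$marker
  meta <- v@meta
  fam_lines <- grep("^##LINEFAMILY=", meta, value = TRUE)
  if (length(fam_lines)) {
    parts <- strsplit(sub("^##LINEFAMILY=", "", fam_lines), ",")
    fams <- setNames(vapply(parts, `[`, "", 2L),
                     vapply(parts, `[`, "", 1L))
    fams <- fams[rownames(geno)]
  } else if (!is.null(families)) {
    fams <- if (length(families) == 1L)
      setNames(rep(families, nrow(geno)), rownames(geno))
    else setNames(families, rownames(geno))
  } else {
    fams <- setNames(rep("FNA", nrow(geno)), rownames(geno))
  }
  GenotypePanel(geno, map, fams)
}

#' Write a GenotypePanel as PLINK-like TSVs
#'
#' \code{<prefix>_geno.tsv}: lines x markers table with columns
#' \code{line}, \code{family}, then one column per marker id (values 0,
#' 2 or NA).  \code{<prefix>_map.tsv}: marker, chrom, pos.
#'
#' @param panel a [GenotypePanel-class].
#' @param prefix path prefix for the two files.
#' @return character vector of the two paths, invisibly.
#' @export
writeGenoTSV <- function(panel, prefix) {
  g <- genoMatrix(panel)
  geno_df <- data.frame(line = rownames(g),
                        family = unname(lineFamilies(panel)),
                        g, check.names = FALSE)
  fg <- paste0(prefix, "_geno.tsv")
  fm <- paste0(prefix, "_map.tsv")
  write.table(geno_df, fg, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(markerMap(panel), fm, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fg, fm))
}

#' Read a GenotypePanel from PLINK-like TSVs
#'
#' @param prefix path prefix used by [writeGenoTSV()].
#' @return A [GenotypePanel-class].
#' @export
readGenoTSV <- function(prefix) {
  geno_df <- read.table(paste0(prefix, "_geno.tsv"), sep = "\t",
                        header = TRUE, check.names = FALSE)
  map <- read.table(paste0(prefix, "_map.tsv"), sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "integer"))
  g <- as.matrix(geno_df[, -(1:2), drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- geno_df$line
  GenotypePanel(g, map, setNames(geno_df$family, geno_df$line))
}

#' Write / read long-format phenotypes
#'
#' Columns \code{genotype}, \code{trait}, \code{env}, \code{rep},
#' \code{value}, tab-separated.
#'
#' @param phenotypes data.frame from [simulatePhenotypes()].
#' @param file path.
#' @return the path (writer) or the data.frame (reader).
#' @export
writePhenoTSV <- function(phenotypes, file) {
  write.table(phenotypes, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname writePhenoTSV
#' @export
readPhenoTSV <- function(file) {
  read.table(file, sep = "\t", header = TRUE,
             colClasses = c("character", "character", "character",
                            "integer", "numeric"))
}

#' Write / read the QTL truth registry
#'
#' @param registry a [QTLRegistry-class].
#' @param file TSV path.
#' @return the path (writer) or a [QTLRegistry-class] (reader).
#' @export
writeQTLRegistryTSV <- function(registry, file) {
  write.table(qtlEntries(registry), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname writeQTLRegistryTSV
#' @export
readQTLRegistryTSV <- function(file) {
  QTLRegistry(read.table(file, sep = "\t", header = TRUE,
                         colClasses = c("character", "character",
                                        "numeric", "numeric", "logical")))
}
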