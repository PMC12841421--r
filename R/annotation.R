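## Downstream interpretation of retained SNPs: region classification
## against a GFF3 annotation, GO overrepresentation, karyogram (BED)
## export, and allele-direction analysis of antagonistic pleiotropy.

#' @importFrom GenomicRanges GRanges findOverlaps distanceToNearest
#'   reduce mcols start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

.checkGFF3 <- function(file) {
  lines <- readLines(file)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
  bad <- body[nf != 9L]
  if (length(bad))
    stop("malformed GFF3 at line ", bad[1L],
         ": expected 9 tab-separated fields")
  invisible(TRUE)
}

#' Classify markers into coding / intronic / intergenic regions
#'
#' A marker inside any CDS interval (union over transcripts) is
#' \code{coding}; inside a gene body but outside every CDS,
#' \code{intronic} (UTR positions therefore classify as intronic in
#' this three-way scheme); otherwise \code{intergenic}, with the bp
#' distance to the nearest gene boundary.
#'
#' @param markers data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos} (e.g. a [markerMap()] subset).
#' @param gff3 path to a GFF3 file with gene/mRNA/CDS features
#'   (1-based, inclusive coordinates).
#' @return data.frame: \code{marker}, \code{region}, \code{gene_id}
#'   (NA for intergenic), \code{distance} (0 inside a gene).
#' @export
classifyRegion <- function(markers, gff3) {
  .checkGFF3(gff3)
  ann <- rtracklayer::import(gff3)
  genes <- ann[ann$type == "gene"]
  mrna  <- ann[ann$type == "mRNA"]
  cds   <- ann[ann$type == "CDS"]
  ## CDS -> gene via the Parent chain (CDS -> mRNA -> gene, or direct)
  first_parent <- function(x) vapply(as.list(x$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, "")
  mrna_gene <- setNames(first_parent(mrna), mrna$ID)
  cds_parent <- first_parent(cds)
  cds_gene <- ifelse(cds_parent %in% names(mrna_gene),
                     mrna_gene[cds_parent], cds_parent)

  mk <- GRanges(markers$chrom, IRanges(markers$pos, markers$pos))
  region <- rep("intergenic", nrow(markers))
  gene_id <- rep(NA_character_, nrow(markers))
  distance <- rep(NA_real_, nrow(markers))

  ov_g <- findOverlaps(mk, genes)
  region[queryHits(ov_g)] <- "intronic"
  gene_id[queryHits(ov_g)] <- genes$ID[subjectHits(ov_g)]
  distance[queryHits(ov_g)] <- 0

  ov_c <- findOverlaps(mk, cds)
  region[queryHits(ov_c)] <- "coding"
  gene_id[queryHits(ov_c)] <- cds_gene[subjectHits(ov_c)]
  distance[queryHits(ov_c)] <- 0

  inter <- which(region == "intergenic")
  if (length(inter) && length(genes)) {
    dn <- distanceToNearest(mk[inter], genes)
    ## +1: report the positional difference to the gene boundary, not
    ## the zero-based gap
    distance[inter[queryHits(dn)]] <- mcols(dn)$distance + 1
  }
  data.frame(marker = markers$marker, region = region,
             gene_id = gene_id, distance = distance)
}

#' GO term overrepresentation
#'
#' One-sided Fisher exact test per GO term on the 2x2 table (study vs
#' rest) x (annotated to term vs not), with Benjamini-Hochberg FDR
#' across the tested terms.  Genes are the counting unit (a gene counts
#' once however many SNPs hit it); terms with zero study genes are
#' skipped.
#'
#' @param study_genes character vector of study gene ids (must be a
#'   subset of the population).
#' @param population_genes character vector: the genome-wide reference
#'   set.
#' @param gene2go data.frame with columns \code{gene_id}, \code{go_id}
#'   (optionally \code{namespace}).
#' @return data.frame per tested term: \code{go_id},
#'   \code{study_count}, \code{study_size}, \code{pop_count},
#'   \code{pop_size}, \code{odds_ratio}, \code{p_value}, \code{fdr},
#'   ordered by p-value.
#' @export
goEnrichment <- function(study_genes, population_genes, gene2go) {
  study <- unique(study_genes)
  pop <- unique(population_genes)
  if (!all(study %in% pop))
    stop("study genes must be a subset of the population")
  g2g <- gene2go[gene2go$gene_id %in% pop, , drop = FALSE]
  terms <- split(unique(g2g[, c("gene_id", "go_id")])$gene_id,
                 unique(g2g[, c("gene_id", "go_id")])$go_id)
  ns <- length(study)
  np <- length(pop)
  rows <- lapply(names(terms), function(tm) {
    tg <- terms[[tm]]
    a <- sum(study %in% tg)
    if (a == 0L) return(NULL)
    b <- ns - a
    c_ <- sum(!(tg %in% study))
    d <- (np - ns) - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = "greater")
    data.frame(go_id = tm, study_count = a, study_size = ns,
               pop_count = length(tg), pop_size = np,
               odds_ratio = (a * d) / (b * c_),
               p_value = ft$p.value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(go_id = character(), study_count = integer(),
                      study_size = integer(), pop_count = integer(),
                      pop_size = integer(), odds_ratio = numeric(),
                      p_value = numeric(), fdr = numeric()))
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Allele-direction analysis (antagonistic pleiotropy)
#'
#' For each retained marker, stratifies the plasticity estimators by
#' allele and compares the marker's estimated effects under the two
#' environments.  A marker is flagged antagonistic when the effect
#' signs differ between WW and WL and each |effect| exceeds
#' \code{k} standard errors (the noise floor guarding against sign
#' flips of near-zero effects).
#'
#' @param panel a [GenotypePanel-class].
#' @param plasticity a [plasticityTable()] data.frame.
#' @param scan_ww,scan_wl scan results (e.g. [mlmScan()]) for the WW
#'   and WL environment means of the trait, providing \code{score} and
#'   \code{se} per marker.
#' @param markers marker ids to analyse.
#' @param trait trait name (selects the plasticity rows).
#' @param k noise floor in standard errors (default 2).
#' @return data.frame, one row per (marker, estimator): allele-mean
#'   columns \code{mean_allele0}, \code{mean_allele2}, the
#'   per-environment effects and the \code{antagonistic} flag.
#'   Monomorphic markers are skipped with a warning.
#' @export
alleleDirection <- function(panel, plasticity, scan_ww, scan_wl,
                            markers, trait, k = 2) {
  g <- genoMatrix(panel)
  pl <- plasticity[plasticity$trait == trait, , drop = FALSE]
  ests <- intersect(ESTIMATORS, names(pl))
  rows <- list()
  for (m in markers) {
    x <- g[pl$genotype, m]
    if (length(unique(na.omit(x))) < 2L) {
      warning("marker ", m, " is monomorphic: skipped")
      next
    }
    iww <- match(m, scan_ww$marker)
    iwl <- match(m, scan_wl$marker)
    bww <- scan_ww$score[iww]; sww <- scan_ww$se[iww]
    bwl <- scan_wl$score[iwl]; swl <- scan_wl$se[iwl]
    ant <- !is.na(bww) && !is.na(bwl) &&
      sign(bww) != sign(bwl) &&
      abs(bww) > k * sww && abs(bwl) > k * swl
    for (e in ests) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, trait = trait, estimator = e,
        mean_allele0 = mean(pl[[e]][!is.na(x) & x == 0], na.rm = TRUE),
        mean_allele2 = mean(pl[[e]][!is.na(x) & x == 2], na.rm = TRUE),
        effect_WW = bww, effect_WL = bwl, antagonistic = ant)
    }
  }
  if (!length(rows))
    return(data.frame(marker = character(), trait = character(),
                      estimator = character(),
                      mean_allele0 = numeric(),
                      mean_allele2 = numeric(),
                      effect_WW = numeric(), effect_WL = numeric(),
                      antagonistic = logical()))
  do.call(rbind, rows)
}

#' Karyogram (BED) export of significant markers
#'
#' Converts 1-based map positions to BED intervals (0-based, half-open:
#' a marker at bp p becomes [p-1, p)), named by trait, grouped per
#' chromosome for plotting.
#'
#' @param markers data.frame with columns \code{marker}, \code{trait}.
#' @param map marker map (\code{marker}, \code{chrom}, \code{pos}).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param file optional path; when given the track is written as BED.
#' @return data.frame with BED columns \code{chrom}, \code{start},
#'   \code{end}, \code{name} (trait) plus \code{marker}.
#' @export
karyogramExport <- function(markers, map, chrom_lengths, file = NULL) {
  if (!nrow(markers)) {
    bed <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      marker = character())
  } else {
    i <- match(markers$marker, map$marker)
    if (anyNA(i)) stop("marker absent from map")
    pos <- map$pos[i]; chrom <- map$chrom[i]
    if (any(pos > chrom_lengths[chrom]))
      stop("marker position beyond chromosome length")
    bed <- data.frame(chrom = chrom, start = pos - 1L, end = pos,
                      name = markers$trait, marker = markers$marker)
    bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
    rownames(bed) <- NULL
  }
  if (!is.null(file))
    write.table(bed[, c("chrom", "start", "end", "name")], file,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  bed
}

#' Recover 1-based map positions from a BED track
#'
#' Inverse of the [karyogramExport()] coordinate convention.
#'
#' @param bed data.frame with \code{chrom}, \code{start}, \code{end}.
#' @return data.frame with \code{chrom}, \code{pos} (1-based).
#' @export
bedToPositions <- function(bed) {
  data.frame(chrom = bed$chrom, pos = bed$start + 1L)
}

#' Generate a synthetic annotation fixture (GFF3 + gene-to-GO map)
#'
#' Writes a small synthetic GFF3 (gene -> mRNA -> CDS blocks with
#' intron gaps) and a gene-to-GO TSV over a pool of invented GO ids so
#' region classification and enrichment are testable fully offline.
#' The files are labelled synthetic; they imitate the structure, not
#' the content, of a real genome annotation.
#'
#' @param dir output directory.
#' @param chroms chromosome names.
#' @param chrom_length chromosome length (bp).
#' @param genes_per_chrom genes per chromosome.
#' @param n_terms size of the GO term pool.
#' @param seed integer seed.
#' @return list with paths \code{gff3}, \code{gene2go} and the gene
#'   table \code{genes}.
#' @export
makeAnnotationFixture <- function(dir, chroms = paste0(1:7, "H"),
                                  chrom_length = 5e8,
                                  genes_per_chrom = 40, n_terms = 15,
                                  seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withSeed(seed, {
    rows <- character()
    genes <- list()
    for (ch in chroms) {
      starts <- sort(sample.int(chrom_length - 6e4, genes_per_chrom))
      for (i in seq_len(genes_per_chrom)) {
        gid <- sprintf("GENE.%s.%03d", ch, i)
        s <- starts[i]
        glen <- sample(8000:40000, 1L)
        e <- s + glen - 1L
        rows <- c(rows, paste(ch, "synthetic", "gene", s, e, ".", "+",
                              ".", sprintf("ID=%s", gid), sep = "\t"))
        mid <- paste0(gid, ".1")
        rows <- c(rows, paste(ch, "synthetic", "mRNA", s, e, ".", "+",
                              ".", sprintf("ID=%s;Parent=%s", mid, gid),
                              sep = "\t"))
        ## 2-3 CDS blocks separated by intron gaps
        nb <- sample(2:3, 1L)
        bl <- floor(glen / (2 * nb))
        for (b in seq_len(nb)) {
          cs <- s + (b - 1L) * 2L * bl
          rows <- c(rows, paste(ch, "synthetic", "CDS", cs,
                                cs + bl - 1L, ".", "+", "0",
                                sprintf("ID=%s.cds%d;Parent=%s",
                                        gid, b, mid), sep = "\t"))
        }
        genes[[gid]] <- data.frame(gene_id = gid, chrom = ch,
                                   start = s, end = e)
      }
    }
    gff <- file.path(dir, "synthetic_annotation.gff3")
    writeLines(c("##gff-version 3", rows), gff)

    gene_df <- do.call(rbind, genes)
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    g2g <- do.call(rbind, lapply(gene_df$gene_id, function(g)
      data.frame(gene_id = g,
                 go_id = sample(terms, sample(1:4, 1L)),
                 namespace = "biological_process")))
    g2g_path <- file.path(dir, "synthetic_gene2go.tsv")
    write.table(g2g, g2g_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(gff3 = gff, gene2go = g2g_path, genes = gene_df)
  })
}
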