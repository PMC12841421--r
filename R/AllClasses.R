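#' @import methods
#' @importFrom stats var cor sd aggregate anova as.formula complete.cases
#'   coef dist ecdf lm optimize p.adjust pchisq pnorm prcomp pt quantile
#'   resid rbinom rnorm rpois runif setNames fisher.test wilcox.test
#'   ks.test residuals na.omit model.matrix logLik
#' @importFrom utils head read.table write.table combn
NULL

## ------------------------------------------------------------------------
## GenotypePanel
## ------------------------------------------------------------------------

#' GenotypePanel: biallelic marker data for an inbred panel
#'
#' Container for an inbred (homozygote-coded) biallelic marker panel:
#' a lines x markers genotype matrix with values in \{0, 2, NA\}, a marker
#' map (chromosome, 1-based bp position) and a family label per line.
#' Heterozygotes are not represented: the panel models advanced-generation
#' inbred material such as a nested association mapping population, where
#' lines are (near-)homozygous at every locus.
#'
#' @slot genotypes numeric matrix, lines x markers, values 0, 2 or NA;
#'   rownames are line ids, colnames are marker ids.
#' @slot map data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos} (1-based bp), one row per column of \code{genotypes},
#'   positions strictly increasing within a chromosome.
#' @slot families character vector of family labels, named by line id.
#'
#' @seealso [GenotypePanel()] for the constructor, [markerQC()],
#'   [kinshipMatrix()], [simulateGenotypes()].
#' @export
setClass("GenotypePanel",
  representation(
    genotypes = "matrix",
    map       = "data.frame",
    families  = "character"
  )
)

setValidity("GenotypePanel", function(object) {
  g <- object@genotypes
  m <- object@map
  msg <- character()
  if (is.null(rownames(g)) || is.null(colnames(g)))
    msg <- c(msg, "genotype matrix must have line and marker dimnames")
  bad <- g[!is.na(g)]
  if (length(bad) && !all(bad %in% c(0, 2)))
    msg <- c(msg, "genotype values must be 0, 2 or NA (inbred coding)")
  if (!all(c("marker", "chrom", "pos") %in% names(m)))
    msg <- c(msg, "map must have columns marker, chrom, pos")
  else {
    if (nrow(m) != ncol(g))
      msg <- c(msg, "map rows must match genotype columns")
    else if (!identical(as.character(m$marker), colnames(g)))
      msg <- c(msg, "map marker ids must equal genotype column names")
    if (anyDuplicated(m$marker))
      msg <- c(msg, "marker ids must be unique")
    inc <- vapply(split(m$pos, m$chrom), function(p) all(diff(p) > 0),
                  logical(1))
    if (!all(inc))
      msg <- c(msg, "positions must be strictly increasing per chromosome")
  }
  if (length(object@families) != nrow(g) ||
      !identical(names(object@families), rownames(g)))
    msg <- c(msg, "families must be named by line id, one per line")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param genotypes lines x markers numeric matrix with values 0/2/NA and
#'   full dimnames.
#' @param map data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos} matching the matrix columns.
#' @param families family label per line; a single value is recycled.
#' @return A [GenotypePanel-class] object.
#' @examples
#' g <- matrix(c(0, 2, 2, 0), 2, 2,
#'             dimnames = list(c("L1", "L2"), c("m1", "m2")))
#' map <- data.frame(marker = c("m1", "m2"), chrom = "1H", pos = c(100, 200))
#' GenotypePanel(g, map, families = "F01")
#' @export
GenotypePanel <- function(genotypes, map, families) {
  if (length(families) == 1L)
    families <- rep(families, nrow(genotypes))
  if (is.null(names(families)))
    names(families) <- rownames(genotypes)
  map$marker <- as.character(map$marker)
  map$chrom  <- as.character(map$chrom)
  rownames(map) <- NULL
  new("GenotypePanel", genotypes = genotypes, map = map,
      families = families)
}

#' @describeIn GenotypePanel-class number of lines
#' @param object,x a \code{GenotypePanel}
#' @export
nLines <- function(x) nrow(x@genotypes)

#' @describeIn GenotypePanel-class number of markers
#' @export
nMarkers <- function(x) ncol(x@genotypes)

#' @describeIn GenotypePanel-class the lines x markers genotype matrix
#' @export
genoMatrix <- function(x) x@genotypes

#' @describeIn GenotypePanel-class the marker map (marker, chrom, pos)
#' @export
markerMap <- function(x) x@map

#' @describeIn GenotypePanel-class family label per line
#' @export
lineFamilies <- function(x) x@families

#' Mean-imputed genotype matrix
#'
#' Missing entries of the genotype matrix replaced by the marker mean
#' (computed over non-missing lines).  Used for all numeric work
#' (kinship, PCA, scans); exported files keep the original missing codes.
#'
#' @param x a [GenotypePanel-class]
#' @return numeric matrix without NAs.
#' @export
imputedMatrix <- function(x) {
  g <- x@genotypes
  if (!anyNA(g)) return(g)
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  g[idx] <- mu[idx[, 2L]]
  g
}

setMethod("show", "GenotypePanel", function(object) {
  g <- object@genotypes
  cat("GenotypePanel:", nrow(g), "lines x", ncol(g), "markers\n")
  cat("  chromosomes:", paste(unique(object@map$chrom), collapse = ", "),
      "\n")
  cat("  families:", length(unique(object@families)), "\n")
  cat("  missing: ", sprintf("%.2f%%", 100 * mean(is.na(g))), "\n",
      sep = "")
})

## ------------------------------------------------------------------------
## QTLRegistry
## ------------------------------------------------------------------------

#' QTLRegistry: planted-truth ledger of simulated QTL effects
#'
#' One row per planted QTL: marker id, trait, additive allele effect in
#' each environment (trait units per allele copy), and an antagonism
#' flag.  A QTL is antagonistic if and only if its two environment
#' effects are nonzero and of opposite sign -- the simulated analogue of
#' antagonistic pleiotropy, where the allele that helps under stress
#' hurts under optimal conditions.
#'
#' @slot entries data.frame with columns \code{marker}, \code{trait},
#'   \code{effect_WW}, \code{effect_WL}, \code{antagonistic}.
#' @seealso [plantQTLs()], [simulatePhenotypes()]
#' @export
setClass("QTLRegistry", representation(entries = "data.frame"))

setValidity("QTLRegistry", function(object) {
  e <- object@entries
  need <- c("marker", "trait", "effect_WW", "effect_WL", "antagonistic")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns",
                 paste(need, collapse = ", ")))
  ant <- sign(e$effect_WW) * sign(e$effect_WL) < 0 &
    e$effect_WW != 0 & e$effect_WL != 0
  if (nrow(e) && !identical(as.logical(e$antagonistic), ant))
    return("antagonistic flag must equal sign(effect_WW)*sign(effect_WL) < 0 with both effects nonzero")
  TRUE
})

#' Construct a QTLRegistry
#'
#' @param entries data.frame with columns \code{marker}, \code{trait},
#'   \code{effect_WW}, \code{effect_WL}; the \code{antagonistic} flag is
#'   derived from the effect signs.
#' @return A [QTLRegistry-class]
#' @export
QTLRegistry <- function(entries) {
  entries$marker <- as.character(entries$marker)
  entries$trait  <- as.character(entries$trait)
  entries$antagonistic <-
    sign(entries$effect_WW) * sign(entries$effect_WL) < 0 &
    entries$effect_WW != 0 & entries$effect_WL != 0
  rownames(entries) <- NULL
  new("QTLRegistry", entries = entries)
}

#' @describeIn QTLRegistry-class the entries data.frame
#' @param object,x a \code{QTLRegistry}
#' @export
qtlEntries <- function(x) x@entries

setMethod("show", "QTLRegistry", function(object) {
  e <- object@entries
  cat("QTLRegistry:", nrow(e), "planted QTLs (",
      sum(e$antagonistic), "antagonistic )\n")
  if (nrow(e)) print(utils::head(e, 8))
})
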