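## Marker quality control, genomic relationship (kinship), population
## structure by PCA, and linkage-disequilibrium decay.

#' Marker quality control
#'
#' Applies, in order: (i) removal of markers with a missing-call
#' fraction at or above \code{max_missing}; (ii) removal of monomorphic
#' markers (no variation among non-missing calls); (iii) removal of
#' markers in complete linkage disequilibrium (r^2 = 1 on complete
#' cases) with an earlier marker, keeping the first in map order.
#' Missingness is preserved in the returned panel; numeric analyses
#' impute to the marker mean on the fly via [imputedMatrix()], so QC is
#' reversible on export.
#'
#' @param panel a [GenotypePanel-class].
#' @param max_missing markers with missing fraction >= this are removed
#'   (default 0.10, i.e. markers are kept with < 10% missing data).
#' @return list with \code{panel} (filtered [GenotypePanel-class]) and
#'   \code{report} (one-row data.frame: \code{n_input},
#'   \code{n_removed_missing}, \code{n_removed_monomorphic},
#'   \code{n_removed_duplicate_ld}, \code{n_retained}).
#' @export
markerQC <- function(panel, max_missing = 0.10) {
  g <- genoMatrix(panel)
  n_input <- ncol(g)

  miss_frac <- colMeans(is.na(g))
  keep1 <- miss_frac < max_missing
  n_miss <- sum(!keep1)
  g1 <- g[, keep1, drop = FALSE]

  mono <- apply(g1, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || length(unique(x)) < 2L
  })
  n_mono <- sum(mono)
  g2 <- g1[, !mono, drop = FALSE]
  if (ncol(g2) == 0L) stop("all markers removed by QC")

  ## complete LD: r^2 == 1 on complete cases; keep first in map order
  r <- suppressWarnings(cor(g2, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  dup <- rep(FALSE, ncol(g2))
  for (j in seq_len(ncol(g2))[-1])
    dup[j] <- any(abs(r[seq_len(j - 1L), j][!dup[seq_len(j - 1L)]]) >
                    1 - 1e-9)
  n_dup <- sum(dup)
  keep_markers <- colnames(g2)[!dup]
  if (length(keep_markers) == 0L) stop("all markers removed by QC")

  map <- markerMap(panel)
  out <- GenotypePanel(g2[, !dup, drop = FALSE],
                       map[match(keep_markers, map$marker), ],
                       lineFamilies(panel))
  list(panel = out,
       report = data.frame(n_input = n_input,
                           n_removed_missing = n_miss,
                           n_removed_monomorphic = n_mono,
                           n_removed_duplicate_ld = n_dup,
                           n_retained = length(keep_markers)))
}

#' VanRaden genomic relationship matrix
#'
#' \eqn{K = W W^T / (2 \sum_m p_m (1 - p_m))} where W is the
#' mean-imputed genotype matrix centred by twice the allele frequency.
#' Symmetric and positive semi-definite up to numerical tolerance; used
#' as the random-effect covariance of the kinship mixed-model scan.
#'
#' @param panel a QC'd [GenotypePanel-class].
#' @return line x line numeric matrix.
#' @export
kinshipMatrix <- function(panel) {
  g <- imputedMatrix(panel)
  p <- colMeans(g) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: kinship undefined")
  w <- sweep(g, 2, 2 * p)
  (w %*% t(w)) / denom
}

#' Principal component analysis of the genotype matrix
#'
#' PCA of the centred, mean-imputed genotype matrix -- the standard
#' population-structure summary.  Variance percentages are
#' non-increasing and sum to at most 100.
#'
#' @param panel a QC'd [GenotypePanel-class].
#' @param n_components number of components to return.
#' @return list with \code{scores} (lines x components),
#'   \code{var_pct} (percent variance per component) and
#'   \code{families} (for plotting).
#' @export
panelPCA <- function(panel, n_components = 10) {
  g <- imputedMatrix(panel)
  pr <- prcomp(g, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > 1e-12)
  k <- min(n_components, ncol(pr$x))
  if (n_components > rank)
    warning("n_components exceeds matrix rank; truncated to ", rank)
  tot <- sum(pr$sdev^2)
  var_pct <- if (tot > 0) 100 * pr$sdev[seq_len(k)]^2 / tot
             else rep(0, k)
  list(scores = pr$x[, seq_len(k), drop = FALSE], var_pct = var_pct,
       families = lineFamilies(panel))
}

#' Linkage-disequilibrium decay curve
#'
#' For every within-chromosome marker pair with bp distance at most
#' \code{max_distance}, r^2 is the squared Pearson correlation of
#' allele counts on pairwise-complete cases; pairs are averaged within
#' half-open distance bins [lo, hi).
#'
#' @param panel a QC'd [GenotypePanel-class].
#' @param max_distance largest pair distance considered (bp).
#' @param bin_width bin width (bp).
#' @return data.frame with columns \code{bin_lo}, \code{bin_hi},
#'   \code{mean_r2}, \code{n_pairs}; empty (with a warning) when no
#'   pair qualifies.
#' @export
ldDecay <- function(panel, max_distance = 5e7, bin_width = 5e6) {
  g <- genoMatrix(panel)
  map <- markerMap(panel)
  dists <- numeric()
  r2s <- numeric()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2L) next
    r <- suppressWarnings(cor(g[, idx, drop = FALSE],
                              use = "pairwise.complete.obs"))
    dmat <- abs(outer(map$pos[idx], map$pos[idx], "-"))
    ut <- upper.tri(dmat)
    ok <- ut & dmat <= max_distance & !is.na(r)
    dists <- c(dists, dmat[ok])
    r2s <- c(r2s, r[ok]^2)
  }
  if (!length(dists)) {
    warning("no eligible marker pairs for LD decay")
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      mean_r2 = numeric(), n_pairs = integer()))
  }
  bin <- findInterval(dists, seq(0, max_distance, by = bin_width),
                      rightmost.closed = FALSE)
  lo <- (sort(unique(bin)) - 1) * bin_width
  data.frame(bin_lo = lo, bin_hi = lo + bin_width,
             mean_r2 = as.numeric(tapply(r2s, bin, mean)),
             n_pairs = as.integer(table(bin)))
}
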