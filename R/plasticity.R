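## Plasticity estimation: per-genotype environment means and the five
## estimators used to structure the association scans -- the WW and WL
## means themselves, the WW/WL ratio, the relative distance plasticity
## index (RDPI), the across-environment coefficient of variation, and
## the Finlay-Wilkinson regression slope ("Linear").

ESTIMATORS <- c("WW", "WL", "Ratio", "RDPI", "CV", "Linear")

## fixed priority used by the redundancy screen (higher = kept when a
## correlated pair must be broken)
.ESTIMATOR_PRIORITY <- c(WW = 6, WL = 5, Linear = 4, RDPI = 3,
                         Ratio = 2, CV = 1)

#' Per-genotype environment means
#'
#' Arithmetic mean over replicates for every (genotype, trait,
#' environment) cell.  A cell with no replicates is reported as NA
#' (absent), never as zero; genotypes lacking one environment are
#' thereby excluded from all paired metrics downstream.
#'
#' @param phenotypes long-format data.frame with columns
#'   \code{genotype}, \code{trait}, \code{env}, \code{value}.
#' @return data.frame with one row per (genotype, trait): columns
#'   \code{WW}, \code{WL} (means) and \code{n_WW}, \code{n_WL}
#'   (replicate counts).
#' @export
envMeans <- function(phenotypes) {
  stopifnot(nrow(phenotypes) > 0,
            all(c("genotype", "trait", "env", "value") %in%
                  names(phenotypes)))
  agg <- aggregate(value ~ genotype + trait + env, phenotypes, mean)
  cnt <- aggregate(value ~ genotype + trait + env, phenotypes, length)
  key <- unique(agg[, c("genotype", "trait")])
  pick <- function(df, e) {
    i <- match(paste(key$genotype, key$trait),
               paste(df$genotype[df$env == e], df$trait[df$env == e]))
    df$value[df$env == e][i]
  }
  out <- data.frame(key,
                    WW = pick(agg, "WW"), WL = pick(agg, "WL"),
                    n_WW = pick(cnt, "WW"), n_WL = pick(cnt, "WL"))
  out$n_WW[is.na(out$n_WW)] <- 0L
  out$n_WL[is.na(out$n_WL)] <- 0L
  rownames(out) <- NULL
  out
}

#' Relative distance plasticity index
#'
#' RDPI = |x_WW - x_WL| / (x_WW + x_WL) for nonnegative trait values:
#' the absolute distance between conditions divided by their sum.  With
#' two environments and genotype means, the pairwise-distance definition
#' of the index collapses to this single ratio.  Bounded in [0, 1],
#' symmetric in its arguments and scale-invariant.
#'
#' @param x_ww,x_wl nonnegative trait means under each environment
#'   (vectorised).
#' @return numeric vector in [0, 1]; NA where both inputs are zero (the
#'   index is undefined there).
#' @examples
#' rdpi(18.33, 7.63)   # 0.4122
#' @export
rdpi <- function(x_ww, x_wl) {
  if (any(x_ww < 0 | x_wl < 0, na.rm = TRUE))
    warning("RDPI assumes nonnegative trait values")
  out <- abs(x_ww - x_wl) / (x_ww + x_wl)
  out[!is.na(x_ww) & !is.na(x_wl) & x_ww == 0 & x_wl == 0] <- NA_real_
  out
}

#' WW/WL ratio and across-environment coefficient of variation
#'
#' The ratio x_WW / x_WL is a simple relative measure of change (> 1
#' means reduction under stress).  The CV is the sample (n-1) standard
#' deviation of the two environment means divided by their mean, a proxy
#' for intra-genotype variability across environments.
#'
#' @param x_ww,x_wl trait means under each environment (vectorised).
#' @return data.frame with columns \code{ratio} (NA where x_WL = 0) and
#'   \code{cv} (NA where the mean is 0).
#' @examples
#' ratioCV(18.33, 7.63)  # ratio 2.4023
#' @export
ratioCV <- function(x_ww, x_wl) {
  ratio <- ifelse(!is.na(x_wl) & x_wl == 0, NA_real_, x_ww / x_wl)
  m <- (x_ww + x_wl) / 2
  s <- abs(x_ww - x_wl) / sqrt(2)   # sample sd of two values
  cv <- ifelse(!is.na(m) & m == 0, NA_real_, s / m)
  data.frame(ratio = ratio, cv = cv)
}

#' Finlay-Wilkinson slopes
#'
#' Classic joint-regression reaction-norm model
#' \eqn{y_{ij} = \mu_i + b_i E_j + \epsilon_{ij}}: the environmental
#' index \eqn{E_j} is the centred environment mean (mean over genotypes
#' in environment j minus the grand mean, computed from genotypes with
#' complete data), and \eqn{b_i} is the least-squares slope of each
#' genotype's values on that index.  With exactly two environments
#' \eqn{b_i = (y_{i,WW} - y_{i,WL}) / (E_{WW} - E_{WL})}.  By
#' construction the average slope over complete-data genotypes is
#' exactly 1; slopes near 1 indicate average environmental sensitivity,
#' near 0 stability.
#'
#' @param env_means output of [envMeans()].
#' @param trait trait name to use.
#' @return list with \code{slopes} (named per genotype; NA where a
#'   genotype lacks an environment) and \code{index} (named environment
#'   index, \code{WW}/\code{WL}).
#' @export
fwSlopes <- function(env_means, trait) {
  em <- env_means[env_means$trait == trait, , drop = FALSE]
  if (!nrow(em)) stop("no data for trait ", trait)
  cc <- !is.na(em$WW) & !is.na(em$WL)
  if (sum(cc) < 2) stop("need >= 2 genotypes with both environments")
  grand <- mean(c(em$WW[cc], em$WL[cc]))
  index <- c(WW = mean(em$WW[cc]) - grand, WL = mean(em$WL[cc]) - grand)
  if (index["WW"] == index["WL"])
    stop("degenerate environmental index: environments do not differ")
  slopes <- rep(NA_real_, nrow(em))
  slopes[cc] <- (em$WW[cc] - em$WL[cc]) / (index[["WW"]] - index[["WL"]])
  names(slopes) <- em$genotype
  list(slopes = slopes, index = index)
}

#' Paired Wilcoxon signed-rank test between environments
#'
#' Two-sided signed-rank test on per-genotype (WW - WL) differences.
#' Zero differences are dropped; the exact null distribution is used for
#' n <= 25 untied differences, the tie-corrected normal approximation
#' otherwise.
#'
#' @param x [envMeans()] output or a long-format phenotype table (which
#'   is aggregated first).
#' @param trait trait name.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with \code{statistic} (V, sum of positive ranks),
#'   \code{p_value}, and \code{n} (nonzero pairs used).
#' @export
wilcoxonEnv <- function(x, trait, exact_max = 25) {
  if ("value" %in% names(x)) x <- envMeans(x)
  em <- x[x$trait == trait & !is.na(x$WW) & !is.na(x$WL), , drop = FALSE]
  if (nrow(em) < 5) stop("need >= 5 paired genotypes")
  d <- em$WW - em$WL
  nz <- d[d != 0]
  if (!length(nz)) {
    warning("all paired differences are zero")
    return(list(statistic = 0, p_value = 1, n = 0L))
  }
  ties <- any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    wilcox.test(em$WW, em$WL, paired = TRUE,
                exact = length(nz) <= exact_max && !ties,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(nz))
}

#' Full plasticity table
#'
#' Computes every estimator for every (genotype, trait): the WW and WL
#' means, Ratio, RDPI, CV and the Finlay-Wilkinson slope (Linear).
#'
#' @param phenotypes long-format phenotype data.frame.
#' @return data.frame with columns \code{genotype}, \code{trait},
#'   \code{WW}, \code{WL}, \code{Ratio}, \code{RDPI}, \code{CV},
#'   \code{Linear}.
#' @export
plasticityTable <- function(phenotypes) {
  em <- envMeans(phenotypes)
  rc <- ratioCV(em$WW, em$WL)
  out <- data.frame(genotype = em$genotype, trait = em$trait,
                    WW = em$WW, WL = em$WL,
                    Ratio = rc$ratio, RDPI = rdpi(em$WW, em$WL),
                    CV = rc$cv, Linear = NA_real_)
  for (tr in unique(out$trait)) {
    fw <- fwSlopes(em, tr)
    i <- out$trait == tr
    out$Linear[i] <- fw$slopes[match(out$genotype[i], names(fw$slopes))]
  }
  out
}

#' Estimator redundancy screen
#'
#' Computes pairwise Spearman correlations among the six estimator
#' columns (complete cases, pooled over traits) and iteratively breaks
#' any pair with |rho| above the threshold by dropping its
#' lower-priority member, with fixed priority
#' WW > WL > Linear > RDPI > Ratio > CV.  The strongest violating pair
#' is broken first.  The retained set is never empty.
#'
#' @param plasticity a [plasticityTable()] data.frame.
#' @param threshold absolute Spearman correlation above which a pair is
#'   redundant (default 0.95).
#' @return character vector of retained estimator names, with the
#'   dropped ones in \code{attr(, "dropped")}.
#' @export
estimatorScreen <- function(plasticity, threshold = 0.95) {
  cols <- intersect(ESTIMATORS, names(plasticity))
  stopifnot(length(cols) >= 2)
  x <- plasticity[, cols, drop = FALSE]
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need >= 3 complete genotypes to screen")
  retained <- cols
  dropped <- character()
  repeat {
    r <- cor(x[, retained, drop = FALSE], method = "spearman")
    diag(r) <- 0
    r[is.na(r)] <- 0
    if (max(abs(r)) <= threshold || length(retained) == 1L) break
    ij <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1L, ]
    pair <- retained[ij]
    loser <- pair[which.min(.ESTIMATOR_PRIORITY[pair])]
    dropped <- c(dropped, loser)
    retained <- setdiff(retained, loser)
  }
  structure(retained, dropped = dropped)
}
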