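## Genome-wide association scans over a per-genotype response (a trait
## mean or a plasticity estimator): a kinship mixed-model scan, an
## iterative multi-locus scan with pseudo-QTN covariates, and two
## tree-ensemble importance scans with max-statistic permutation nulls.

.scanResult <- function(df, method, trait = NA_character_,
                        estimator = NA_character_, meta = list()) {
  attr(df, "method") <- method
  attr(df, "trait") <- trait
  attr(df, "estimator") <- estimator
  attr(df, "meta") <- meta
  df
}

.alignResponse <- function(panel, response) {
  g <- imputedMatrix(panel)
  if (is.null(names(response))) {
    if (length(response) != nrow(g))
      stop("response length does not match panel lines")
    names(response) <- rownames(g)
  }
  if (!all(names(response) %in% rownames(g)))
    stop("response names do not match panel lines")
  keep <- names(response)[!is.na(response)]
  list(g = g[keep, , drop = FALSE], y = response[keep])
}

## per-marker OLS tests of y on each column of G given covariates C
## (without intercept column); returns beta, se, p
.olsScan <- function(y, G, C = NULL) {
  n <- length(y)
  X0 <- cbind(rep(1, n), C)
  qr0 <- qr(X0)
  ry <- qr.resid(qr0, y)
  RG <- qr.resid(qr0, G)
  css <- colSums(RG^2)
  df <- n - qr0$rank - 1L
  b <- colSums(RG * ry) / css
  rss <- sum(ry^2) - b^2 * css
  sigma2 <- rss / df
  se <- sqrt(sigma2 / css)
  t <- b / se
  p <- 2 * pt(-abs(t), df)
  bad <- css < 1e-12
  b[bad] <- NA_real_; se[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(beta = b, se = se, p_value = p, row.names = colnames(G))
}

## REML estimate of delta = sigma2_e / sigma2_g on the null model,
## given the eigendecomposition of K (rotated intercept-only model)
.remlDelta <- function(yr, xr, lambda) {
  n <- length(yr)
  q <- ncol(xr)
  negll <- function(logd) {
    d <- exp(logd)
    w <- 1 / (lambda + d)
    xtwx <- crossprod(xr * w, xr)
    beta <- solve(xtwx, crossprod(xr * w, yr))
    r <- yr - xr %*% beta
    s2 <- sum(w * r^2) / (n - q)
    0.5 * ((n - q) * log(s2) + sum(log(lambda + d)) +
             determinant(xtwx, logarithm = TRUE)$modulus)
  }
  opt <- optimize(negll, c(log(1e-5), log(1e5)))
  exp(opt$minimum)
}

#' Kinship mixed-model association scan
#'
#' Per-marker mixed linear model
#' \eqn{y = \mu + x_m \beta_m + g + \epsilon}, with polygenic effect
#' \eqn{g \sim N(0, \sigma^2_g K)}.  The variance ratio
#' \eqn{\delta = \sigma^2_e/\sigma^2_g} is estimated once by REML on the
#' null (intercept-only) model via the eigendecomposition of K, then
#' every marker is tested by generalized least squares in the rotated
#' space with a Wald t-test (the population-parameters-previously-
#' determined shortcut).  With K = I the test reduces exactly to the
#' ordinary least-squares t-test.
#'
#' @param panel a QC'd [GenotypePanel-class].
#' @param response named numeric vector, one value per line (a trait
#'   environment mean or plasticity estimator); NAs are dropped.
#' @param K kinship matrix; supplying one disables LOCO.
#' @param loco leave-one-chromosome-out kinship: markers on the tested
#'   chromosome are excluded from K, avoiding the mild conservativeness
#'   of proximal contamination (the tested marker contributing to its
#'   own covariance correction).  Default TRUE when K is not supplied
#'   and the panel has more than one chromosome.
#' @param trait,estimator labels stored on the result.
#' @return data.frame (\code{marker}, \code{chrom}, \code{pos},
#'   \code{score} = effect estimate, \code{se}, \code{p_value},
#'   \code{significant} = NA until [callSignificant()]); the fitted
#'   variance ratio(s) are in \code{attr(, "meta")$delta}.
#' @export
mlmScan <- function(panel, response, K = NULL, loco = is.null(K),
                    trait = NA_character_, estimator = NA_character_) {
  al <- .alignResponse(panel, response)
  g <- al$g; y <- al$y
  map <- markerMap(panel)
  if (length(unique(map$chrom)) < 2L) loco <- FALSE

  out <- data.frame(marker = map$marker, chrom = map$chrom,
                    pos = map$pos, score = NA_real_, se = NA_real_,
                    p_value = NA_real_, significant = NA)
  deltas <- list()
  if (loco) {
    for (ch in unique(map$chrom)) {
      on_ch <- map$chrom == ch
      Kc <- .vanRaden(g[, !on_ch, drop = FALSE])
      res <- .mlmCore(y, g[, on_ch, drop = FALSE], Kc)
      out$score[on_ch] <- res$beta
      out$se[on_ch] <- res$se
      out$p_value[on_ch] <- res$p
      deltas[[ch]] <- res$delta
    }
  } else {
    if (is.null(K)) K <- kinshipMatrix(panel)
    res <- .mlmCore(y, g, K[names(y), names(y)])
    out$score <- res$beta
    out$se <- res$se
    out$p_value <- res$p
    deltas <- list(all = res$delta)
  }
  .scanResult(out, method = "MLM", trait = trait, estimator = estimator,
              meta = list(delta = deltas, loco = loco, n = length(y)))
}

.vanRaden <- function(g) {
  p <- colMeans(g) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: kinship undefined")
  w <- sweep(g, 2, 2 * p)
  (w %*% t(w)) / denom
}

## GLS per-marker tests of y on columns of g under covariance
## sigma_g^2 K + sigma_e^2 I (delta estimated once by null REML)
.mlmCore <- function(y, g, K) {
  n <- length(y)
  eig <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  yr <- drop(crossprod(U, y))
  ones <- crossprod(U, rep(1, n))
  delta <- .remlDelta(yr, ones, lambda)
  w <- 1 / (lambda + delta)

  Gr <- crossprod(U, g)
  s11 <- sum(w * ones^2)
  s1y <- sum(w * ones * yr)
  syy <- sum(w * yr^2)
  s1x <- colSums(w * ones[, 1] * Gr)
  sxx <- colSums(w * Gr^2)
  sxy <- colSums(w * Gr * yr)
  det <- s11 * sxx - s1x^2
  beta <- (s11 * sxy - s1x * s1y) / det
  alpha <- (sxx * s1y - s1x * sxy) / det
  rss <- syy - alpha * s1y - beta * sxy
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * s11 / det)
  p <- 2 * pt(-abs(beta / se), n - 2)
  novar <- apply(g, 2, var) < 1e-12
  beta[novar] <- NA_real_; se[novar] <- NA_real_; p[novar] <- NA_real_
  list(beta = unname(beta), se = unname(se), p = unname(p),
       delta = delta)
}

#' Iterative multi-locus association scan
#'
#' A multi-locus procedure in the FarmCPU/BLINK family, re-derived from
#' its published principles: (i) single-marker fixed-effect tests given
#' the current pseudo-QTN covariates; (ii) candidate pseudo-QTNs chosen
#' by ascending p-value, skipping any candidate in linkage
#' disequilibrium (r^2 > \code{r2_max}) with an already-selected one;
#' (iii) the pseudo-QTN set size chosen to minimise the Bayesian
#' information criterion of the multiple-regression model; (iv) every
#' marker re-tested with the selected pseudo-QTNs (excluding itself and
#' linked ones) as covariates; iterated until the selected set
#' stabilises or \code{max_iter} is reached.  With no marker passing the
#' entry threshold the scan equals the plain single-marker scan.
#'
#' @inheritParams mlmScan
#' @param entry_alpha p-value threshold a marker must pass to become a
#'   pseudo-QTN candidate.
#' @param r2_max LD exclusion threshold between pseudo-QTNs.
#' @param max_qtn maximum number of candidate pseudo-QTNs per iteration.
#' @param max_iter maximum outer iterations.
#' @return as [mlmScan()]; selected pseudo-QTNs are reported in
#'   \code{attr(, "meta")$pseudo_qtns}.
#' @export
multilocusScan <- function(panel, response, trait = NA_character_,
                           estimator = NA_character_,
                           entry_alpha = 0.01, r2_max = 0.7,
                           max_qtn = 20, max_iter = 10) {
  al <- .alignResponse(panel, response)
  g <- al$g; y <- al$y
  n <- length(y)
  markers <- colnames(g)
  r2 <- suppressWarnings(cor(g))^2
  r2[is.na(r2)] <- 0

  selected <- character()
  for (it in seq_len(max_iter)) {
    sc <- .olsScan(y, g, C = if (length(selected))
      g[, selected, drop = FALSE] else NULL)
    ## greedy LD-pruned candidate list by ascending p
    ord <- order(sc$p_value, na.last = NA)
    cand <- character()
    for (j in ord) {
      if (sc$p_value[j] > entry_alpha) break
      m <- markers[j]
      if (all(r2[m, cand] <= r2_max)) cand <- c(cand, m)
      if (length(cand) >= max_qtn) break
    }
    ## BIC model choice over nested candidate sets
    bics <- vapply(0:length(cand), function(k) {
      X <- cbind(rep(1, n),
                 if (k) g[, cand[seq_len(k)], drop = FALSE])
      rss <- sum(qr.resid(qr(X), y)^2)
      n * log(rss / n) + (qr(X)$rank) * log(n)
    }, numeric(1))
    new_sel <- cand[seq_len(which.min(bics) - 1L)]
    if (setequal(new_sel, selected)) { selected <- new_sel; break }
    selected <- new_sel
  }

  ## final pass: re-test every marker, excluding itself and linked
  ## pseudo-QTNs from its covariate set
  res <- .olsScan(y, g, C = if (length(selected))
    g[, selected, drop = FALSE] else NULL)
  redo <- unique(c(selected,
                   markers[vapply(markers, function(m)
                     any(r2[m, selected] > r2_max), logical(1))]))
  for (m in redo) {
    keep <- setdiff(selected[r2[m, selected] <= r2_max], m)
    sc1 <- .olsScan(y, g[, m, drop = FALSE],
                    C = if (length(keep)) g[, keep, drop = FALSE]
                        else NULL)
    res[m, ] <- sc1[1, ]
  }

  map <- markerMap(panel)
  .scanResult(
    data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
               score = res$beta, se = res$se, p_value = res$p_value,
               significant = NA),
    method = "MULTILOCUS", trait = trait, estimator = estimator,
    meta = list(pseudo_qtns = selected, n = n))
}

#' Tree-ensemble importance scan with permutation null
#'
#' Fits a random-forest (\pkg{ranger}, impurity importance) or
#' gradient-boosting (\pkg{xgboost}, gain importance) regressor of the
#' response on all markers, then builds a max-statistic empirical null:
#' the model is refit on \code{n_permutations} response-permuted copies
#' and the maximum importance of each refit is pooled.  The empirical
#' p-value of marker m is \eqn{(1 + \#\{null\ maxima \ge I_m\}) /
#' (B + 1)}, which is family-wise valid (and therefore conservative
#' per-marker).  Deterministic given the seed.
#'
#' @inheritParams mlmScan
#' @param learner \code{"RF"} or \code{"GB"}.
#' @param n_permutations number of permutation refits (>= 100 for
#'   usable resolution at alpha = 0.05).
#' @param seed integer seed (mandatory).
#' @param num_trees random-forest trees per fit.
#' @param nrounds,eta,max_depth gradient-boosting hyperparameters.
#' @return as [mlmScan()] with \code{score} = importance and empirical
#'   \code{p_value}.
#' @export
mlImportanceScan <- function(panel, response, learner = c("RF", "GB"),
                             n_permutations = 100, seed,
                             trait = NA_character_,
                             estimator = NA_character_,
                             num_trees = 500, nrounds = 150,
                             eta = 0.05, max_depth = 4) {
  learner <- match.arg(learner)
  al <- .alignResponse(panel, response)
  g <- al$g; y <- al$y
  if (var(y) == 0) stop("degenerate (constant) response")
  markers <- colnames(g)

  fit_imp <- function(yy, s) {
    if (learner == "RF") {
      rf <- ranger::ranger(x = as.data.frame(g), y = yy,
                           num.trees = num_trees,
                           importance = "impurity",
                           seed = s, num.threads = 1)
      imp <- rf$variable.importance[markers]
    } else {
      dtr <- xgboost::xgb.DMatrix(g, label = yy, nthread = 1)
      bst <- xgboost::xgb.train(
        params = list(eta = eta, max_depth = max_depth, nthread = 1,
                      subsample = 1, colsample_bytree = 1,
                      seed = s),
        data = dtr, nrounds = nrounds, verbose = 0)
      it <- xgboost::xgb.importance(model = bst)
      imp <- setNames(rep(0, length(markers)), markers)
      imp[it$Feature] <- it$Gain
    }
    unname(imp)
  }

  withSeed(seed, {
    obs <- fit_imp(y, seed)
    perms <- replicate(n_permutations, sample.int(length(y)))
    null_max <- vapply(seq_len(n_permutations), function(b)
      max(fit_imp(y[perms[, b]], seed + b)), numeric(1))
    p <- vapply(obs, function(i)
      (1 + sum(null_max >= i)) / (n_permutations + 1), numeric(1))

    map <- markerMap(panel)
    .scanResult(
      data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
                 score = obs, se = NA_real_, p_value = p,
                 significant = NA),
      method = learner, trait = trait, estimator = estimator,
      meta = list(n_permutations = n_permutations, seed = seed,
                  n = length(y)))
  })
}

#' Significance calling on a scan result
#'
#' \code{bonferroni}: p <= alpha / m (m = markers with a p-value);
#' \code{bh_fdr}: Benjamini-Hochberg step-up at level alpha;
#' \code{empirical}: p <= alpha directly (for permutation p-values,
#' which are already family-wise via the max-null construction).
#'
#' @param result a scan result data.frame.
#' @param procedure one of \code{"bh_fdr"}, \code{"bonferroni"},
#'   \code{"empirical"}.
#' @param alpha level.
#' @return the result with the \code{significant} flag set and the
#'   procedure recorded in \code{attr(, "meta")}.
#' @export
callSignificant <- function(result,
                            procedure = c("bh_fdr", "bonferroni",
                                          "empirical"),
                            alpha = 0.05) {
  procedure <- match.arg(procedure)
  p <- result$p_value
  m <- sum(!is.na(p))
  sig <- switch(procedure,
    bonferroni = p <= alpha / m,
    bh_fdr = p.adjust(p, method = "BH") <= alpha,
    empirical = p <= alpha)
  result$significant <- ifelse(is.na(p), FALSE, sig)
  meta <- attr(result, "meta")
  meta$procedure <- procedure
  meta$alpha <- alpha
  attr(result, "meta") <- meta
  result
}
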