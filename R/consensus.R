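## Two-stage consensus retention across plasticity estimators and scan
## methods, intersection (upset-style) summaries, and the variance
## explained by retained QTLs.

#' Collect significant calls from scan results
#'
#' Stacks the significant markers of one or more scan results (after
#' [callSignificant()]) into the long "call set" format used by the
#' consensus stage.
#'
#' @param ... scan result data.frames, or a single list of them.
#' @return data.frame with columns \code{method}, \code{trait},
#'   \code{estimator}, \code{marker}.
#' @export
collectCalls <- function(...) {
  results <- list(...)
  if (length(results) == 1L && is.data.frame(results[[1L]]) == FALSE)
    results <- results[[1L]]
  out <- lapply(results, function(r) {
    sig <- r$marker[which(r$significant)]
    if (!length(sig)) return(NULL)
    data.frame(method = attr(r, "method"), trait = attr(r, "trait"),
               estimator = attr(r, "estimator"), marker = sig)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(method = character(), trait = character(),
                      estimator = character(), marker = character())
  out
}

#' Markers supported by at least two plasticity estimators
#'
#' Within one trait and one scan method, retains the markers called
#' significant for two or more of the five estimators (the WW and WL
#' absolute values count toward the tally alongside Ratio, RDPI and
#' Linear).
#'
#' @param calls call-set data.frame from [collectCalls()].
#' @param trait,method labels selecting the slice.
#' @return data.frame with \code{marker} and \code{estimators}
#'   (comma-separated support list).
#' @export
estimatorIntersection <- function(calls, trait, method) {
  cc <- calls[calls$trait == trait & calls$method == method, ,
              drop = FALSE]
  if (!nrow(cc))
    return(data.frame(marker = character(), estimators = character()))
  sup <- tapply(cc$estimator, cc$marker,
                function(e) sort(unique(e)), simplify = FALSE)
  keep <- names(sup)[lengths(sup) >= 2L]
  data.frame(marker = keep,
             estimators = vapply(sup[keep], paste, "", collapse = ","),
             row.names = NULL)
}

#' Prioritise markers by cross-method support
#'
#' Union of the per-method retained sets, annotated with method
#' support; markers retained by two or more scan methods are flagged
#' high-confidence.
#'
#' @param per_method named list (method -> data.frame with a
#'   \code{marker} column, e.g. [estimatorIntersection()] output).
#' @param trait trait label for the output.
#' @return data.frame with \code{trait}, \code{marker},
#'   \code{method_support}, \code{n_methods}, \code{high_confidence}.
#' @export
methodPrioritization <- function(per_method, trait = NA_character_) {
  sup <- list()
  for (m in names(per_method))
    for (mk in per_method[[m]]$marker)
      sup[[mk]] <- c(sup[[mk]], m)
  if (!length(sup))
    return(data.frame(trait = character(), marker = character(),
                      method_support = character(),
                      n_methods = integer(),
                      high_confidence = logical()))
  data.frame(trait = trait, marker = names(sup),
             method_support = vapply(sup, function(s)
               paste(sort(unique(s)), collapse = ","), ""),
             n_methods = vapply(sup, function(s)
               length(unique(s)), 0L),
             high_confidence = vapply(sup, function(s)
               length(unique(s)) >= 2L, FALSE),
             row.names = NULL)
}

#' Two-stage consensus retention
#'
#' Stage 1 (within each scan method): keep markers significant for at
#' least two plasticity estimators.  Stage 2: annotate the union of the
#' per-method retained sets with method support; markers retained by
#' two or more methods are high-confidence.  With
#' \code{within_method = FALSE} the alternative order is used: estimator
#' support is pooled across methods before the two-estimator rule.
#'
#' @param calls call-set data.frame from [collectCalls()].
#' @param trait trait to process.
#' @param within_method apply the two-estimator rule within each method
#'   first (default) or on estimator support pooled across methods.
#' @return data.frame as [methodPrioritization()] plus
#'   \code{estimator_support}.
#' @export
consensusSet <- function(calls, trait, within_method = TRUE) {
  cc <- calls[calls$trait == trait, , drop = FALSE]
  methods <- unique(cc$method)
  if (within_method) {
    per_method <- lapply(setNames(methods, methods), function(m)
      estimatorIntersection(cc, trait, m))
  } else {
    sup <- tapply(cc$estimator, cc$marker,
                  function(e) sort(unique(e)), simplify = FALSE)
    pooled <- names(sup)[lengths(sup) >= 2L]
    per_method <- lapply(setNames(methods, methods), function(m)
      data.frame(marker = intersect(pooled,
                                    cc$marker[cc$method == m])))
  }
  out <- methodPrioritization(per_method, trait)
  esup <- tapply(cc$estimator, cc$marker,
                 function(e) paste(sort(unique(e)), collapse = ","),
                 simplify = TRUE)
  out$estimator_support <- unname(esup[out$marker])
  out
}

#' Exact-subset intersection counts (upset-style)
#'
#' For every non-empty subset of methods (or estimators), the number of
#' markers significant in exactly that subset within the given trait.
#' Counts over all subsets sum to the size of the union.
#'
#' @param calls call-set data.frame.
#' @param trait trait to tabulate.
#' @param by \code{"method"} or \code{"estimator"}.
#' @return data.frame with \code{subset} (comma-separated, sorted) and
#'   \code{count}, ordered by decreasing count.
#' @export
intersectionCounts <- function(calls, trait, by = c("method",
                                                    "estimator")) {
  by <- match.arg(by)
  cc <- calls[calls$trait == trait, , drop = FALSE]
  if (!nrow(cc))
    return(data.frame(subset = character(), count = integer()))
  sig <- tapply(cc[[by]], cc$marker,
                function(v) paste(sort(unique(v)), collapse = ","))
  tab <- table(sig)
  out <- data.frame(subset = names(tab), count = as.integer(tab),
                    row.names = NULL)
  out[order(-out$count, out$subset), , drop = FALSE]
}

#' Variance explained by retained QTLs
#'
#' Regresses one response (a trait x plasticity-measure vector per
#' genotype, or the two-environment means jointly) on the genotypes of
#' the retained markers and reports the percentage of variance
#' attributable to the marker term, the environment term (when
#' present) and the residual.  In-sample proportions are accompanied by
#' an adjusted proportion and a k-fold cross-validated R^2 to temper
#' small-sample inflation.
#'
#' @param panel a [GenotypePanel-class].
#' @param response either a named numeric vector per genotype, or a
#'   data.frame with columns \code{genotype}, \code{env}, \code{value}
#'   (two-environment means; an environment term is then fitted).
#' @param markers character vector of retained marker ids.
#' @param cv_folds folds for cross-validated R^2 (default 5).
#' @param seed seed for the fold assignment.
#' @return one-row data.frame: \code{prop_G_QTL}, \code{prop_E},
#'   \code{prop_resid} (percent, in-sample), \code{prop_G_adj}
#'   (adjusted), \code{r2_cv} (cross-validated, marker term),
#'   \code{n_markers}.
#' @export
qtlVarianceExplained <- function(panel, response, markers,
                                 cv_folds = 5, seed = 1) {
  g <- imputedMatrix(panel)
  if (!all(markers %in% colnames(g)))
    stop("unknown marker in retained set")
  if (is.data.frame(response)) {
    y <- response$value
    env <- factor(response$env)
    X_env <- model.matrix(~env)[, -1, drop = FALSE]
    G <- g[response$genotype, markers, drop = FALSE]
  } else {
    y <- as.numeric(response)
    ids <- names(response)
    if (is.null(ids)) ids <- rownames(g)[seq_along(y)]
    env <- NULL
    X_env <- NULL
    G <- g[ids, markers, drop = FALSE]
  }
  ok <- !is.na(y)
  y <- y[ok]; G <- G[ok, , drop = FALSE]
  if (!is.null(X_env)) X_env <- X_env[ok, , drop = FALSE]
  n <- length(y)
  sst <- sum((y - mean(y))^2)

  if (length(markers) == 0L) {
    warning("empty marker set: no QTL variance to attribute")
    prop_e <- if (is.null(X_env)) 0 else
      100 * (sst - sum(qr.resid(qr(cbind(1, X_env)), y)^2)) / sst
    return(data.frame(prop_G_QTL = 0, prop_E = prop_e,
                      prop_resid = 100 - prop_e, prop_G_adj = 0,
                      r2_cv = 0, n_markers = 0L))
  }

  ## sequential decomposition: environment first, then markers
  X0 <- cbind(rep(1, n), X_env)
  r0 <- qr.resid(qr(X0), y)
  ss_after_env <- sum(r0^2)
  prop_e <- 100 * (sst - ss_after_env) / sst
  X1 <- cbind(X0, G)
  qr1 <- qr(X1)
  ss_resid <- sum(qr.resid(qr1, y)^2)
  prop_g <- 100 * (ss_after_env - ss_resid) / sst
  prop_resid <- 100 * ss_resid / sst
  df_model <- qr1$rank - 1L
  r2 <- (sst - ss_resid) / sst
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - df_model - 1)
  prop_g_adj <- max(0, 100 * r2_adj - prop_e)

  ## k-fold cross-validated R^2 of the full model
  press <- 0
  withSeed(seed, {
    fold <- sample(rep(seq_len(cv_folds), length.out = n))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      Xtr <- X1[tr, , drop = FALSE]
      fit <- qr.coef(qr(Xtr), y[tr])
      fit[is.na(fit)] <- 0
      pred <- drop(X1[!tr, , drop = FALSE] %*% fit)
      press <- press + sum((y[!tr] - pred)^2)
    }
  })
  r2_cv <- max(0, 1 - press / sst)

  data.frame(prop_G_QTL = prop_g, prop_E = prop_e,
             prop_resid = prop_resid, prop_G_adj = prop_g_adj,
             r2_cv = r2_cv, n_markers = length(markers))
}
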