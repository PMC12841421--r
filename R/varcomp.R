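## Variance decomposition of replicate-level traits into genotype (G),
## environment (ENV), optional GxE and residual components by REML, with
## boundary-corrected likelihood-ratio tests and the trait-retention
## rules applied before association mapping.

#' REML variance decomposition of a trait
#'
#' Fits the random-effects model
#' \eqn{y_{ijk} = \mu + G_i + E_j + (GE)_{ij} + \epsilon_{ijk}} by
#' restricted maximum likelihood (via \pkg{lme4}) and reports variance
#' components, their percentages of the total, and boundary-corrected
#' likelihood-ratio p-values for G and ENV (the 0.5 chi-square(0) +
#' 0.5 chi-square(1) mixture appropriate for testing a variance on the
#' parameter boundary).  Negative estimates cannot occur under REML
#' (they are truncated at zero by construction).
#'
#' By default the GxE term is pooled into the residual
#' (\code{include_gxe = FALSE}); when requested it is fitted only if the
#' design has replication within (genotype, environment) cells,
#' otherwise it is confounded with the residual and reported merged with
#' a flag.  Because a two-level environment factor gives an unstable
#' random-effect variance, the fixed-effect environment mean-square
#' proportion is also reported (\code{prop_ENV_fixed}) as a flagged
#' fallback.
#'
#' @param phenotypes long-format data.frame (\code{genotype},
#'   \code{trait}, \code{env}, \code{rep}, \code{value}).
#' @param trait trait to decompose.
#' @param include_gxe fit a (genotype x environment) variance component
#'   when replication allows it.
#' @return one-row data.frame: \code{trait}, \code{var_G},
#'   \code{prop_G}, \code{p_value_G}, \code{var_ENV}, \code{prop_ENV},
#'   \code{p_value_ENV}, \code{var_GxE}, \code{prop_GxE},
#'   \code{var_resid}, \code{prop_resid}, \code{prop_ENV_fixed},
#'   \code{gxe_pooled}.  Proportions are percentages summing to 100.
#' @export
fitVarianceComponents <- function(phenotypes, trait,
                                  include_gxe = FALSE) {
  d <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("no data for trait ", trait)
  if (length(unique(d$genotype)) < 2 || length(unique(d$env)) < 2)
    stop("need >= 2 genotypes and 2 environments")
  if (var(d$value) == 0) stop("zero total variance for trait ", trait)
  d$genotype <- factor(d$genotype)
  d$env <- factor(d$env)

  replicated <- any(table(d$genotype, d$env) > 1)
  use_gxe <- include_gxe && replicated
  if (include_gxe && !replicated)
    warning("no replication within (genotype, environment): ",
            "GxE is confounded with the residual and reported merged")

  fit <- function(fml) suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = d, REML = TRUE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 optCtrl = list(xtol_rel = 1e-14, ftol_rel = 1e-14,
                                xtol_abs = 1e-12, ftol_abs = 1e-14)))))
  base_terms <- c("(1 | genotype)", "(1 | env)",
                  if (use_gxe) "(1 | genotype:env)")
  fml_of <- function(terms)
    as.formula(paste("value ~ 1 +", paste(terms, collapse = " + ")))
  full <- fit(fml_of(base_terms))

  vc <- as.data.frame(lme4::VarCorr(full))
  getv <- function(grp) {
    i <- vc$grp == grp
    if (any(i)) vc$vcov[i] else 0
  }
  v_g  <- getv("genotype")
  v_e  <- getv("env")
  v_ge <- if (use_gxe) getv("genotype:env") else NA_real_
  v_r  <- getv("Residual")

  lrt_p <- function(drop_term) {
    red <- fit(fml_of(setdiff(base_terms, drop_term)))
    lr <- as.numeric(-2 * (logLik(red) - logLik(full)))
    if (lr <= 0) 1 else 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  }
  p_g <- lrt_p("(1 | genotype)")
  p_e <- lrt_p("(1 | env)")

  total <- v_g + v_e + v_r + ifelse(use_gxe, v_ge, 0)
  pct <- function(v) 100 * v / total
  ## fixed-effect fallback: share of the total sum of squares carried by
  ## the environment means
  em <- tapply(d$value, d$env, mean)
  ss_env <- sum((em[d$env] - mean(d$value))^2)
  prop_env_fixed <- 100 * ss_env / sum((d$value - mean(d$value))^2)

  data.frame(trait = trait,
             var_G = v_g, prop_G = pct(v_g), p_value_G = p_g,
             var_ENV = v_e, prop_ENV = pct(v_e), p_value_ENV = p_e,
             var_GxE = v_ge,
             prop_GxE = if (use_gxe) pct(v_ge) else NA_real_,
             var_resid = v_r, prop_resid = pct(v_r),
             prop_ENV_fixed = prop_env_fixed,
             gxe_pooled = !use_gxe)
}

#' Trait-retention rules
#'
#' @param alpha_G significance level required of the genotype variance
#'   component (traits with \code{p_value_G > alpha_G} are dropped).
#' @param min_prop_env minimum environmental variance percentage: traits
#'   below it show no relevant environmental response and are dropped.
#' @param drop_max_residual additionally drop the single surviving trait
#'   with the largest residual percentage (the least-repeatable trait).
#' @return list of class \code{RetentionRules}.
#' @export
retentionRules <- function(alpha_G = 0.05, min_prop_env = 5,
                           drop_max_residual = TRUE) {
  stopifnot(alpha_G > 0, alpha_G < 1,
            min_prop_env >= 0, min_prop_env < 100)
  structure(list(alpha_G = alpha_G, min_prop_env = min_prop_env,
                 drop_max_residual = drop_max_residual),
            class = "RetentionRules")
}

#' Apply trait-retention rules to variance decompositions
#'
#' Drops traits whose genotype component is not significant, traits
#' without a relevant environmental response, and (optionally) the one
#' remaining trait most dominated by residual noise.
#'
#' @param decompositions data.frame with one row per trait and columns
#'   \code{trait}, \code{p_value_G}, \code{prop_ENV}, \code{prop_resid}
#'   (e.g. stacked [fitVarianceComponents()] rows, or published values).
#' @param rules a [retentionRules()] object.
#' @return list with \code{retained} (character vector of traits) and
#'   \code{reasons} (data.frame trait/dropped/reason).
#' @export
retentionFilter <- function(decompositions, rules = retentionRules()) {
  if (!nrow(decompositions))
    return(list(retained = character(),
                reasons = data.frame(trait = character(),
                                     dropped = logical(),
                                     reason = character())))
  d <- decompositions
  reason <- rep(NA_character_, nrow(d))
  reason[d$p_value_G > rules$alpha_G] <- "genotype component not significant"
  drop_env <- is.na(reason) & d$prop_ENV < rules$min_prop_env
  reason[drop_env] <- "no relevant environmental response"
  if (rules$drop_max_residual) {
    alive <- which(is.na(reason))
    if (length(alive)) {
      worst <- alive[which.max(d$prop_resid[alive])]
      reason[worst] <- "highest residual proportion"
    }
  }
  list(retained = d$trait[is.na(reason)],
       reasons = data.frame(trait = d$trait, dropped = !is.na(reason),
                            reason = reason))
}

#' Published barley variance decomposition (reference values)
#'
#' Variance decomposition reported for nine agronomic traits of a large
#' spring-barley nested association mapping panel grown under
#' well-watered and water-limited regimes, shipped as a plain-text
#' fixture.  Used as the worked example for [retentionFilter()]:
#' applying the default rules retains six traits (GFP, GN, GY, TDM,
#' MAT, HI).
#'
#' @return data.frame with columns \code{trait}, \code{var_G},
#'   \code{prop_G}, \code{p_value_G}, \code{var_ENV}, \code{prop_ENV},
#'   \code{p_value_ENV}, \code{var_resid}, \code{prop_resid}.
#' @export
barleyVarianceTable <- function() {
  f <- system.file("extdata", "barley_variance_decomposition.tsv",
                   package = "plastGWAS", mustWork = TRUE)
  read.table(f, sep = "\t", header = TRUE,
             colClasses = c("character", rep("numeric", 8)))
}

#' Published barley trait means under contrasting water regimes
#'
#' Trait means (and standard errors) under the well-watered (WW) and
#' water-limited (WL) regimes for the six retained traits of the same
#' barley panel, shipped as a plain-text fixture.  These are the default
#' trait baselines of [simConfig()] and the worked example for the
#' plasticity estimators (e.g. grain yield 18.33 g under WW versus
#' 7.63 g under WL, a relative reduction just under 60%).
#'
#' @return data.frame with columns \code{trait}, \code{mean_WW},
#'   \code{se_WW}, \code{mean_WL}, \code{se_WL}.
#' @export
barleyTraitMeans <- function() {
  f <- system.file("extdata", "barley_trait_means.tsv",
                   package = "plastGWAS", mustWork = TRUE)
  read.table(f, sep = "\t", header = TRUE,
             colClasses = c("character", rep("numeric", 4)))
}
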