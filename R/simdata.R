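## Synthetic multi-family inbred panels with planted QTLs.
##
## The generator emulates a nested-association-mapping-like design: each
## family descends from two founder haplotypes, lines are single-mosaic
## recombinant inbred derivatives, and phenotypes follow an additive
## model with environment-specific QTL effects, a polygenic line effect,
## an environment shift and replicate-level residual noise.

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed, evaluates \code{code}, and restores the previous RNG
#' state so simulations are pure functions of (arguments, seed) without
#' disturbing the caller's random stream.
#' @param seed integer seed (mandatory).
#' @param code expression to evaluate.
#' @keywords internal
withSeed <- function(seed, code) {
  if (is.null(seed) || !is.finite(seed))
    stop("a finite integer seed is required for stochastic operations")
  gl <- globalenv()
  if (exists(".Random.seed", envir = gl, inherits = FALSE)) {
    old <- get(".Random.seed", envir = gl)
    on.exit(assign(".Random.seed", old, envir = gl), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = gl, inherits = FALSE))
      rm(".Random.seed", envir = gl), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic two-environment trial.
#' Defaults follow the emulated design: a multi-family barley-like panel
#' on 7 chromosomes, two water regimes (WW = well-watered,
#' WL = water-limited) with replicated plots.  Trait baselines default
#' to the well-watered grain-yield scale so synthetic values look like
#' field data (grams per plant).
#'
#' @param n_families number of families (the emulated panel has 25).
#' @param lines_per_family inbred lines per family.
#' @param n_chromosomes number of chromosomes (default 7, labelled
#'   \code{1H..7H}).
#' @param markers_per_chromosome biallelic SNPs per chromosome.
#' @param chromosome_length chromosome length in bp (default 5e8,
#'   barley-scale).
#' @param recombination_rate expected crossovers per chromosome per
#'   meiosis (Poisson mean); 0 gives perfect within-family linkage.
#' @param missing_rate fraction of genotype calls set missing, MCAR.
#' @param n_replicates replicates per (line, environment).
#' @param env_effect trait-unit shift between environments,
#'   mean(WW) - mean(WL); applied as +/- env_effect/2.
#' @param sigma2_poly variance of the iid polygenic line effect
#'   (trait units squared).
#' @param sigma2_resid replicate-level residual variance.
#' @param traits named numeric vector of trait baselines (mu per trait);
#'   default a single grain-yield-like trait \code{c(GY = 18.33)}.
#' @param seed integer seed; mandatory for every stochastic call.
#' @return A list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(n_families = 2, lines_per_family = 10,
#'                  markers_per_chromosome = 20, seed = 1)
#' @export
simConfig <- function(n_families = 25, lines_per_family = 16,
                      n_chromosomes = 7, markers_per_chromosome = 100,
                      chromosome_length = 5e8, recombination_rate = 1.5,
                      missing_rate = 0, n_replicates = 2,
                      env_effect = 2, sigma2_poly = 1, sigma2_resid = 1,
                      traits = c(GY = 18.33), seed = NULL) {
  cfg <- list(n_families = n_families, lines_per_family = lines_per_family,
              n_chromosomes = n_chromosomes,
              markers_per_chromosome = markers_per_chromosome,
              chromosome_length = chromosome_length,
              recombination_rate = recombination_rate,
              missing_rate = missing_rate, n_replicates = n_replicates,
              env_effect = env_effect, sigma2_poly = sigma2_poly,
              sigma2_resid = sigma2_resid, traits = traits, seed = seed)
  counts <- c("n_families", "lines_per_family", "n_chromosomes",
              "markers_per_chromosome", "n_replicates")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop("invalid SimConfig: ", f, " must be an integer >= 1")
  if (chromosome_length < markers_per_chromosome)
    stop("invalid SimConfig: chromosome_length too short for marker count")
  if (recombination_rate < 0)
    stop("invalid SimConfig: recombination_rate must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("invalid SimConfig: missing_rate must be in [0, 1)")
  if (sigma2_poly < 0 || sigma2_resid < 0)
    stop("invalid SimConfig: variances must be >= 0")
  if (is.null(names(traits)) || any(names(traits) == ""))
    stop("invalid SimConfig: traits must be a named numeric vector")
  structure(cfg, class = "SimConfig")
}

#' Choose simulation variances that plant target variance proportions
#'
#' Converts target proportions of genotypic, environmental and residual
#' variance (summing to 1) into \code{sigma2_poly}, \code{env_effect}
#' and \code{sigma2_resid} on a chosen total-variance scale.  The
#' environmental component is parameterised as the between-environment
#' sample variance of the two level means, d^2/2 for a shift of d, which
#' is the quantity a two-level random-intercept REML fit estimates.
#'
#' @param prop_G,prop_ENV,prop_resid target proportions in (0,1),
#'   summing to 1.
#' @param total total variance on the trait scale (default 1).
#' @param ... further arguments passed to [simConfig()].
#' @return A \code{SimConfig}.
#' @export
configForProportions <- function(prop_G, prop_ENV, prop_resid,
                                 total = 1, ...) {
  props <- c(prop_G, prop_ENV, prop_resid)
  if (any(props < 0) || abs(sum(props) - 1) > 1e-8)
    stop("proportions must be nonnegative and sum to 1")
  simConfig(sigma2_poly = prop_G * total,
            env_effect = sqrt(2 * prop_ENV * total),
            sigma2_resid = prop_resid * total, ...)
}

#' Simulate a multi-family recombinant inbred genotype panel
#'
#' Each family descends from two fully homozygous founder haplotypes
#' that differ at every marker (biparental segregation, expected allele
#' frequency 1/2 within each family).  A line inherits, per chromosome,
#' a founder mosaic with a Poisson(\code{recombination_rate}) number of
#' uniformly placed crossovers, so linkage disequilibrium decays with bp
#' distance.  Founder allele orientation is randomised per family and
#' marker, which creates the weak between-family stratification typical
#' of multi-parent panels.  Missing calls are injected completely at
#' random at \code{missing_rate}.
#'
#' @param config a [simConfig()] with a seed.
#' @return A [GenotypePanel-class].
#' @examples
#' panel <- simulateGenotypes(simConfig(n_families = 2,
#'   lines_per_family = 10, markers_per_chromosome = 30, seed = 7))
#' panel
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(config$seed, {
    nc  <- config$n_chromosomes
    mpc <- config$markers_per_chromosome
    L   <- config$chromosome_length
    nf  <- config$n_families
    lpf <- config$lines_per_family
    nl  <- nf * lpf

    chroms <- paste0(seq_len(nc), "H")
    map <- do.call(rbind, lapply(seq_len(nc), function(ci) {
      data.frame(marker = sprintf("M_%s_%03d", chroms[ci], seq_len(mpc)),
                 chrom = chroms[ci],
                 pos = sort(sample.int(L, mpc)))
    }))
    lines <- sprintf("F%02d_L%03d", rep(seq_len(nf), each = lpf),
                     rep(seq_len(lpf), nf))
    fams  <- setNames(sprintf("F%02d", rep(seq_len(nf), each = lpf)), lines)

    geno <- matrix(NA_real_, nl, nrow(map),
                   dimnames = list(lines, map$marker))
    chrom_idx <- split(seq_len(nrow(map)), map$chrom)[chroms]
    for (fi in seq_len(nf)) {
      rows <- ((fi - 1) * lpf + 1):(fi * lpf)
      ## orientation: which founder carries allele 2 at each marker
      orient <- matrix(sample(c(0, 1), nrow(map), replace = TRUE))
      for (ci in seq_len(nc)) {
        idx <- chrom_idx[[ci]]
        pos <- map$pos[idx]
        for (li in rows) {
          start <- sample(c(0L, 1L), 1L)
          ncross <- rpois(1L, config$recombination_rate)
          if (ncross > 0) {
            bp <- sort(runif(ncross, 0, L))
            founder <- (start + findInterval(pos, bp)) %% 2L
          } else founder <- rep(start, length(idx))
          ## founder 0 carries allele 2 where orient == 1
          geno[li, idx] <- 2 * as.numeric(founder == orient[idx])
        }
      }
    }
    if (config$missing_rate > 0) {
      miss <- runif(length(geno)) < config$missing_rate
      geno[miss] <- NA_real_
    }
    GenotypePanel(geno, map, fams)
  })
}

#' Plant QTL effects on a simulated panel
#'
#' Assigns additive per-allele effects to randomly chosen polymorphic
#' markers.  Effect sizes are scaled so that each QTL explains its
#' target fraction of the replicate-level phenotypic variance in its
#' designated environment, on the realized genotype frequencies:
#' with base variance \eqn{\sigma^2_{poly} + \sigma^2_{resid}} and total
#' requested fraction F, the implied total is
#' \eqn{T = (\sigma^2_{poly} + \sigma^2_{resid})/(1 - F)} and each
#' effect solves \eqn{\beta^2 Var(g) = f\,T}.
#'
#' Kinds: \code{main} has the same effect in both environments;
#' \code{plastic} acts only under WW (effects differ between
#' environments); \code{antagonistic} has opposite-sign effects of equal
#' magnitude (the allele that helps under stress hurts without it).
#'
#' @param panel a [GenotypePanel-class].
#' @param qtls data.frame with columns \code{kind} (one of
#'   \code{"main"}, \code{"plastic"}, \code{"antagonistic"}),
#'   \code{trait}, \code{var_frac} in (0,1); optional \code{marker} to
#'   pin a QTL to a specific marker.
#' @param config the [simConfig()] used for phenotype simulation
#'   (supplies the base variances and, by default, the seed).
#' @param seed integer seed; defaults to \code{config$seed}.
#' @param min_maf minimum minor-allele frequency for eligible markers.
#' @return A [QTLRegistry-class].
#' @export
plantQTLs <- function(panel, qtls, config, seed = config$seed,
                      min_maf = 0.1) {
  stopifnot(is(panel, "GenotypePanel"), is.data.frame(qtls))
  if (!all(c("kind", "trait", "var_frac") %in% names(qtls)))
    stop("qtls must have columns kind, trait, var_frac")
  if (!all(qtls$kind %in% c("main", "plastic", "antagonistic")))
    stop("unknown QTL kind")
  if (any(qtls$var_frac <= 0 | qtls$var_frac >= 1))
    stop("var_frac must lie in (0, 1)")
  withSeed(seed, {
    g <- imputedMatrix(panel)
    p <- colMeans(g) / 2
    eligible <- colnames(g)[pmin(p, 1 - p) >= min_maf]
    if (is.null(qtls$marker)) qtls$marker <- NA_character_
    free <- setdiff(eligible, qtls$marker[!is.na(qtls$marker)])
    n_pick <- sum(is.na(qtls$marker))
    if (n_pick > length(free))
      stop("more QTLs requested than eligible polymorphic markers")
    qtls$marker[is.na(qtls$marker)] <- sample(free, n_pick)
    if (!all(qtls$marker %in% colnames(g)))
      stop("requested QTL marker absent from panel")

    entries <- do.call(rbind, lapply(split(qtls, qtls$trait), function(q) {
      Ftot <- sum(q$var_frac)
      if (Ftot >= 1) stop("total var_frac per trait must be < 1")
      Tvar <- (config$sigma2_poly + config$sigma2_resid) / (1 - Ftot)
      beta <- sqrt(q$var_frac * Tvar /
                     apply(g[, q$marker, drop = FALSE], 2, var))
      data.frame(marker = q$marker, trait = q$trait,
                 effect_WW = beta,
                 effect_WL = ifelse(q$kind == "main", beta,
                                    ifelse(q$kind == "plastic", 0, -beta)))
    }))
    QTLRegistry(entries)
  })
}

#' Simulate replicate-level two-environment phenotypes
#'
#' Forward model, per line i, environment j and replicate k:
#' \deqn{y_{ijk} = \mu_t + \sum_q \beta_q(j)\, g_{iq} + u_i + E_j +
#'   \epsilon_{ijk}}
#' with polygenic line effect \eqn{u_i \sim N(0, \sigma^2_{poly})},
#' environment shift \eqn{E_j = \pm} \code{env_effect}/2 (+ for WW,
#' - for WL) and iid residual
#' \eqn{\epsilon \sim N(0, \sigma^2_{resid})}.  Missing genotype calls
#' contribute through their marker-mean imputation.  Deterministic given
#' the seed.
#'
#' @param panel a [GenotypePanel-class].
#' @param registry a [QTLRegistry-class] (may be empty); every entry's
#'   marker must exist in the panel.
#' @param config a [simConfig()].
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return Long-format data.frame with columns \code{genotype},
#'   \code{trait}, \code{env} (\code{"WW"}/\code{"WL"}), \code{rep},
#'   \code{value}.
#' @export
simulatePhenotypes <- function(panel, registry, config,
                               seed = config$seed) {
  stopifnot(is(panel, "GenotypePanel"), is(registry, "QTLRegistry"),
            inherits(config, "SimConfig"))
  ent <- qtlEntries(registry)
  if (nrow(ent) && !all(ent$marker %in% colnames(genoMatrix(panel))))
    stop("registry references a marker absent from the panel")
  withSeed(seed, {
    g <- imputedMatrix(panel)
    lines <- rownames(g)
    nl <- length(lines)
    envs <- c(WW = config$env_effect / 2, WL = -config$env_effect / 2)
    out <- vector("list", length(config$traits))
    for (ti in seq_along(config$traits)) {
      trait <- names(config$traits)[ti]
      mu <- config$traits[[ti]]
      poly <- rnorm(nl, 0, sqrt(config$sigma2_poly))
      qt <- ent[ent$trait == trait, , drop = FALSE]
      qeff <- list(WW = 0, WL = 0)
      if (nrow(qt)) {
        G <- g[, qt$marker, drop = FALSE]
        qeff$WW <- drop(G %*% qt$effect_WW)
        qeff$WL <- drop(G %*% qt$effect_WL)
      }
      recs <- lapply(names(envs), function(e) {
        base <- mu + envs[[e]] + poly + qeff[[e]]
        do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
          data.frame(genotype = lines, trait = trait, env = e, rep = r,
                     value = base + rnorm(nl, 0, sqrt(config$sigma2_resid)))
        }))
      })
      out[[ti]] <- do.call(rbind, recs)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
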