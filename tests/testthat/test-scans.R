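# Association scans: oracle equivalences, recovery, determinism,
# significance calling.

scanFixture <- function(seed, n_families = 3, lines_per_family = 30,
                        markers_per_chromosome = 30, n_chromosomes = 3,
                        qtl_frac = NULL, kind = "main") {
  cfg <- simConfig(n_families = n_families,
                   lines_per_family = lines_per_family,
                   n_chromosomes = n_chromosomes,
                   markers_per_chromosome = markers_per_chromosome,
                   sigma2_poly = 0.3, sigma2_resid = 0.7,
                   n_replicates = 2, seed = seed)
  panel <- simulateGenotypes(cfg)
  if (is.null(qtl_frac)) {
    reg <- QTLRegistry(data.frame(marker = character(),
                                  trait = character(),
                                  effect_WW = numeric(),
                                  effect_WL = numeric()))
  } else {
    reg <- plantQTLs(panel, data.frame(kind = kind, trait = "GY",
                                       var_frac = qtl_frac), cfg)
  }
  ph <- simulatePhenotypes(panel, reg, cfg)
  em <- envMeans(ph)
  list(cfg = cfg, panel = panel, registry = reg, pheno = ph,
       y_ww = setNames(em$WW, em$genotype),
       y_wl = setNames(em$WL, em$genotype))
}

test_that("mlmScan with identity kinship equals the OLS oracle", {
  fx <- scanFixture(61)
  y <- fx$y_ww
  K <- diag(length(y))
  dimnames(K) <- list(names(y), names(y))
  sc <- mlmScan(fx$panel, y, K = K)
  g <- imputedMatrix(fx$panel)
  for (j in sample(ncol(g), 12)) {
    ols <- summary(lm(y ~ g[names(y), j]))$coefficients
    expect_equal(sc$p_value[j], ols[2, 4], tolerance = 1e-8)
    expect_equal(sc$score[j], ols[2, 1], tolerance = 1e-8)
  }
})

test_that("a strong planted QTL is the top mixed-model hit", {
  hits <- vapply(1:5, function(s) {
    fx <- scanFixture(700 + s, qtl_frac = 0.25)
    qc <- markerQC(fx$panel)
    sc <- mlmScan(qc$panel, fx$y_ww, kinshipMatrix(qc$panel))
    top <- sc$marker[which.min(sc$p_value)]
    causal <- qtlEntries(fx$registry)$marker
    g <- imputedMatrix(fx$panel)
    causal %in% colnames(genoMatrix(qc$panel)) &&
      (top == causal ||
         suppressWarnings(cor(g[, top], g[, causal]))^2 >= 0.8)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("multilocus scan degenerates to the single-marker scan", {
  fx <- scanFixture(63)
  # entry threshold no marker can pass: zero pseudo-QTNs
  ml <- multilocusScan(fx$panel, fx$y_ww, entry_alpha = 1e-12)
  expect_length(attr(ml, "meta")$pseudo_qtns, 0)
  g <- imputedMatrix(fx$panel)
  y <- fx$y_ww
  ols <- summary(lm(y ~ g[names(y), 5]))$coefficients
  expect_equal(ml$p_value[5], ols[2, 4], tolerance = 1e-10)
})

test_that("multilocus scan recovers two unlinked QTLs", {
  hits <- vapply(1:5, function(s) {
    cfg <- simConfig(n_families = 3, lines_per_family = 40,
                     n_chromosomes = 3, markers_per_chromosome = 30,
                     sigma2_poly = 0.3, sigma2_resid = 0.7,
                     n_replicates = 2, seed = 800 + s)
    panel <- simulateGenotypes(cfg)
    map <- markerMap(panel)
    # pin the two QTLs to different chromosomes (unlinked)
    m1 <- map$marker[map$chrom == "1H"][15]
    m2 <- map$marker[map$chrom == "2H"][15]
    reg <- plantQTLs(panel, data.frame(kind = "main", trait = "GY",
                                       var_frac = 0.15,
                                       marker = c(m1, m2)), cfg)
    ph <- simulatePhenotypes(panel, reg, cfg)
    em <- envMeans(ph)
    y <- setNames(em$WW, em$genotype)
    ml <- callSignificant(multilocusScan(panel, y), "bh_fdr", 0.05)
    g <- imputedMatrix(panel)
    found <- vapply(c(m1, m2), function(mq) {
      sig <- ml$marker[ml$significant]
      any(vapply(sig, function(ms)
        suppressWarnings(cor(g[, ms], g[, mq]))^2 >= 0.8, logical(1)))
    }, logical(1))
    all(found)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("multilocus null family-wise error is controlled", {
  fp <- vapply(1:10, function(s) {
    fx <- scanFixture(900 + s)
    ml <- callSignificant(multilocusScan(fx$panel, fx$y_ww),
                          "bonferroni", 0.05)
    any(ml$significant)
  }, logical(1))
  expect_lte(mean(fp), 0.2)
})

test_that("importance scans are deterministic and rank a planted QTL first", {
  fx <- scanFixture(65, qtl_frac = 0.3)
  causal <- qtlEntries(fx$registry)$marker
  for (lrn in c("RF", "GB")) {
    s1 <- mlImportanceScan(fx$panel, fx$y_ww, lrn,
                           n_permutations = 10, seed = 5,
                           num_trees = 150, nrounds = 60)
    s2 <- mlImportanceScan(fx$panel, fx$y_ww, lrn,
                           n_permutations = 10, seed = 5,
                           num_trees = 150, nrounds = 60)
    expect_identical(s1$score, s2$score)
    expect_identical(s1$p_value, s2$p_value)
    top <- s1$marker[which.max(s1$score)]
    g <- imputedMatrix(fx$panel)
    expect_gte(suppressWarnings(cor(g[, top], g[, causal]))^2, 0.8)
  }
  expect_error(mlImportanceScan(fx$panel,
                                setNames(rep(1, nLines(fx$panel)),
                                         rownames(genoMatrix(fx$panel))),
                                "RF", n_permutations = 10, seed = 1),
               "constant")
})

test_that("empirical p-values are valid under the null", {
  # max-null construction is conservative: fraction of markers at
  # p <= 0.05 stays below 0.05 + Monte-Carlo tolerance
  fx <- scanFixture(66, lines_per_family = 20,
                    markers_per_chromosome = 15)
  rates <- vapply(c("RF", "GB"), function(lrn) {
    sc <- mlImportanceScan(fx$panel, fx$y_ww, lrn,
                           n_permutations = 60, seed = 7,
                           num_trees = 120, nrounds = 50)
    mean(sc$p_value <= 0.05)
  }, numeric(1))
  expect_true(all(rates <= 0.05 + 0.05))
})

test_that("callSignificant implements its three procedures", {
  df <- data.frame(marker = paste0("m", 1:4), chrom = "1H", pos = 1:4,
                   score = 1, se = 1,
                   p_value = c(0.001, 0.01, 0.02, 0.8),
                   significant = NA)
  # brute-force BH step-up oracle
  bh_oracle <- function(p, a) {
    o <- order(p); m <- length(p)
    passed <- which(p[o] <= a * seq_len(m) / m)
    out <- rep(FALSE, m)
    if (length(passed)) out[o[seq_len(max(passed))]] <- TRUE
    out
  }
  bh <- callSignificant(df, "bh_fdr", 0.05)
  expect_identical(bh$significant, bh_oracle(df$p_value, 0.05))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(50)^2
    d2 <- data.frame(marker = paste0("m", 1:50), chrom = "1H",
                     pos = 1:50, score = 1, se = 1, p_value = p,
                     significant = NA)
    expect_identical(callSignificant(d2, "bh_fdr", 0.1)$significant,
                     bh_oracle(p, 0.1))
  }

  bon <- callSignificant(df, "bonferroni", 0.05)
  expect_identical(bon$significant, df$p_value <= 0.05 / 4)
  emp <- callSignificant(df, "empirical", 0.05)
  expect_identical(emp$significant, df$p_value <= 0.05)
  allone <- df; allone$p_value <- 1
  expect_false(any(callSignificant(allone, "bh_fdr", 0.05)$significant))
  expect_error(callSignificant(df, "magic"), "arg")
})

test_that("scan outputs are invariant to marker order", {
  fx <- scanFixture(67)
  panel <- fx$panel
  g <- genoMatrix(panel)
  map <- markerMap(panel)
  ord <- order(match(map$chrom, c("2H", "3H", "1H")))
  shuf <- GenotypePanel(g[, ord], map[ord, ], lineFamilies(panel))
  K <- kinshipMatrix(panel)
  sc1 <- mlmScan(panel, fx$y_ww, K)
  sc2 <- mlmScan(shuf, fx$y_ww, K)
  m <- match(sc1$marker, sc2$marker)
  expect_equal(sc1$p_value, sc2$p_value[m], tolerance = 1e-10)
  expect_error(mlmScan(panel, fx$y_ww[-1][seq_len(nLines(panel) - 5)], K),
               NA)
  expect_error(mlmScan(panel, unname(fx$y_ww[1:5])), "length")
})
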