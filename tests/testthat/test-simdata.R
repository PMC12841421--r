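# Synthetic panel / phenotype generator contracts.

test_that("simulateGenotypes honours the construction contract", {
  cfg <- simConfig(n_families = 2, lines_per_family = 10,
                   n_chromosomes = 7, markers_per_chromosome = 100,
                   missing_rate = 0, seed = 11)
  panel <- simulateGenotypes(cfg)
  g <- genoMatrix(panel)
  expect_equal(dim(g), c(20L, 700L))
  expect_true(all(g %in% c(0, 2)))
  map <- markerMap(panel)
  expect_true(all(vapply(split(map$pos, map$chrom),
                         function(p) all(diff(p) > 0), logical(1))))
  expect_equal(length(unique(lineFamilies(panel))), 2L)
})

test_that("generation is deterministic given config and seed", {
  cfg <- smallConfig(seed = 5, missing_rate = 0.05)
  p1 <- simulateGenotypes(cfg)
  p2 <- simulateGenotypes(cfg)
  expect_identical(genoMatrix(p1), genoMatrix(p2))
  expect_identical(markerMap(p1), markerMap(p2))
  q1 <- plantQTLs(p1, data.frame(kind = "main", trait = "GY",
                                 var_frac = 0.1), cfg)
  q2 <- plantQTLs(p2, data.frame(kind = "main", trait = "GY",
                                 var_frac = 0.1), cfg)
  expect_identical(qtlEntries(q1), qtlEntries(q2))
  ph1 <- simulatePhenotypes(p1, q1, cfg)
  ph2 <- simulatePhenotypes(p2, q2, cfg)
  expect_identical(ph1, ph2)
})

test_that("zero recombination gives complete within-family LD", {
  cfg <- smallConfig(seed = 3, recombination_rate = 0,
                     lines_per_family = 12)
  panel <- simulateGenotypes(cfg)
  g <- genoMatrix(panel)
  map <- markerMap(panel)
  fams <- lineFamilies(panel)
  for (f in unique(fams)) {
    gf <- g[fams == f, , drop = FALSE]
    for (ch in unique(map$chrom)) {
      gc <- gf[, map$chrom == ch, drop = FALSE]
      poly <- apply(gc, 2, var) > 0
      if (sum(poly) < 2) next
      r2 <- suppressWarnings(cor(gc[, poly]))^2
      expect_true(all(abs(r2 - 1) < 1e-12))
    }
  }
})

test_that("segregating markers are founder-balanced within families", {
  cfg <- simConfig(n_families = 4, lines_per_family = 40,
                   n_chromosomes = 5, markers_per_chromosome = 40,
                   seed = 17)
  panel <- simulateGenotypes(cfg)
  g <- genoMatrix(panel)
  fams <- lineFamilies(panel)
  freqs <- unlist(lapply(unique(fams), function(f) {
    gf <- g[fams == f, , drop = FALSE]
    p <- colMeans(gf) / 2
    p[p > 0 & p < 1]
  }))
  expect_gt(length(freqs), 100)
  # mean allele frequency 0.5 up to Monte-Carlo error
  expect_lt(abs(mean(freqs) - 0.5), 3 * sd(freqs) / sqrt(length(freqs)) + 0.02)
})

test_that("plantQTLs enforces kinds, preconditions and variance targets", {
  cfg <- smallConfig(seed = 7)
  panel <- simulateGenotypes(cfg)
  reg <- plantQTLs(panel, data.frame(kind = c("main", "antagonistic"),
                                     trait = "GY",
                                     var_frac = c(0.1, 0.1)), cfg)
  e <- qtlEntries(reg)
  expect_equal(nrow(e), 2L)
  expect_false(e$antagonistic[e$effect_WW == e$effect_WL])
  ant <- e[e$antagonistic, ]
  expect_true(sign(ant$effect_WW) != sign(ant$effect_WL))

  tiny <- smallConfig(seed = 8, n_chromosomes = 1,
                      markers_per_chromosome = 10)
  tiny_panel <- simulateGenotypes(tiny)
  expect_error(plantQTLs(tiny_panel,
                         data.frame(kind = rep("main", 50), trait = "GY",
                                    var_frac = 0.01), tiny),
               "more QTLs")
})

test_that("realized single-locus variance fraction matches its target", {
  # brute force on the simulated output: Var(genotype column x effect)
  # over total WW phenotypic variance
  fracs <- vapply(1:5, function(s) {
    cfg <- simConfig(n_families = 4, lines_per_family = 50,
                     n_chromosomes = 3, markers_per_chromosome = 30,
                     sigma2_poly = 0.5, sigma2_resid = 0.5,
                     n_replicates = 2, seed = 100 + s)
    panel <- simulateGenotypes(cfg)
    reg <- plantQTLs(panel, data.frame(kind = "main", trait = "GY",
                                       var_frac = 0.10), cfg)
    ph <- simulatePhenotypes(panel, reg, cfg)
    e <- qtlEntries(reg)
    gcol <- genoMatrix(panel)[, e$marker]
    ww <- ph[ph$env == "WW", ]
    var(gcol[ww$genotype] * e$effect_WW) / var(ww$value)
  }, numeric(1))
  expect_true(all(abs(fracs - 0.10) < 0.03))
})

test_that("degenerate phenotype model is exactly mu + env shift", {
  cfg <- smallConfig(seed = 2, sigma2_poly = 0, sigma2_resid = 0,
                     env_effect = 5, traits = c(GY = 10))
  panel <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(panel, QTLRegistry(data.frame(
    marker = character(), trait = character(), effect_WW = numeric(),
    effect_WL = numeric())), cfg)
  expect_true(all(ph$value[ph$env == "WW"] == 12.5))
  expect_true(all(ph$value[ph$env == "WL"] == 7.5))
})

test_that("environment shift is recovered in the simulated means", {
  cfg <- simConfig(n_families = 4, lines_per_family = 50,
                   env_effect = 5, sigma2_poly = 1, sigma2_resid = 1,
                   n_chromosomes = 2, markers_per_chromosome = 10,
                   n_replicates = 2, seed = 21)
  panel <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(panel, QTLRegistry(data.frame(
    marker = character(), trait = character(), effect_WW = numeric(),
    effect_WL = numeric())), cfg)
  dbar <- mean(ph$value[ph$env == "WW"]) - mean(ph$value[ph$env == "WL"])
  n <- sum(ph$env == "WW")
  se <- sqrt(2 * (1 + 1) / n)
  expect_lt(abs(dbar - 5), 3 * se)
})

test_that("planted genotype variance is recovered by an ANOVA oracle", {
  # independent one-way ANOVA estimate of the genotypic variance
  # fraction within one environment
  props <- vapply(1:20, function(s) {
    cfg <- configForProportions(0.5, 0.3, 0.2,
                                n_families = 4, lines_per_family = 50,
                                n_chromosomes = 2,
                                markers_per_chromosome = 10,
                                n_replicates = 2, seed = 200 + s)
    panel <- simulateGenotypes(cfg)
    ph <- simulatePhenotypes(panel, QTLRegistry(data.frame(
      marker = character(), trait = character(), effect_WW = numeric(),
      effect_WL = numeric())), cfg)
    ww <- ph[ph$env == "WW", ]
    fit <- aov(value ~ genotype, ww)
    ms <- summary(fit)[[1]]$`Mean Sq`
    r <- cfg$n_replicates
    vg <- max(0, (ms[1] - ms[2]) / r)
    vg / (vg + ms[2])   # genotype fraction within one environment
  }, numeric(1))
  # within one environment the env component drops out: planted
  # fraction is 0.5 / (0.5 + 0.2)
  expect_lt(abs(mean(props) - 0.5 / 0.7), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(n_families = 0, seed = 1), "n_families")
  expect_error(simConfig(missing_rate = 1, seed = 1), "missing_rate")
  expect_error(simConfig(recombination_rate = -1, seed = 1),
               "recombination_rate")
  expect_error(simulatePhenotypes(
    smallPanel(1),
    QTLRegistry(data.frame(marker = "nope", trait = "GY",
                           effect_WW = 1, effect_WL = 1)),
    smallConfig(1)), "absent")
})
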