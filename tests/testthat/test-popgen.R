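# Marker QC, kinship, PCA, LD decay.

test_that("markerQC removes high-missing, monomorphic and duplicate markers", {
  panel <- smallPanel(seed = 41, lines_per_family = 20)
  g <- genoMatrix(panel)
  map <- markerMap(panel)
  # corrupt: marker 1 gets 15% missing, marker 2 made monomorphic,
  # marker 4 duplicated into marker 5
  g[1:6, 1] <- NA           # 6/40 = 15% missing
  g[, 2] <- 2
  g[, 5] <- g[, 4]
  dirty <- GenotypePanel(g, map, lineFamilies(panel))
  qc <- markerQC(dirty, max_missing = 0.10)
  rep_ <- qc$report
  expect_gte(rep_$n_removed_missing, 1L)
  expect_gte(rep_$n_removed_monomorphic, 1L)
  expect_gte(rep_$n_removed_duplicate_ld, 1L)
  kept <- colnames(genoMatrix(qc$panel))
  expect_false(map$marker[1] %in% kept)
  expect_false(map$marker[2] %in% kept)
  # of the duplicated pair the first in map order is kept
  expect_true(map$marker[4] %in% kept)
  expect_false(map$marker[5] %in% kept)
  expect_equal(rep_$n_input,
               rep_$n_retained + rep_$n_removed_missing +
                 rep_$n_removed_monomorphic + rep_$n_removed_duplicate_ld)

  # clean panel passes through unchanged
  clean <- smallPanel(seed = 42, recombination_rate = 5)
  qc2 <- markerQC(clean)
  if (qc2$report$n_removed_duplicate_ld == 0 &&
      qc2$report$n_removed_monomorphic == 0)
    expect_identical(genoMatrix(qc2$panel), genoMatrix(clean))
})

test_that("markerQC is idempotent", {
  panel <- smallPanel(seed = 43, missing_rate = 0.08)
  qc1 <- markerQC(panel)
  qc2 <- markerQC(qc1$panel)
  expect_identical(genoMatrix(qc2$panel), genoMatrix(qc1$panel))
  expect_equal(qc2$report$n_removed_missing, 0L)
  expect_equal(qc2$report$n_removed_duplicate_ld, 0L)
})

test_that("kinship matches the VanRaden brute force and is PSD", {
  panel <- toyPanel()
  K <- kinshipMatrix(panel)
  # independent brute force of the formula
  g <- genoMatrix(panel)
  p <- colMeans(g) / 2
  W <- sweep(g, 2, 2 * p)
  K_oracle <- W %*% t(W) / (2 * sum(p * (1 - p)))
  expect_equal(K, K_oracle, tolerance = 1e-12)
  expect_equal(K, t(K))

  # duplicate lines have identical rows/diagonals
  g2 <- rbind(g, L4 = g["L1", ])
  map <- markerMap(panel)
  dup <- GenotypePanel(g2, map, "F01")
  K2 <- kinshipMatrix(dup)
  expect_equal(K2["L1", "L4"], K2["L1", "L1"])
  expect_equal(K2["L4", "L4"], K2["L1", "L1"])

  big <- smallPanel(seed = 44)
  Kb <- kinshipMatrix(big)
  expect_gte(min(eigen(Kb, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)

  mono <- GenotypePanel(matrix(2, 3, 2,
                               dimnames = list(paste0("L", 1:3),
                                               c("m1", "m2"))),
                        data.frame(marker = c("m1", "m2"), chrom = "1H",
                                   pos = c(1, 2)), "F01")
  expect_error(kinshipMatrix(mono), "monomorphic")
})

test_that("PCA separates divergent families and matches the eigen oracle", {
  # construct two families with divergent founder allele frequencies
  set.seed(45)
  m <- 200; nl <- 15
  gA <- matrix(2 * rbinom(nl * m, 1, 0.15), nl, m)
  gB <- matrix(2 * rbinom(nl * m, 1, 0.85), nl, m)
  g0 <- rbind(gA, gB)
  dimnames(g0) <- list(sprintf("L%02d", 1:(2 * nl)),
                       sprintf("m%03d", 1:m))
  panel <- GenotypePanel(g0,
                         data.frame(marker = colnames(g0), chrom = "1H",
                                    pos = seq_len(m) * 100),
                         setNames(rep(c("F01", "F02"), each = nl),
                                  rownames(g0)))
  pc <- panelPCA(panel, 4)
  expect_true(all(diff(pc$var_pct) <= 1e-9))
  expect_lte(sum(pc$var_pct), 100 + 1e-9)

  # oracle: eigendecomposition of the covariance matrix
  g <- imputedMatrix(panel)
  gc <- scale(g, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(gc) / (nrow(gc) - 1), symmetric = TRUE)
  sc_oracle <- gc %*% ev$vectors[, 1:4]
  for (j in 1:4)
    expect_equal(abs(cor(pc$scores[, j], sc_oracle[, j])), 1,
                 tolerance = 1e-6)

  fams <- lineFamilies(panel)
  gap <- abs(mean(pc$scores[fams == "F01", 1]) -
               mean(pc$scores[fams == "F02", 1]))
  within_sd <- mean(c(sd(pc$scores[fams == "F01", 1]),
                      sd(pc$scores[fams == "F02", 1])))
  expect_gt(gap, within_sd)

  # identical lines: no variance anywhere
  flat <- GenotypePanel(matrix(2, 4, 3,
                               dimnames = list(paste0("L", 1:4),
                                               paste0("m", 1:3))),
                        data.frame(marker = paste0("m", 1:3),
                                   chrom = "1H", pos = 1:3), "F01")
  pcf <- suppressWarnings(panelPCA(flat, 2))
  expect_true(all(pcf$var_pct == 0))
})

test_that("ldDecay matches direct correlations and decays with distance", {
  # brute-force oracle on a 5-marker toy
  set.seed(46)
  g <- matrix(sample(c(0, 2), 5 * 30, replace = TRUE), 30, 5,
              dimnames = list(sprintf("L%02d", 1:30),
                              paste0("m", 1:5)))
  map <- data.frame(marker = paste0("m", 1:5), chrom = "1H",
                    pos = c(10, 20, 30, 40, 50))
  toy <- GenotypePanel(g, map, "F01")
  curve <- ldDecay(toy, max_distance = 100, bin_width = 100)
  r2s <- cor(g)[upper.tri(diag(5))]^2
  expect_equal(curve$mean_r2, mean(r2s), tolerance = 1e-12)
  expect_equal(curve$n_pairs, 10L)

  # duplicated adjacent marker gives r2 = 1 in the first bin
  g2 <- cbind(g, m6 = g[, 5])
  map2 <- rbind(map, data.frame(marker = "m6", chrom = "1H", pos = 51))
  curve2 <- ldDecay(GenotypePanel(g2, map2, "F01"),
                    max_distance = 5, bin_width = 5)
  expect_equal(curve2$mean_r2[1], 1)

  # independent markers: mean r2 near the 1/(n-1) sampling floor
  set.seed(47)
  n <- 60
  gi <- matrix(sample(c(0, 2), n * 40, replace = TRUE), n, 40,
               dimnames = list(sprintf("L%02d", 1:n),
                               sprintf("m%02d", 1:40)))
  mapi <- data.frame(marker = sprintf("m%02d", 1:40), chrom = "1H",
                     pos = (1:40) * 1000)
  ci <- ldDecay(GenotypePanel(gi, mapi, "F01"),
                max_distance = 4e4, bin_width = 4e4)
  expect_lt(abs(ci$mean_r2 - 1 / (n - 1)), 0.01)

  # simulated panel with recombination: mean r2 non-increasing over
  # distance (one bin violation allowed at Monte-Carlo noise level)
  panel <- simulateGenotypes(simConfig(
    n_families = 3, lines_per_family = 30, n_chromosomes = 3,
    markers_per_chromosome = 40, recombination_rate = 2, seed = 48))
  cd <- ldDecay(panel, max_distance = 3e8, bin_width = 5e7)
  viol <- sum(diff(cd$mean_r2) > 0.02)
  expect_lte(viol, 1)

  expect_warning(ldDecay(toy, max_distance = 1), "no eligible")
})

test_that("kinship and PCA are invariant to marker order", {
  panel <- smallPanel(seed = 49)
  g <- genoMatrix(panel)
  map <- markerMap(panel)
  # reorder chromosomes blockwise (keeps within-chromosome order valid)
  ord <- order(match(map$chrom, c("3H", "1H", "2H")))
  shuf <- GenotypePanel(g[, ord], map[ord, ], lineFamilies(panel))
  expect_equal(kinshipMatrix(shuf), kinshipMatrix(panel),
               tolerance = 1e-12)
  p1 <- panelPCA(panel, 3)$var_pct
  p2 <- panelPCA(shuf, 3)$var_pct
  expect_equal(p1, p2, tolerance = 1e-9)
})
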