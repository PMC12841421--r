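# Shared fixture builders; everything is generated in code at test time.

smallConfig <- function(seed, n_families = 2, lines_per_family = 10,
                        n_chromosomes = 3, markers_per_chromosome = 20,
                        ...) {
  simConfig(n_families = n_families, lines_per_family = lines_per_family,
            n_chromosomes = n_chromosomes,
            markers_per_chromosome = markers_per_chromosome,
            seed = seed, ...)
}

smallPanel <- function(seed = 1, ...) simulateGenotypes(smallConfig(seed, ...))

# hand-built 3-line x 4-marker panel for closed-form oracles
toyPanel <- function() {
  g <- matrix(c(0, 2, 2,
                2, 0, 2,
                0, 0, 2,
                2, 2, 0), nrow = 3,
              dimnames = list(c("L1", "L2", "L3"),
                              c("m1", "m2", "m3", "m4")))
  map <- data.frame(marker = colnames(g), chrom = "1H",
                    pos = c(100, 200, 300, 400))
  GenotypePanel(g, map, families = "F01")
}

# random call set over a marker universe, for set-algebra oracles
randomCalls <- function(markers, methods, estimators, trait = "T1",
                        p = 0.3) {
  combos <- expand.grid(method = methods, estimator = estimators,
                        stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- markers[runif(length(markers)) < p]
    if (!length(sel)) return(NULL)
    data.frame(method = combos$method[i], trait = trait,
               estimator = combos$estimator[i], marker = sel)
  }))
}

# exact two-sided signed-rank p by enumeration over all 2^n sign
# assignments (independent oracle, n small)
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  pl <- mean(v_all <= v_obs)
  pu <- mean(v_all >= v_obs)
  min(1, 2 * min(pl, pu))
}
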