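## Convenience driver: run every (method x estimator) scan for a trait
## and collect significant calls for the consensus stage.

#' Run the full scan suite for one trait
#'
#' Runs the four scan families over each requested plasticity
#' estimator, applies significance calling (Benjamini-Hochberg FDR for
#' the model-based scans, direct empirical alpha for the permutation
#' scans) and returns the per-scan results together with the pooled
#' call set.
#'
#' @param panel a QC'd [GenotypePanel-class].
#' @param plasticity a [plasticityTable()] data.frame.
#' @param trait trait to scan.
#' @param methods subset of \code{c("MLM", "MULTILOCUS", "RF", "GB")}.
#' @param estimators subset of the five estimators used as responses.
#' @param K kinship matrix for the mixed-model scan; left NULL the scan
#'   uses its leave-one-chromosome-out default.
#' @param alpha significance level for every procedure.
#' @param n_permutations permutations for the tree-ensemble scans.
#' @param seed integer seed for the tree-ensemble scans.
#' @param num_trees,nrounds passed to [mlImportanceScan()].
#' @return list with \code{results} (named list of scan results) and
#'   \code{calls} ([collectCalls()] data.frame).
#' @export
runScanSuite <- function(panel, plasticity, trait,
                         methods = c("MLM", "MULTILOCUS", "RF", "GB"),
                         estimators = c("WW", "WL", "Ratio", "RDPI",
                                        "Linear"),
                         K = NULL, alpha = 0.05, n_permutations = 100,
                         seed = 1, num_trees = 300, nrounds = 100) {
  stopifnot(all(methods %in% c("MLM", "MULTILOCUS", "RF", "GB")))
  pl <- plasticity[plasticity$trait == trait, , drop = FALSE]
  if (!nrow(pl)) stop("no plasticity rows for trait ", trait)
  results <- list()
  for (est in estimators) {
    y <- setNames(pl[[est]], pl$genotype)
    for (m in methods) {
      r <- switch(m,
        MLM = callSignificant(
          mlmScan(panel, y, K = K, trait = trait, estimator = est),
          "bh_fdr", alpha),
        MULTILOCUS = callSignificant(
          multilocusScan(panel, y, trait = trait, estimator = est),
          "bh_fdr", alpha),
        RF = callSignificant(
          mlImportanceScan(panel, y, "RF",
                           n_permutations = n_permutations,
                           seed = seed, trait = trait,
                           estimator = est, num_trees = num_trees),
          "empirical", alpha),
        GB = callSignificant(
          mlImportanceScan(panel, y, "GB",
                           n_permutations = n_permutations,
                           seed = seed, trait = trait,
                           estimator = est, nrounds = nrounds),
          "empirical", alpha))
      results[[paste(m, est, sep = ".")]] <- r
    }
  }
  list(results = results, calls = collectCalls(results))
}
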