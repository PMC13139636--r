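#' Iterative collinearity pre-filter
#'
#' While any variable pair has `|Spearman rho| > r_max`, the member of the
#' worst (largest `|rho|`) pair with the larger mean absolute correlation to
#' all other variables is dropped (ties to the later column). Deterministic.
#'
#' @param variables samples x variables numeric matrix or data.frame.
#' @param r_max absolute Spearman correlation threshold.
#' @return character vector of retained variable names.
#' @export
collinearity_filter <- function(variables, r_max = 0.6) {
  x <- as.matrix(variables)
  if (ncol(x) < 2) return(colnames(x))
  keep <- colnames(x)
  repeat {
    if (length(keep) < 2) break
    r <- abs(stats::cor(x[, keep, drop = FALSE], method = "spearman"))
    diag(r) <- 0
    if (max(r) <= r_max) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    mean_abs <- (rowSums(r) / (length(keep) - 1))[worst]
    drop_at <- if (mean_abs[1] > mean_abs[2]) worst[1]
               else if (mean_abs[2] > mean_abs[1]) worst[2]
               else max(worst)              # tie -> later column
    keep <- keep[-drop_at]
  }
  keep
}

#' Redundancy analysis of community composition on host variables
#'
#' Hellinger-transforms the community table (square root of relative
#' abundances, the standard pre-transform for species data), fits an RDA on
#' the explanatory matrix via `vegan::rda`, and tests the global model and
#' each marginal term with seeded permutation tests. Factor columns (e.g. the
#' enterotype label) are dummy-coded by the underlying model matrix.
#'
#' @param community samples x taxa abundance matrix.
#' @param explanatory samples x variables data.frame (numeric and/or factor).
#' @param n_perm permutations for the significance tests.
#' @param seed integer seed.
#' @param hellinger apply the Hellinger pre-transform (default) or use the
#'   community matrix as given.
#' @return object of class `rda_result`: `F`, `p` (global),
#'   `constrained_fraction`, `unconstrained_fraction`, `terms` data.frame
#'   (marginal F/p per variable), `biplot` scores and the vegan fit.
#' @export
rda_fit <- function(community, explanatory, n_perm = 999, seed = 1L,
                    hellinger = TRUE) {
  explanatory <- as.data.frame(explanatory)
  if (nrow(explanatory) != nrow(community))
    stop("community and explanatory row counts differ")
  if (nrow(community) <= ncol(explanatory) + 1)
    stop("need n_samples > n_variables + 1")
  y <- if (hellinger) vegan::decostand(community, method = "hellinger")
       else as.matrix(community)
  fit <- vegan::rda(y ~ ., data = explanatory)
  if (is.null(fit$CCA) || fit$CCA$rank == 0)
    stop("explanatory matrix is rank-deficient after filtering")
  global <- with_seed_(seed, vegan::anova.cca(fit, permutations = n_perm))
  marginal <- with_seed_(stage_seed(seed, "margin"),
                         vegan::anova.cca(fit, by = "margin",
                                          permutations = n_perm))
  tot <- fit$tot.chi
  structure(list(F = global$F[1], p = global$`Pr(>F)`[1],
                 constrained_fraction = fit$CCA$tot.chi / tot,
                 unconstrained_fraction = fit$CA$tot.chi / tot,
                 terms = data.frame(term = rownames(marginal)[-nrow(marginal)],
                                    F = marginal$F[-nrow(marginal)],
                                    p = marginal$`Pr(>F)`[-nrow(marginal)],
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 biplot = vegan::scores(fit, display = "bp",
                                        choices = seq_len(min(2, fit$CCA$rank))),
                 fit = fit),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA: global F = %.3f, p = %.4g; constrained %.1f%% of inertia\n",
              x$F, x$p, 100 * x$constrained_fraction))
  print(x$terms, row.names = FALSE)
  invisible(x)
}
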