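#' Fit Sloan's neutral community model
#'
#' Fits the observed occurrence frequency of each taxon against its mean
#' relative abundance under the neutral expectation
#' `freq(p) = 1 - BetaCDF(d; N m p, N m (1 - p))`, with `N` the mean reads
#' per sample and detection limit `d = 1/N` (one read). The migration
#' parameter `m` is estimated by bounded least squares on the untransformed
#' frequency scale; `R^2 = 1 - SSE/SST` may be negative for gross misfit and
#' is reported as-is. Each taxon is partitioned against the 95% (Wilson)
#' band around its predicted frequency at the realised number of samples.
#'
#' @param ct samples x taxa count matrix (>= 10 samples).
#' @param ci confidence level of the partition band.
#' @return object of class `ncm_fit`: `m`, `N`, `Nm`, `r2` and a `taxa`
#'   data.frame (`taxon`, `mean_relabund`, `occ_freq`, `predicted_freq`,
#'   `ci_low`, `ci_high`, `partition`).
#' @export
fit_ncm <- function(ct, ci = 0.95) {
  validate_count_table(ct)
  if (nrow(ct) < 10) stop("need at least 10 samples to fit the neutral model")
  N <- mean(rowSums(ct))
  p <- colMeans(to_relative(ct))
  occ <- colMeans(ct > 0)
  keep <- p > 0
  p <- p[keep]; occ <- occ[keep]
  d <- 1 / N
  pred_fun <- function(m) stats::pbeta(d, N * m * p, N * m * (1 - p),
                                       lower.tail = FALSE)
  sse <- function(m) sum((occ - pred_fun(m))^2)
  opt <- stats::optimize(sse, interval = c(1e-6, 1), tol = 1e-8)
  m_hat <- opt$minimum
  pred <- pred_fun(m_hat)
  sst <- sum((occ - mean(occ))^2)
  if (sst <= 0) stop("degenerate occurrence frequencies (no variation)")
  r2 <- 1 - opt$objective / sst
  band <- wilson_band_(pred, nrow(ct), ci)
  partition <- ifelse(occ > band$high, "above",
                      ifelse(occ < band$low, "below", "within"))
  structure(list(m = m_hat, N = N, Nm = N * m_hat, r2 = r2,
                 taxa = data.frame(taxon = names(p), mean_relabund = p,
                                   occ_freq = occ, predicted_freq = pred,
                                   ci_low = band$low, ci_high = band$high,
                                   partition = partition, row.names = NULL,
                                   stringsAsFactors = FALSE)),
            class = "ncm_fit")
}

wilson_band_ <- function(phat, n, ci = 0.95) {
  z <- stats::qnorm(1 - (1 - ci) / 2)
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(centre - half, 0), high = pmin(centre + half, 1))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral community model: m = %.4f, N = %.0f, Nm = %.1f, R2 = %.3f\n",
              x$m, x$N, x$Nm, x$r2))
  cat("  partition:", paste(names(table(x$taxa$partition)),
                            table(x$taxa$partition), collapse = ", "), "\n")
  invisible(x)
}

# Patristic distances and relative-abundance matrix aligned on a canonical
# (alphabetical) taxon order shared between table and tree.
bmntd_inputs_ <- function(ct, tree) {
  taxa <- sort(colnames(ct))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("tree lacks tip(s): ", paste(utils::head(missing, 5), collapse = ", "))
  if (any(rowSums(ct) == 0)) stop("sample(s) with no taxa")
  tr <- ape::keep.tip(tree, taxa)
  D <- stats::cophenetic(tr)[taxa, taxa]
  F <- t(to_relative(ct[, taxa, drop = FALSE]))
  list(D = D, F = F, samples = rownames(ct))
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' `betaMNTD(A, B) = 0.5 (sum_i f_iA min_j d(i, j in B) + sum_j f_jB
#' min_i d(j, i in A))` with `f` the within-sample relative abundances and
#' `d` patristic distances on the tree.
#'
#' @param ct samples x taxa count matrix.
#' @param tree rooted `phylo` covering the table's taxa.
#' @param pair optional length-2 vector of sample ids/indices; when `NULL`
#'   the full samples x samples matrix is returned.
#' @return scalar (for a pair) or symmetric matrix.
#' @export
beta_mntd <- function(ct, tree, pair = NULL) {
  inp <- bmntd_inputs_(ct, tree)
  obs <- cpp_bmntd_nti(inp$D, inp$F, 0L)$obs
  dimnames(obs) <- list(inp$samples, inp$samples)
  if (is.null(pair)) obs else obs[pair[1], pair[2]]
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardised effect size of betaMNTD against a tip-shuffle null: taxon
#' labels are permuted across the tree tips `n_null` times, betaMNTD is
#' recomputed for every sample pair, and
#' `betaNTI = (obs - mean_null) / sd_null`. `|betaNTI| >= 2` flags
#' deterministic (selection) assembly. Taxa should be pre-filtered (the
#' conventional cut drops mean relative abundance < 0.01%).
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip shuffles.
#' @param seed integer seed.
#' @return list with matrices `bnti`, `obs`, `null_mean`, `null_sd`.
#' @export
beta_nti <- function(ct, tree, n_null = 999, seed = 1L) {
  inp <- bmntd_inputs_(ct, tree)
  res <- with_seed_(seed, cpp_bmntd_nti(inp$D, inp$F, as.integer(n_null)))
  degen <- res$null_sd[upper.tri(res$null_sd)] == 0
  if (all(degen))
    stop("degenerate null (sd = 0 for every pair); tree carries no usable ",
         "distance variation")
  if (any(degen))
    warning(sum(degen), " pair(s) with a degenerate null (sd = 0, e.g. ",
            "identical single-clade communities); their betaNTI is NA")
  for (nm in c("bnti", "obs", "null_mean", "null_sd"))
    dimnames(res[[nm]]) <- list(inp$samples, inp$samples)
  res
}

#' Raup-Crick index on Bray-Curtis distances
#'
#' For each sample pair, null communities preserve each sample's observed
#' richness (taxa drawn without replacement with probability proportional to
#' their occurrence frequency) and total reads (allocated proportionally to
#' metacommunity relative abundance), giving a null Bray-Curtis distribution.
#' `RC = 2 [ #(null < obs) + 0.5 #(null = obs) ] / n_null - 1`, in
#' `[-1, 1]`; `RC > 0.95` and `RC < -0.95` conventionally flag dispersal
#' limitation and homogenising dispersal.
#'
#' @param ct samples x taxa count matrix; by default the metacommunity is
#'   formed from all samples given here (pass one analysis group at a time).
#' @param pairs optional 2-column matrix of sample index pairs; default all.
#' @param n_null number of null draws.
#' @param seed integer seed.
#' @param occ_freq optional explicit per-taxon occurrence frequencies for the
#'   null draw (default: prevalence across `ct`).
#' @param metacommunity optional explicit metacommunity relative abundances
#'   (default: mean relative abundance across `ct`).
#' @return symmetric matrix (or vector aligned with `pairs` rows).
#' @export
raup_crick_bray <- function(ct, pairs = NULL, n_null = 999, seed = 1L,
                            occ_freq = NULL, metacommunity = NULL) {
  validate_count_table(ct)
  n <- nrow(ct)
  as_matrix <- is.null(pairs)
  if (is.null(pairs)) {
    iu <- which(upper.tri(diag(n)), arr.ind = TRUE)
    pairs <- iu[order(iu[, 1], iu[, 2]), , drop = FALSE]
  }
  pairs <- as.matrix(pairs)
  occ_w <- if (is.null(occ_freq)) colMeans(ct > 0) else occ_freq
  meta_p <- if (is.null(metacommunity)) colMeans(to_relative(ct))
            else metacommunity
  stopifnot(length(occ_w) == ncol(ct), length(meta_p) == ncol(ct))
  rc <- with_seed_(seed,
    cpp_rc_bray(ct * 1.0, matrix(as.integer(pairs - 1L), ncol = 2),
                as.integer(n_null), occ_w, meta_p))
  if (as_matrix) {
    out <- matrix(0, n, n, dimnames = list(rownames(ct), rownames(ct)))
    out[pairs] <- rc
    out[pairs[, c(2, 1), drop = FALSE]] <- rc
    out
  } else rc
}

#' Classify ecological assembly processes
#'
#' Five-way classification of sample pairs from (betaNTI, RCBray):
#' homogeneous selection (`betaNTI < -2`), heterogeneous selection
#' (`betaNTI > 2`), dispersal limitation (`|betaNTI| < 2` and `RC > 0.95`),
#' homogenising dispersal (`|betaNTI| < 2` and `RC < -0.95`), otherwise
#' drift/undominated. Boundary values (`betaNTI = +-2`, `RC = +-0.95`) fall
#' to drift, matching the strict inequalities of the convention.
#'
#' @param bnti numeric vector (or matrix) of betaNTI values per pair.
#' @param rc matching RCBray values.
#' @return object of class `assembly_result`: per-pair `process` and the
#'   `fractions` over the five processes (summing to one).
#' @export
classify_processes <- function(bnti, rc) {
  if (is.matrix(bnti)) bnti <- bnti[upper.tri(bnti)]
  if (is.matrix(rc)) rc <- rc[upper.tri(rc)]
  if (length(bnti) != length(rc)) stop("bnti and rc lengths differ")
  process <- ifelse(bnti < -2, "homogeneous_selection",
             ifelse(bnti > 2, "heterogeneous_selection",
             ifelse(abs(bnti) < 2 & rc > 0.95, "dispersal_limitation",
             ifelse(abs(bnti) < 2 & rc < -0.95, "homogenizing_dispersal",
                    "drift"))))
  lv <- c("homogeneous_selection", "heterogeneous_selection",
          "dispersal_limitation", "homogenizing_dispersal", "drift")
  fr <- table(factor(process, levels = lv)) / length(process)
  structure(list(process = process,
                 fractions = stats::setNames(as.numeric(fr), lv)),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("Assembly processes over", length(x$process), "pairs:\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-24s %5.1f%%\n", nm, 100 * x$fractions[nm]))
  invisible(x)
}
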