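#' Levins niche breadth
#'
#' `B = 1 / sum_s p_s^2` where `p_s` is the taxon's share of its own total
#' across samples, evaluated on whatever abundance scale the matrix carries.
#' `B` ranges from 1 (single-sample specialist) to the number of samples
#' (perfectly even generalist).
#'
#' @param mat samples x taxa abundance matrix.
#' @param taxon optional taxon id/index; when `NULL` all taxa are scored.
#' @return named numeric vector (or scalar) of breadths.
#' @export
levins_breadth <- function(mat, taxon = NULL) {
  x <- if (is.null(taxon)) mat else mat[, taxon, drop = FALSE]
  tot <- colSums(x)
  if (any(tot <= 0))
    stop("taxon with zero total abundance: ",
         paste(utils::head(colnames(x)[tot <= 0], 5), collapse = ", "))
  p <- sweep(x, 2, tot, "/")
  b <- 1 / colSums(p^2)
  if (is.null(taxon)) b else unname(b[if (is.character(taxon)) taxon else 1])
}

#' Classify taxa into generalists / specialists / neutral
#'
#' Permutation null: every taxon's abundances are shuffled across samples
#' independently (taxon totals preserved) `n_perm` times and Levins breadth
#' is recomputed, giving a per-taxon null distribution; the observed breadth
#' is compared with its (2.5, 97.5)% percentiles. Breadth is computed on
#' per-sample relative abundances (`relative = TRUE`, the default): because
#' sequencing depths differ between samples, realigning a taxon's counts to
#' different depths changes its relative-abundance profile, which is what
#' makes the shuffle null informative. (On raw counts the shuffle would leave
#' `B` unchanged.)
#'
#' @param ct samples x taxa count matrix (>= 5 samples).
#' @param n_perm number of permutations.
#' @param ci confidence level of the null band.
#' @param seed integer seed.
#' @param relative compute breadth on relative abundances (recommended).
#' @return object of class `niche_classification`: `taxa` data.frame
#'   (`taxon`, `B`, `ci_low`, `ci_high`, `class`), `fractions`, `mean_B`.
#' @export
classify_niche <- function(ct, n_perm = 1000, ci = 0.95, seed = 1L,
                           relative = TRUE) {
  validate_count_table(ct)
  if (nrow(ct) < 5) stop("need at least 5 samples")
  keep <- colSums(ct) > 0
  ct <- ct[, keep, drop = FALSE]
  depth <- rowSums(ct)
  n <- nrow(ct); S <- ncol(ct)
  value_mat <- function(cnt) if (relative) cnt / depth else cnt
  b_obs <- levins_breadth(value_mat(ct))
  nulls <- with_seed_(seed, {
    out <- matrix(0, n_perm, S)
    for (r in seq_len(n_perm)) {
      perm <- matrix(0L, n, S)
      for (j in seq_len(S)) perm[, j] <- ct[sample.int(n), j]
      out[r, ] <- levins_breadth(value_mat(perm))
    }
    out
  })
  alpha <- (1 - ci) / 2
  lo <- apply(nulls, 2, stats::quantile, probs = alpha)
  hi <- apply(nulls, 2, stats::quantile, probs = 1 - alpha)
  cls <- ifelse(b_obs > hi, "generalist",
                ifelse(b_obs < lo, "specialist", "neutral"))
  lv <- c("generalist", "specialist", "neutral")
  fr <- table(factor(cls, levels = lv)) / length(cls)
  structure(list(taxa = data.frame(taxon = colnames(ct), B = unname(b_obs),
                                   ci_low = unname(lo), ci_high = unname(hi),
                                   class = unname(cls), row.names = NULL,
                                   stringsAsFactors = FALSE),
                 fractions = stats::setNames(as.numeric(fr), lv),
                 mean_B = mean(b_obs)),
            class = "niche_classification")
}

#' @export
print.niche_classification <- function(x, ...) {
  cat("Niche classification of", nrow(x$taxa), "taxa; mean B =",
      round(x$mean_B, 2), "\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-10s %5.1f%%\n", nm, 100 * x$fractions[nm]))
  invisible(x)
}

#' Compare niche breadth between two sample groups
#'
#' Levins breadth is computed within each group's sample subset over the taxa
#' present there, and the two breadth distributions are compared by the
#' Mann-Whitney U test.
#'
#' @param ct samples x taxa count matrix.
#' @param groups two-level group per sample.
#' @param relative compute breadth on relative abundances.
#' @return list with per-group breadth vectors (`B`), `median_B`, `p`.
#' @export
compare_group_breadth <- function(ct, groups, relative = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  bs <- lapply(levels(groups), function(g) {
    sub <- ct[groups == g, , drop = FALSE]
    if (nrow(sub) < 5)
      warning("group '", g, "' has fewer than 5 samples")
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    levins_breadth(if (relative) to_relative(sub) else sub)
  })
  names(bs) <- levels(groups)
  ht <- suppressWarnings(stats::wilcox.test(bs[[1]], bs[[2]], exact = FALSE))
  list(B = bs, median_B = vapply(bs, stats::median, numeric(1)),
       p = ht$p.value)
}
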