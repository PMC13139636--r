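#' Alpha diversity table
#'
#' Computes observed richness, Shannon entropy (natural log by default),
#' Chao1 and ACE (classical rare-taxa estimators, via `vegan::estimateR`) and,
#' when a tree is supplied, Faith's phylogenetic diversity (total branch
#' length spanning each sample's observed tips, root path included).
#'
#' @param ct samples x taxa count matrix.
#' @param tree optional rooted `phylo` whose tips cover the table's taxa.
#' @param base logarithm base for Shannon (`exp(1)` = nats, `2` = bits).
#' @param include_root include the root-spanning path in Faith PD.
#' @return data.frame keyed by sample with columns `observed`, `shannon`,
#'   `chao1`, `ace` and (if a tree is given) `faith_pd`.
#' @export
alpha_diversity <- function(ct, tree = NULL, base = exp(1),
                            include_root = TRUE) {
  validate_count_table(ct)
  rel <- to_relative(ct)
  shannon <- apply(rel, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p, base = base))
  })
  est <- vegan::estimateR(ct)              # S.obs, S.chao1, S.ACE
  out <- data.frame(sample_id = rownames(ct),
                    observed = as.numeric(est["S.obs", ]),
                    shannon = as.numeric(shannon),
                    chao1 = as.numeric(est["S.chao1", ]),
                    ace = as.numeric(est["S.ACE", ]),
                    stringsAsFactors = FALSE)
  # samples where every taxon count exceeds the ACE rare-taxon cutoff have no
  # rare group; vegan reports NA there, but the estimator reduces to S.obs
  out$ace[is.na(out$ace)] <- out$observed[is.na(out$ace)]
  if (!is.null(tree)) {
    missing <- setdiff(colnames(ct), tree$tip.label)
    if (length(missing))
      stop("tree lacks tip(s): ", paste(utils::head(missing, 5), collapse = ", "))
    pruned <- ape::keep.tip(tree, colnames(ct))
    pd <- picante::pd(ct, pruned, include.root = include_root)
    out$faith_pd <- pd$PD
  }
  rownames(out) <- NULL
  out
}

#' Bray-Curtis distance matrix
#'
#' `d_ij = sum |x_i - x_j| / sum (x_i + x_j)`, computed on relative abundances
#' by default (set `relative = FALSE` to use the values as given).
#'
#' @param x samples x taxa abundance matrix.
#' @param relative row-normalise before computing distances.
#' @return symmetric distance matrix.
#' @export
bray_curtis <- function(x, relative = TRUE) {
  if (relative) x <- to_relative(x)
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (wraps `vegan::adonis2` with a seeded permutation stream). The p-value
#' carries the usual `+1` correction.
#'
#' @param d distance matrix.
#' @param groups factor-like group assignment, >= 2 groups of >= 2 samples.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `pseudo_F`, `R2`, `p`, `n_permutations`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- check_groups_(d, groups)
  dd <- stats::as.dist(as.matrix(d))
  fit <- with_seed_(seed, vegan::adonis2(dd ~ g,
                                         data = data.frame(g = groups),
                                         permutations = n_perm))
  list(pseudo_F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1],
       n_permutations = n_perm)
}

#' PERMDISP (homogeneity of multivariate dispersions)
#'
#' Wraps `vegan::betadisper` (spatial centroid by default, per the standard
#' construction that embeds the distance matrix by PCoA with imaginary-part
#' correction for negative eigenvalues) followed by a seeded permutation test.
#'
#' @inheritParams permanova
#' @param type `"centroid"` (default) or `"median"`.
#' @return list with `F`, `p`, `n_permutations`.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = 1L, type = "centroid") {
  groups <- check_groups_(d, groups)
  bd <- vegan::betadisper(stats::as.dist(as.matrix(d)), groups, type = type)
  pt <- with_seed_(seed, vegan::permutest(bd, permutations = n_perm))
  list(F = pt$tab$F[1], p = pt$tab$`Pr(>F)`[1], n_permutations = n_perm)
}

check_groups_ <- function(d, groups) {
  groups <- factor(groups)
  if (length(groups) != nrow(as.matrix(d)))
    stop("groups length does not match distance matrix")
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two samples")
  droplevels(groups)
}

#' Shared/unique taxon partition (UpSet-style)
#'
#' A taxon belongs to a group if it has a positive count in at least one of
#' the group's samples. Every non-empty intersection cell of group membership
#' is reported with its count and its fraction of the union.
#'
#' @param ct samples x taxa count matrix.
#' @param groups group per sample.
#' @return data.frame with columns `groups` (cell label, `+`-separated),
#'   `n_taxa`, `fraction`.
#' @export
upset_partition <- function(ct, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  member <- vapply(levels(groups), function(g)
    colSums(ct[groups == g, , drop = FALSE] > 0) > 0,
    logical(ncol(ct)))
  present <- rowSums(member) > 0
  member <- member[present, , drop = FALSE]
  cell <- apply(member, 1, function(m)
    paste(levels(groups)[m], collapse = "+"))
  tab <- table(cell)
  data.frame(groups = names(tab), n_taxa = as.integer(tab),
             fraction = as.numeric(tab) / sum(present),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group comparisons with FDR correction
#'
#' Welch's t-test or the (tie-corrected, normal-approximation) Mann-Whitney U
#' test per variable, with Benjamini-Hochberg q-values across the family.
#'
#' @param values samples x variables numeric matrix (or vector).
#' @param groups two-level group per sample.
#' @param test `"mannwhitney"` or `"t"`.
#' @param fdr compute BH-adjusted q-values.
#' @return data.frame with `variable`, `statistic`, `p`, and `q` when
#'   `fdr = TRUE`.
#' @export
compare_groups <- function(values, groups, test = c("mannwhitney", "t"),
                           fdr = TRUE) {
  test <- match.arg(test)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("every group needs at least two samples")
  a <- groups == levels(groups)[1]
  res <- apply(values, 2, function(v) {
    if (stats::sd(v) == 0) return(c(statistic = 0, p = 1))
    ht <- if (test == "t") stats::t.test(v[a], v[!a])
          else suppressWarnings(stats::wilcox.test(v[a], v[!a],
                                                   exact = FALSE,
                                                   correct = TRUE))
    c(statistic = unname(ht$statistic), p = ht$p.value)
  })
  out <- data.frame(variable = colnames(values),
                    statistic = res["statistic", ], p = res["p", ],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (fdr) out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
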