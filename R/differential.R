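#' LEfSe-style biomarker scoring (two groups)
#'
#' Stage 1 screens features with Kruskal-Wallis at `alpha`; stage 2 estimates
#' an LDA-derived effect size for the survivors over `n_boot` bootstrap
#' rounds (2/3 subsamples): a one-dimensional Fisher discriminant is fitted
#' on the survivor set (pooled covariance ridge-regularised by
#' `1e-6 * mean(diag)`), and the per-feature effect is
#' `|(m1_f - m2_f) + w_f (w.m1 - w.m2)| / 2`, averaged over rounds. The score
#' is `sign(m1_f - m2_f) * log10(1 + effect)`; features are reported when
#' `|score| > lda_threshold`. Features are analysed on the conventional
#' relative-abundance-per-million scale. The original subclass/Wilcoxon stage
#' is intentionally omitted (no subclass structure here); the contract is the
#' thresholds, not score parity with the reference implementation.
#'
#' @param rel samples x features relative-abundance matrix (rows sum to 1).
#' @param groups two-level group per sample.
#' @param alpha Kruskal-Wallis significance gate.
#' @param lda_threshold absolute log10 effect-size threshold.
#' @param n_boot bootstrap rounds for the effect size.
#' @param seed integer seed.
#' @return data.frame `feature`, `kw_p`, `lda_score`, `enriched_group`,
#'   sorted by decreasing `|lda_score|`; zero rows if nothing passes.
#' @export
lefse_like <- function(rel, groups, alpha = 0.05, lda_threshold = 2.5,
                       n_boot = 30L, seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  x <- as.matrix(rel) * 1e6
  kw_p <- apply(x, 2, function(v) {
    if (stats::sd(v) == 0) return(1)
    stats::kruskal.test(v, groups)$p.value
  })
  keep <- which(kw_p < alpha)
  empty <- data.frame(feature = character(), kw_p = numeric(),
                      lda_score = numeric(), enriched_group = character(),
                      stringsAsFactors = FALSE)
  if (length(keep) < 2) return(empty)
  xs <- x[, keep, drop = FALSE]
  g1 <- groups == levels(groups)[1]
  eff <- matrix(0, n_boot, ncol(xs))
  with_seed_(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sort(sample.int(nrow(xs), ceiling(2 * nrow(xs) / 3)))
      if (length(unique(groups[idx])) < 2) next
      xb <- xs[idx, , drop = FALSE]
      gb <- g1[idx]
      m1 <- colMeans(xb[gb, , drop = FALSE])
      m2 <- colMeans(xb[!gb, , drop = FALSE])
      cv <- (crossprod_centered_(xb[gb, , drop = FALSE]) +
             crossprod_centered_(xb[!gb, , drop = FALSE])) /
            max(nrow(xb) - 2, 1)
      diag(cv) <- diag(cv) + 1e-6 * mean(diag(cv))
      w <- tryCatch(solve(cv, m1 - m2), error = function(e) m1 - m2)
      w <- w / sqrt(sum(w^2))
      proj_gap <- sum(w * m1) - sum(w * m2)
      eff[b, ] <- abs((m1 - m2) + w * proj_gap) / 2
    }
  })
  effect <- colMeans(eff)
  dir1 <- colMeans(xs[g1, , drop = FALSE]) >= colMeans(xs[!g1, , drop = FALSE])
  score <- ifelse(dir1, 1, -1) * log10(1 + effect)
  pass <- abs(score) > lda_threshold
  if (!any(pass)) return(empty)
  out <- data.frame(feature = colnames(xs)[pass], kw_p = kw_p[keep][pass],
                    lda_score = score[pass],
                    enriched_group = ifelse(dir1[pass], levels(groups)[1],
                                            levels(groups)[2]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-abs(out$lda_score)), , drop = FALSE]
}

crossprod_centered_ <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  crossprod(xc)
}

#' SIMPER: per-taxon contributions to between-group Bray-Curtis
#'
#' For every between-group sample pair `(i, j)` the per-taxon share is
#' `delta_f = |x_fi - x_fj| / sum_g (x_gi + x_gj)`; shares are averaged over
#' pairs (their sum equals the mean between-group Bray-Curtis dissimilarity),
#' normalised to fractions, and ranked.
#'
#' @param rel samples x taxa relative-abundance matrix.
#' @param groups two-level group per sample.
#' @return data.frame `taxon`, `mean_delta` (raw mean share),
#'   `contribution` (fraction of the total), `cumulative`, sorted descending.
#' @export
simper <- function(rel, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  rel <- as.matrix(rel)
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  acc <- numeric(ncol(rel))
  for (i in ia) {
    num <- abs(rel[ib, , drop = FALSE] -
                 rep(rel[i, ], each = length(ib)))
    den <- rowSums(rel[ib, , drop = FALSE]) + sum(rel[i, ])
    acc <- acc + colSums(num / den)
  }
  mean_delta <- acc / (length(ia) * length(ib))
  contribution <- mean_delta / sum(mean_delta)
  ord <- order(-contribution)
  data.frame(taxon = colnames(rel)[ord], mean_delta = mean_delta[ord],
             contribution = contribution[ord],
             cumulative = cumsum(contribution[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' AUC by the rank (Mann-Whitney) formulation
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels logical or two-level factor; `TRUE`/second level = positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  pos <- as.logical(if (is.logical(labels)) labels
                    else factor(labels) == levels(factor(labels))[2])
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams auc_rank
#' @return data.frame of `(fpr, tpr)` starting at (0,0) and ending at (1,1).
#' @export
roc_points <- function(scores, labels) {
  pos <- as.logical(if (is.logical(labels)) labels
                    else factor(labels) == levels(factor(labels))[2])
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE)   # one point per threshold
  data.frame(fpr = c(0, fp[keep] / sum(!pos)),
             tpr = c(0, tp[keep] / sum(pos)))
}

classifier_fits_ <- function() list(
  knn = list(
    fit = function(xtr, ytr) list(x = xtr, y = ytr),
    score = function(fit, xte) {
      pr <- class::knn(fit$x, xte, fit$y, k = 5, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == levels(fit$y)[2], p, 1 - p)
    }),
  random_forest = list(
    fit = function(xtr, ytr) randomForest::randomForest(xtr, ytr, ntree = 500),
    score = function(fit, xte)
      stats::predict(fit, xte, type = "prob")[, 2]),
  naive_bayes = list(
    fit = function(xtr, ytr) e1071::naiveBayes(xtr, ytr),
    score = function(fit, xte)
      stats::predict(fit, xte, type = "raw")[, 2]),
  logistic = list(
    fit = function(xtr, ytr) {
      df <- data.frame(xtr, check.names = FALSE)
      df$.y <- ytr
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial))
    },
    score = function(fit, xte)
      suppressWarnings(stats::predict(fit, data.frame(xte, check.names = FALSE),
                                      type = "response"))),
  decision_tree = list(
    fit = function(xtr, ytr) {
      df <- data.frame(xtr, check.names = FALSE)
      df$.y <- ytr
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    score = function(fit, xte)
      stats::predict(fit, data.frame(xte, check.names = FALSE))[, 2]),
  xgboost = list(
    fit = function(xtr, ytr)
      xgboost::xgboost(xtr, ytr, nrounds = 50, max_depth = 3,
                       learning_rate = 0.3, nthreads = 1, verbosity = 0),
    score = function(fit, xte) stats::predict(fit, xte, type = "response"))
)

#' Screen classifier families for group discrimination
#'
#' Stratified seeded 70/30 split; fits k-nearest neighbours, random forest,
#' Gaussian naive Bayes, logistic regression, a decision tree and
#' gradient-boosted trees; evaluates each by test AUC (rank formulation);
#' ranks features for the best model by permutation importance (mean test-AUC
#' drop over `n_shuffles` seeded shuffles per feature).
#'
#' @param features samples x features numeric matrix.
#' @param labels two-level outcome per sample.
#' @param split training fraction.
#' @param seed integer seed.
#' @param models subset of model names to fit.
#' @param n_shuffles shuffles per feature for permutation importance.
#' @return object of class `classifier_screen`: per-model `auc` and `roc`,
#'   `best_model` (ties broken alphabetically), `importance` data.frame.
#' @export
screen_classifiers <- function(features, labels, split = 0.7, seed = 1L,
                               models = names(classifier_fits_()),
                               n_shuffles = 20L) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(labels)
  if (nlevels(y) != 2) stop("exactly two classes required")
  fits <- classifier_fits_()[match.arg(models, names(classifier_fits_()),
                                       several.ok = TRUE)]
  idx_tr <- with_seed_(stage_seed(seed, "split"), {
    unlist(lapply(levels(y), function(l) {
      i <- which(y == l)
      sort(sample(i, round(split * length(i))))
    }))
  })
  idx_te <- setdiff(seq_along(y), idx_tr)
  if (length(unique(y[idx_te])) < 2 || min(table(y[idx_te])) < 2)
    stop("test fold does not contain both classes (>=2 each); adjust split")
  xtr <- x[idx_tr, , drop = FALSE]; ytr <- droplevels(y[idx_tr])
  xte <- x[idx_te, , drop = FALSE]; yte <- y[idx_te]

  res <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    fit <- with_seed_(stage_seed(seed, paste0("fit_", nm)), f$fit(xtr, ytr))
    sc <- f$score(fit, xte)
    list(fit = fit, scorer = f$score, scores = sc,
         auc = auc_rank(sc, yte), roc = roc_points(sc, yte))
  })
  names(res) <- names(fits)
  aucs <- vapply(res, `[[`, numeric(1), "auc")
  best <- sort(names(aucs)[aucs == max(aucs)])[1]

  bestfit <- res[[best]]
  imp <- with_seed_(stage_seed(seed, "importance"), {
    base_auc <- bestfit$auc
    drops <- vapply(seq_len(ncol(x)), function(j) {
      mean(vapply(seq_len(n_shuffles), function(s) {
        xp <- xte
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        base_auc - auc_rank(bestfit$scorer(bestfit$fit, xp), yte)
      }, numeric(1)))
    }, numeric(1))
    data.frame(feature = colnames(x), auc_drop = drops,
               stringsAsFactors = FALSE)
  })
  imp <- imp[order(-imp$auc_drop), , drop = FALSE]
  rownames(imp) <- NULL
  structure(list(auc = aucs,
                 roc = lapply(res, `[[`, "roc"),
                 best_model = best,
                 importance = imp,
                 test_index = idx_te),
            class = "classifier_screen")
}

#' @export
print.classifier_screen <- function(x, ...) {
  cat("Classifier screen (", length(x$auc), " models)\n", sep = "")
  for (nm in names(sort(x$auc, decreasing = TRUE)))
    cat(sprintf("  %-14s AUC = %.3f%s\n", nm, x$auc[nm],
                if (nm == x$best_model) "  <- best" else ""))
  cat("Top features:", paste(utils::head(x$importance$feature, 5),
                             collapse = ", "), "\n")
  invisible(x)
}
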