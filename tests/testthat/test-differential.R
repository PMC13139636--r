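make_rel <- function(mat) to_relative(mat)

test_that("lefse_like gates on Kruskal-Wallis and scores extreme markers", {
  set.seed(1)
  n <- 30
  g <- rep(c("E1", "E2"), each = n / 2)
  # build relative abundances directly so t2 is exactly flat across samples
  noise <- matrix(rexp(n * 8), n, 8)
  noise <- noise / rowSums(noise)
  marker <- c(rep(0.5, n / 2), rep(1e-6, n / 2))       # extreme marker for E1
  rel <- cbind(marker, 0.2, (1 - marker - 0.2) * noise)
  colnames(rel) <- paste0("t", 1:10)
  res <- lefse_like(rel, g, seed = 2)
  expect_true("t1" %in% res$feature)
  expect_false("t2" %in% res$feature)
  row <- res[res$feature == "t1", ]
  expect_gt(abs(row$lda_score), 2.5)
  expect_equal(row$enriched_group, "E1")
})

test_that("lefse_like is sign-equivariant under group relabelling", {
  set.seed(3)
  n <- 24
  g <- rep(c("A", "B"), each = n / 2)
  m <- matrix(rexp(n * 8), n, 8)
  m[, 1] <- m[, 1] + rep(c(0, 30), each = n / 2)
  m[, 5] <- m[, 5] + rep(c(30, 0), each = n / 2)
  rel <- make_rel(m); colnames(rel) <- paste0("t", 1:8)
  a <- lefse_like(rel, g, lda_threshold = 0, seed = 4)
  b <- lefse_like(rel, factor(g, levels = c("B", "A")), lda_threshold = 0,
                  seed = 4)
  shared <- intersect(a$feature, b$feature)
  expect_gt(length(shared), 0)
  expect_equal(a$lda_score[match(shared, a$feature)],
               -b$lda_score[match(shared, b$feature)], tolerance = 1e-9)
})

test_that("simper contributions are exact on toys and sum to Bray-Curtis", {
  # one feature differs, rest identical -> that feature takes contribution 1
  rel <- rbind(s1 = c(0.5, 0.3, 0.2), s2 = c(0.5, 0.3, 0.2),
               s3 = c(0.3, 0.5, 0.2), s4 = c(0.3, 0.5, 0.2))
  colnames(rel) <- c("x", "y", "z")
  res <- simper(rel, c("A", "A", "B", "B"))
  expect_equal(sum(res$contribution), 1, tolerance = 1e-12)
  expect_equal(res$contribution[res$taxon == "z"], 0)
  # algebraic identity: sum of mean deltas = mean between-group Bray-Curtis
  set.seed(5)
  rel2 <- make_rel(matrix(rexp(8 * 6), 8, 6))
  colnames(rel2) <- paste0("t", 1:6)
  g <- rep(c("A", "B"), each = 4)
  res2 <- simper(rel2, g)
  bc <- bray_curtis(rel2, relative = FALSE)
  expect_equal(sum(res2$mean_delta), mean(bc[1:4, 5:8]), tolerance = 1e-9)
  # hand enumeration on a 3-taxon, 2+2-sample toy
  rel3 <- rbind(a1 = c(0.6, 0.3, 0.1), a2 = c(0.5, 0.4, 0.1),
                b1 = c(0.2, 0.5, 0.3), b2 = c(0.1, 0.6, 0.3))
  colnames(rel3) <- c("x", "y", "z")
  hand <- matrix(0, 4, 3)
  k <- 0
  for (i in 1:2) for (j in 3:4) {
    k <- k + 1
    hand[k, ] <- abs(rel3[i, ] - rel3[j, ]) / sum(rel3[i, ] + rel3[j, ])
  }
  md <- colMeans(hand)
  res3 <- simper(rel3, c("A", "A", "B", "B"))
  expect_equal(res3$mean_delta[match(c("x", "y", "z"), res3$taxon)],
               unname(md), tolerance = 1e-12)
  expect_true(all(diff(res3$cumulative) >= -1e-12))
})

test_that("rank AUC equals the trapezoidal ROC area and is monotone-invariant", {
  set.seed(6)
  for (i in 1:10) {
    sc <- rnorm(40)
    y <- runif(40) < 0.4
    if (length(unique(y)) < 2) next
    roc <- roc_points(sc, y)
    trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
    expect_equal(auc_rank(sc, y), trap, tolerance = 1e-9)
    expect_equal(auc_rank(exp(3 * sc), y), auc_rank(sc, y), tolerance = 1e-12)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  }
})

test_that("classifier screen finds a perfectly separating feature", {
  set.seed(7)
  n <- 60
  y <- rep(c("E1", "E2"), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x[, 3] <- ifelse(y == "E2", 1, -1) * runif(n, 1, 2)   # separating feature
  res <- screen_classifiers(x, y, seed = 8)
  expect_setequal(names(res$auc),
                  c("knn", "random_forest", "naive_bayes", "logistic",
                    "decision_tree", "xgboost"))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_gte(res$auc["random_forest"], 0.99)
  expect_gte(res$auc["logistic"], 0.99)
  expect_equal(res$importance$feature[1], "f3")
  # deterministic given the seed
  res2 <- screen_classifiers(x, y, seed = 8)
  expect_identical(res$auc, res2$auc)
  expect_error(screen_classifiers(x[c(1:3, 31:33), ], y[c(1:3, 31:33)],
                                  split = 0.9), "test fold")
})
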