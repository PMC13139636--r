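test_that("Jensen-Shannon distance matches closed forms and the entropy formula", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(jensen_shannon_distance(p, p), 0)
  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1)), sqrt(log(2)),
               tolerance = 1e-12)
  # direct formula evaluation as the oracle
  q <- c(0.9, 0.1); p2 <- c(0.5, 0.5)
  H <- function(x) { x <- x[x > 0]; -sum(x * log(x)) }
  m <- (p2 + q) / 2
  expect_equal(jensen_shannon_distance(p2, q, take_sqrt = FALSE),
               H(m) - (H(p2) + H(q)) / 2, tolerance = 1e-12)
  expect_error(jensen_shannon_distance(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
  expect_error(jensen_shannon_distance(c(1.5, -0.5), c(0.5, 0.5)), "negative")
})

test_that("sqrt-JSD behaves as a metric on random triples", {
  set.seed(2)
  for (i in 1:25) {
    p <- rexp(6); p <- p / sum(p)
    q <- rexp(6); q <- q / sum(q)
    r <- rexp(6); r <- r / sum(r)
    dpq <- jensen_shannon_distance(p, q)
    expect_equal(dpq, jensen_shannon_distance(q, p))          # symmetry
    expect_lte(dpq, jensen_shannon_distance(p, r) +
                    jensen_shannon_distance(r, q) + 1e-12)    # triangle
  }
})

test_that("jsd_matrix agrees with the pairwise function", {
  set.seed(3)
  rel <- to_relative(matrix(rexp(5 * 8), 5, 8,
                            dimnames = list(paste0("s", 1:5), paste0("t", 1:8))))
  d <- jsd_matrix(rel)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(d[i, j], jensen_shannon_distance(rel[i, ], rel[j, ]),
                 tolerance = 1e-12)
})

test_that("pam_cluster separates blobs and matches the exhaustive optimum", {
  set.seed(4)
  xy <- rbind(matrix(rnorm(8, 0, 0.1), 4), matrix(rnorm(8, 5, 0.1), 4))
  d <- as.matrix(dist(xy)); dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  fit <- pam_cluster(d, 2)
  expect_equal(fit$labels[1:4], rep(fit$labels[1], 4))
  expect_equal(fit$labels[5:8], rep(fit$labels[5], 4))
  expect_false(fit$labels[1] == fit$labels[5])
  # brute-force optimality on random instances
  for (s in 1:8) {
    n <- sample(5:10, 1)
    dd <- random_dist(n, seed = 100 + s)
    expect_equal(pam_cluster(dd, 2)$total_cost, brute_pam_cost(dd, 2),
                 tolerance = 1e-12)
  }
})

test_that("pam_cluster with k = n - 1 pays only the smallest pairwise distance", {
  d <- random_dist(7, seed = 5)
  fit <- pam_cluster(d, 6)
  expect_equal(fit$total_cost, min(d[upper.tri(d)]), tolerance = 1e-12)
})

test_that("distance-based CH equals the classical formula on Euclidean data", {
  set.seed(6)
  xy <- rbind(matrix(rnorm(20, 0, 1), 10), matrix(rnorm(24, 4, 1), 12))
  labels <- rep(1:2, c(10, 12))
  d <- as.matrix(dist(xy))
  expect_equal(calinski_harabasz(d, labels), classical_ch(xy, labels),
               tolerance = 1e-8)
  # three clusters too
  labels3 <- c(rep(1, 10), rep(2, 6), rep(3, 6))
  expect_equal(calinski_harabasz(d, labels3), classical_ch(xy, labels3),
               tolerance = 1e-8)
})

test_that("CH prefers merging duplicate points over splitting them", {
  xy <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  d <- as.matrix(dist(xy))
  ch_merge <- calinski_harabasz(d, c(1, 1, 2, 2))   # duplicates together: Inf
  ch_split <- calinski_harabasz(d, c(1, 2, 1, 2))
  expect_gt(ch_merge, ch_split)
})

test_that("select_enterotypes recovers planted clusters and ignores sample order", {
  d <- small_enterotype_data(seed = 7)
  e <- select_enterotypes(d$counts, d$taxonomy, k_range = 2:4)
  expect_equal(e$chosen_k, 2)
  expect_gte(mclust::adjustedRandIndex(e$labels, d$labels), 0.9)
  expect_true(all(e$medoids %in% rownames(d$counts)))
  expect_equal(unname(e$chosen_k), as.integer(names(which.max(e$ch_by_k))))
  # permutation equivariance
  set.seed(8)
  perm <- sample(nrow(d$counts))
  e2 <- select_enterotypes(d$counts[perm, ], d$taxonomy, k_range = 2:4)
  expect_equal(e2$chosen_k, e$chosen_k)
  expect_gte(mclust::adjustedRandIndex(e2$labels, e$labels[perm]), 0.999)
})

test_that("pcoa reproduces Euclidean configurations and sorts eigenvalues", {
  set.seed(9)
  xy <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(xy))
  res <- pcoa(d, n_axes = 2)
  expect_equal(as.matrix(dist(res$coordinates)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(res$eigenvalues) <= 1e-9))
  expect_lte(sum(res$proportion_explained), 1 + 1e-9)
  # Bray-Curtis toy against an independent eigen-solver
  set.seed(10)
  ct <- matrix(rpois(5 * 6, 20) + 1L, 5, 6,
               dimnames = list(paste0("s", 1:5), paste0("t", 1:6)))
  b <- bray_curtis(ct)
  res2 <- pcoa(b, n_axes = 2)
  A <- -0.5 * b^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  ev <- eigen(G, symmetric = TRUE)
  ax1 <- ev$vectors[, 1] * sqrt(ev$values[1])
  if (sign(ax1[which.max(abs(ax1))]) < 0) ax1 <- -ax1
  expect_equal(unname(res2$coordinates[, 1]), ax1, tolerance = 1e-8)
})
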