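test_that("alpha diversity matches hand-computed toy values", {
  ct <- rbind(a = c(5L, 5L, 5L, 5L), b = c(1L, 1L, 2L, 0L))
  colnames(ct) <- paste0("t", 1:4)
  out <- alpha_diversity(ct)
  expect_equal(out$observed, c(4, 3))
  expect_equal(out$shannon[1], log(4), tolerance = 1e-12)
  # Chao1: S + F1(F1-1)/(2(F2+1)) -> 3 + 2*1/(2*2) = 3.5
  expect_equal(out$chao1[2], 3.5, tolerance = 1e-9)
  # no singletons -> chao1 = observed
  expect_equal(out$chao1[1], 4, tolerance = 1e-9)
  # every count above the rare-taxa cutoff -> ACE = observed
  ct2 <- rbind(a = c(50L, 60L, 70L))
  colnames(ct2) <- paste0("t", 1:3)
  expect_equal(alpha_diversity(ct2)$ace, 3, tolerance = 1e-9)
})

test_that("Faith PD is monotone in added taxa and fails on missing tips", {
  tr <- simulate_yule_tree(10, seed = 1)
  ct1 <- matrix(0L, 1, 10, dimnames = list("s1", tr$tip.label))
  ct1[1, 1:4] <- 1L
  ct2 <- ct1; ct2[1, 5] <- 1L
  pd1 <- alpha_diversity(ct1, tr)$faith_pd
  pd2 <- alpha_diversity(ct2, tr)$faith_pd
  expect_gte(pd2, pd1)
  bad <- ct1; colnames(bad)[1] <- "nope"
  expect_error(alpha_diversity(bad, tr), "nope")
})

test_that("Bray-Curtis matches hand values and stays within [0, 1]", {
  x <- rbind(a = c(0.5, 0.5, 0), b = c(0.25, 0.25, 0.5))
  expect_equal(bray_curtis(x, relative = FALSE)["a", "b"], 0.5)
  same <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(bray_curtis(same, relative = FALSE)["a", "b"], 0)
  disjoint <- rbind(a = c(1, 0), b = c(0, 4))
  expect_equal(bray_curtis(disjoint, relative = FALSE)["a", "b"], 1)
  set.seed(2)
  m <- matrix(rexp(6 * 10), 6, 10)
  d <- bray_curtis(m)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
})

test_that("permanova detects planted structure with the smallest attainable p", {
  set.seed(3)
  xy <- rbind(matrix(rnorm(40, 0, 0.2), 20), matrix(rnorm(40, 5, 0.2), 20))
  d <- as.matrix(dist(xy))
  dimnames(d) <- list(paste0("s", 1:40), paste0("s", 1:40))
  g <- rep(c("a", "b"), each = 20)
  res <- permanova(d, g, n_perm = 99, seed = 4)
  expect_equal(res$p, 1 / (99 + 1))
  expect_gt(res$R2, 0.9)
  expect_error(permanova(d, rep("a", 40), 99, 1), "two groups")
})

test_that("permdisp flags a dispersion difference and tolerates equal spreads", {
  set.seed(5)
  a <- matrix(rnorm(60, 0, 1), 30)
  b <- matrix(rnorm(60, 0, 3), 30)          # scaled x3 about its centroid
  d <- as.matrix(dist(rbind(a, b)))
  g <- rep(c("a", "b"), each = 30)
  res <- permdisp(d, g, n_perm = 199, seed = 6)
  expect_lt(res$p, 0.05)
  d2 <- as.matrix(dist(rbind(a, matrix(rnorm(60, 5, 1), 30))))
  res2 <- permdisp(d2, g, n_perm = 199, seed = 7)
  expect_gt(res2$p, 0.05)
})

test_that("upset_partition enumerates intersection cells exactly", {
  ct <- rbind(s1 = c(1L, 1L, 0L, 0L, 1L, 0L),
              s2 = c(1L, 0L, 1L, 0L, 1L, 0L),
              s3 = c(0L, 0L, 0L, 1L, 1L, 1L),
              s4 = c(0L, 0L, 0L, 1L, 1L, 0L))
  colnames(ct) <- paste0("t", 1:6)
  up <- upset_partition(ct, c("A", "A", "B", "B"))
  cells <- setNames(up$n_taxa, up$groups)
  expect_equal(unname(cells["A"]), 3)       # t1 t2 t3
  expect_equal(unname(cells["B"]), 2)       # t4 t6
  expect_equal(unname(cells["A+B"]), 1)     # t5
  expect_equal(sum(up$fraction), 1)
  # disjoint groups share nothing; identical groups share everything
  dis <- rbind(s1 = c(1L, 0L), s2 = c(0L, 1L)); colnames(dis) <- c("x", "y")
  updis <- upset_partition(dis, c("A", "B"))
  expect_false("A+B" %in% updis$groups)
  same <- rbind(s1 = c(1L, 1L), s2 = c(1L, 1L)); colnames(same) <- c("x", "y")
  expect_equal(upset_partition(same, c("A", "B"))$groups, "A+B")
})

test_that("compare_groups honours test choice, ties and FDR ordering", {
  set.seed(8)
  g <- rep(c("a", "b"), each = 10)
  # both groups carry exactly the same values -> no evidence of a shift
  same <- matrix(rep(rnorm(10), 2), 20, 3)
  res <- compare_groups(same, g)
  expect_true(all(res$p > 0.9))
  shift <- cbind(x = c(rnorm(10), rnorm(10, 8)))
  expect_lt(compare_groups(shift, g)$p, 0.001)
  expect_lt(compare_groups(shift, g, test = "t")$p, 0.001)
  # q-values are the BH adjustment of the reported p-values
  vals <- matrix(rnorm(20 * 6), 20, 6)
  vals[, 1] <- vals[, 1] + rep(c(0, 2), each = 10)
  res2 <- compare_groups(vals, g)
  expect_equal(res2$q, p.adjust(res2$p, "BH"))
  expect_error(compare_groups(vals, rep("a", 20)), "two groups")
})
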