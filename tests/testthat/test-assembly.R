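test_that("fit_ncm attains the least-squares optimum over m", {
  set.seed(1)
  mp <- exp(rnorm(120, 0, 1.2)); mp <- mp / sum(mp)
  ns <- neutral_sim_spec(mp, local_size = 400, migration = 0.2,
                         n_samples = 20, burn_in_steps = 40, seed = 2)
  ct <- simulate_neutral_communities(ns)
  fit <- fit_ncm(ct)
  # grid-search oracle: no m on a fine grid does better
  N <- mean(rowSums(ct))
  p <- colMeans(to_relative(ct)); occ <- colMeans(ct > 0)
  keep <- p > 0; p <- p[keep]; occ <- occ[keep]
  sse <- vapply(seq(1e-4, 1, by = 1e-3), function(m)
    sum((occ - pbeta(1 / N, N * m * p, N * m * (1 - p),
                     lower.tail = FALSE))^2), numeric(1))
  fit_sse <- sum((fit$taxa$occ_freq - fit$taxa$predicted_freq)^2)
  expect_lte(fit_sse, min(sse) + 1e-9)
  expect_equal(fit$Nm, fit$N * fit$m, tolerance = 1e-12)
  expect_lte(fit$r2, 1)
})

test_that("a ubiquitous abundant taxon is predicted present and 'within'", {
  set.seed(3)
  ct <- matrix(rpois(20 * 30, 5), 20, 30,
               dimnames = list(paste0("s", 1:20), paste0("t", 1:30)))
  ct[, 1] <- ct[, 1] + 500L                  # dominant everywhere
  fit <- fit_ncm(ct)
  row <- fit$taxa[fit$taxa$taxon == "t1", ]
  expect_gt(row$predicted_freq, 0.99)
  expect_equal(row$partition, "within")
})

test_that("beta_mntd matches closed forms, hand sums and picante", {
  # two single-taxon samples on a cherry with branch lengths 2 and 2
  cherry <- ape::read.tree(text = "(A:2,B:2);")
  ct <- rbind(s1 = c(A = 5L, B = 0L), s2 = c(A = 0L, B = 3L))
  expect_equal(beta_mntd(ct, cherry, pair = c("s1", "s2")), 4)
  # identical communities -> 0
  ct2 <- rbind(s1 = c(A = 2L, B = 1L), s2 = c(A = 2L, B = 1L))
  expect_equal(beta_mntd(ct2, cherry, pair = c("s1", "s2")), 0)
  # 4-tip toy with printed branch lengths, hand-computed weighted sum
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:2,D:3):1);")
  ct3 <- rbind(s1 = c(A = 3L, B = 1L, C = 0L, D = 0L),
               s2 = c(A = 0L, B = 0L, C = 1L, D = 1L))
  # nearest-taxon distances: A->C 5, B->C 5 ; C->A 5, D->A 6
  hand <- 0.5 * ((0.75 * 5 + 0.25 * 5) + (0.5 * 5 + 0.5 * 6))
  expect_equal(beta_mntd(ct3, tr, pair = c("s1", "s2")), hand)
  # symmetry and picante oracle on random data
  tr2 <- simulate_yule_tree(15, seed = 4)
  set.seed(5)
  ct4 <- matrix(rpois(6 * 15, 2) + 1L, 6, 15,
                dimnames = list(paste0("s", 1:6), tr2$tip.label))
  ours <- beta_mntd(ct4, tr2)
  expect_equal(ours, t(ours))
  oracle <- as.matrix(picante::comdistnt(ct4, cophenetic(tr2),
                                         abundance.weighted = TRUE))
  expect_equal(ours, oracle[rownames(ours), colnames(ours)],
               tolerance = 1e-9)
})

test_that("beta_nti is invariant to taxon column order and errors on flat trees", {
  tr <- simulate_yule_tree(30, seed = 6)
  set.seed(7)
  ct <- matrix(rpois(8 * 30, 0.9), 8, 30,     # sparse: partial taxon overlap
               dimnames = list(paste0("s", 1:8), tr$tip.label))
  ct[cbind(1:8, sample(30, 8))] <- ct[cbind(1:8, sample(30, 8))] + 1L
  storage.mode(ct) <- "integer"
  a <- beta_nti(ct, tr, n_null = 49, seed = 8)
  perm <- sample(30)
  b <- beta_nti(ct[, perm], tr, n_null = 49, seed = 8)
  expect_equal(a$bnti, b$bnti)
  flat <- tr; flat$edge.length[] <- 0
  expect_error(beta_nti(ct, flat, n_null = 49, seed = 8), "degenerate")
})

test_that("raup_crick_bray hits its boundaries on extreme pairs", {
  set.seed(9)
  base <- matrix(rpois(10 * 40, 5), 10, 40,
                 dimnames = list(paste0("s", 1:10), paste0("t", 1:40)))
  base[base == 0] <- 1L
  # identical pair: observed dissimilarity 0, below every null draw
  base[2, ] <- base[1, ]
  rc <- raup_crick_bray(base, pairs = rbind(c(1, 2)), n_null = 199, seed = 10)
  expect_equal(rc, -1)
  # extreme disjoint pair among otherwise even samples
  ct <- base
  ct[1, ] <- 0L; ct[1, 1:20] <- 50L
  ct[2, ] <- 0L; ct[2, 21:40] <- 50L
  rc2 <- raup_crick_bray(ct, pairs = rbind(c(1, 2)), n_null = 199, seed = 11)
  expect_equal(rc2, 1)
})

test_that("classify_processes reproduces the five-way threshold map", {
  bnti <- c(-2.5, 2.5, 0.5, 0.5, 0, -2, 2, 1, -1)
  rc <- c(0.3, 0.3, 0.97, -0.97, 0, 0.99, -0.99, 0.95, -0.95)
  res <- classify_processes(bnti, rc)
  expect_equal(res$process,
               c("homogeneous_selection", "heterogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift",
                 # boundaries fall to drift (strict inequalities)
                 "drift", "drift", "drift", "drift"))
  expect_equal(sum(res$fractions), 1, tolerance = 1e-12)
})
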