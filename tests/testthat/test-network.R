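planted_block_counts <- function(n = 50, seed = 1) {
  # 6 taxa: block {t1,t2,t3} strongly positively correlated, block {t4,t5}
  # strongly negatively coupled, t6 independent
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  lam <- cbind(exp(z1) * 50, exp(z1 + rnorm(n, 0, 0.05)) * 40,
               exp(z1 + rnorm(n, 0, 0.05)) * 30,
               exp(1.5 * z2) * 60, exp(-1.5 * z2) * 60,
               exp(rnorm(n)) * 30)
  ct <- matrix(rpois(length(lam), lam), n, 6,
               dimnames = list(paste0("s", 1:n), paste0("t", 1:6)))
  ct[rowSums(ct) > 0, , drop = FALSE]
}

test_that("build_network keeps exactly the hand-thresholded edge set", {
  ct <- planted_block_counts()
  net <- build_network(ct, min_mean_relabund = 0, min_prevalence = 0,
                       rho_min = 0.6, q_max = 0.05)
  rel <- to_relative(ct)
  rho <- cor(rel, method = "spearman")
  n <- nrow(rel)
  iu <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[iu]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  q <- p.adjust(2 * pt(-abs(tstat), n - 2), "BH")
  hand <- paste(colnames(rel)[iu[, 1]], colnames(rel)[iu[, 2]])[abs(r) > 0.6 & q < 0.05]
  expect_setequal(paste(net$edges$u, net$edges$v), hand)
  expect_true(all(abs(net$edges$rho) > 0.6))
  expect_true(all(net$edges$q < 0.05))
  # the planted positive block and the negative pair are recovered
  expect_true(all(c("t1 t2", "t1 t3", "t2 t3") %in%
                    paste(net$edges$u, net$edges$v)))
  neg <- net$edges[net$edges$sign == "negative", ]
  expect_true("t4 t5" %in% paste(neg$u, neg$v))
})

test_that("independent noise taxa yield an (almost) empty network", {
  set.seed(2)
  ct <- matrix(rpois(50 * 20, 30), 50, 20,
               dimnames = list(paste0("s", 1:50), paste0("t", 1:20)))
  net <- build_network(ct, min_mean_relabund = 0, min_prevalence = 0)
  expect_lte(nrow(net$edges), 1)
})

test_that("identical abundance vectors give a rho = 1 edge", {
  set.seed(3)
  base <- rpois(30, 40) + 1L
  ct <- cbind(t1 = base, t2 = base, t3 = rpois(30, 40) + 1L)
  rownames(ct) <- paste0("s", 1:30)
  net <- build_network(ct, 0, 0)
  e <- net$edges[net$edges$u == "t1" & net$edges$v == "t2", ]
  expect_equal(e$rho, 1)
})

test_that("network_stats matches closed forms on canonical graphs", {
  tri <- structure(list(nodes = c("a", "b", "c"),
                        edges = data.frame(u = c("a", "a", "b"),
                                           v = c("b", "c", "c"),
                                           rho = 1, p = 0, q = 0,
                                           sign = "positive")),
                   class = "cooc_network")
  st <- network_stats(tri)
  expect_equal(st$density, 1)
  expect_equal(st$avg_clustering, 1)
  expect_equal(unname(st$nodes$eccentricity), c(1, 1, 1))
  expect_equal(st$avg_degree, 2)
  path3 <- structure(list(nodes = c("a", "b", "c"),
                          edges = data.frame(u = c("a", "b"), v = c("b", "c"),
                                             rho = 1, p = 0, q = 0,
                                             sign = "positive")),
                     class = "cooc_network")
  st2 <- network_stats(path3)
  expect_equal(st2$nodes$betweenness[st2$nodes$taxon == "b"], 1)
  expect_equal(sum(st2$nodes$betweenness[st2$nodes$taxon != "b"]), 0)
  expect_equal(sum(st2$nodes$degree), 2 * st2$n_edges)
})

test_that("betweenness equals brute-force shortest-path enumeration", {
  for (s in 1:5) {
    set.seed(200 + s)
    n <- 12
    adj <- matrix(0L, n, n)
    while (sum(adj) == 0) {
      adj <- matrix(rbinom(n * n, 1, 0.25), n, n)
      adj[lower.tri(adj, diag = TRUE)] <- 0L
      adj <- adj + t(adj)
    }
    idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    net <- structure(list(nodes = paste0("v", 1:n),
                          edges = data.frame(u = paste0("v", idx[, 1]),
                                             v = paste0("v", idx[, 2]),
                                             rho = 1, p = 0, q = 0,
                                             sign = "positive")),
                     class = "cooc_network")
    st <- network_stats(net)
    expect_equal(unname(st$nodes$betweenness[match(paste0("v", 1:n),
                                                   st$nodes$taxon)]),
                 brute_betweenness(adj), tolerance = 1e-9)
  }
})

test_that("network statistics are invariant under node relabelling", {
  ct <- planted_block_counts(seed = 4)
  net <- build_network(ct, 0, 0)
  st <- network_stats(net)
  perm <- c("t3", "t6", "t1", "t5", "t2", "t4")
  ct2 <- ct[, perm]
  st2 <- network_stats(build_network(ct2, 0, 0))
  expect_equal(st$n_edges, st2$n_edges)
  expect_equal(st$avg_clustering, st2$avg_clustering)
  expect_equal(st$avg_path_length, st2$avg_path_length)
  ord <- match(st$nodes$taxon, st2$nodes$taxon)
  expect_equal(st$nodes$degree, st2$nodes$degree[ord])
  expect_equal(st$nodes$betweenness, st2$nodes$betweenness[ord])
})
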