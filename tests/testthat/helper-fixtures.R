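# Shared fixtures and independent oracles used across the suite.

toy_counts <- function() {
  m <- matrix(c(5L, 0L, 3L, 2L,
                1L, 4L, 0L, 5L,
                2L, 2L, 2L, 2L), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("t1", "t2", "t3", "t4")))
  m
}

toy_taxonomy <- function(ids, genus, phylum = NULL) {
  data.frame(taxon_id = ids, domain = "Bacteria",
             phylum = if (is.null(phylum)) "P1" else phylum,
             class = "", order = "", family = "", genus = genus,
             species = "", stringsAsFactors = FALSE)
}

# random symmetric distance matrix with zero diagonal
random_dist <- function(n, seed) {
  set.seed(seed)
  d <- matrix(runif(n * n), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  d
}

# exhaustive k=2 medoid search: the brute-force PAM oracle
brute_pam_cost <- function(d, k = 2) {
  n <- nrow(d)
  combs <- utils::combn(n, k)
  min(apply(combs, 2, function(med)
    sum(apply(d[, med, drop = FALSE], 1, min))))
}

# classical centroid-based Calinski-Harabasz on Euclidean coordinates
classical_ch <- function(xy, labels) {
  labels <- as.integer(factor(labels))
  n <- nrow(xy); k <- max(labels)
  centroid <- colMeans(xy)
  w <- 0; b <- 0
  for (c in seq_len(k)) {
    pts <- xy[labels == c, , drop = FALSE]
    cc <- colMeans(pts)
    w <- w + sum(sweep(pts, 2, cc)^2)
    b <- b + nrow(pts) * sum((cc - centroid)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

# brute-force betweenness: enumerate all shortest paths with an independent
# BFS + recursive path enumeration (no igraph)
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  dist_from <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in which(adj[v, ] == 1))
        if (d[w] == Inf) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
      frontier <- unique(nxt)
    }
    d
  }
  D <- t(vapply(1:n, dist_from, numeric(n)))
  paths <- function(s, t) {          # all shortest s->t paths (vertex lists)
    if (s == t) return(list(s))
    out <- list()
    for (v in which(adj[t, ] == 1))
      if (is.finite(D[s, v]) && D[s, v] == D[s, t] - 1)
        out <- c(out, lapply(paths(s, v), function(p) c(p, t)))
    out
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    ps <- paths(s, t)
    if (!length(ps)) next
    inner <- unlist(lapply(ps, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tb <- table(inner)
      btw[as.integer(names(tb))] <- btw[as.integer(names(tb))] +
        as.numeric(tb) / length(ps)
    }
  }
  btw
}

# a small two-enterotype dataset for fast module-level tests
small_enterotype_data <- function(seed = 7) {
  spec <- enterotype_sim_spec(n_samples = c(18L, 12L), n_taxa = 240L,
                              n_genera = 60L, seed = seed)
  simulate_enterotype_dataset(spec)
}
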