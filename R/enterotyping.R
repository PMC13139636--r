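#' Jensen-Shannon distance between two compositions
#'
#' `JSD(p, q) = H(m) - (H(p) + H(q)) / 2` with `m = (p + q) / 2` and `H` the
#' Shannon entropy in nats (`0 log 0 := 0`, so no pseudocount is needed). By
#' default the square root is returned, which is a proper metric on the
#' simplex; `take_sqrt = FALSE` gives the raw divergence.
#'
#' @param p,q probability vectors of equal length summing to one (1e-9).
#' @param take_sqrt return `sqrt(JSD)` (metric) rather than raw JSD.
#' @return non-negative scalar.
#' @export
jensen_shannon_distance <- function(p, q, take_sqrt = TRUE) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("negative entries in composition")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("compositions must sum to 1")
  m <- (p + q) / 2
  jsd <- shannon_entropy_(m) -
    (shannon_entropy_(p) + shannon_entropy_(q)) / 2
  jsd <- max(jsd, 0)
  if (take_sqrt) sqrt(jsd) else jsd
}

shannon_entropy_ <- function(x) {
  x <- x[x > 0]
  -sum(x * log(x))
}

#' All-pairs Jensen-Shannon distance matrix
#'
#' @param rel samples x taxa relative-abundance matrix (rows sum to one).
#' @param take_sqrt as in [jensen_shannon_distance()].
#' @return symmetric samples x samples distance matrix.
#' @export
jsd_matrix <- function(rel, take_sqrt = TRUE) {
  if (any(abs(rowSums(rel) - 1) > 1e-9))
    stop("rows must sum to 1; call to_relative() first")
  n <- nrow(rel)
  xlx <- rel * log(rel)
  xlx[rel == 0] <- 0
  h <- -rowSums(xlx)                      # per-sample entropy
  d <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    m <- (rel[rest, , drop = FALSE] + rep(rel[i, ], each = length(rest))) / 2
    mlm <- m * log(m)
    mlm[m == 0] <- 0
    jsd <- pmax(-rowSums(mlm) - (h[rest] + h[i]) / 2, 0)
    d[i, rest] <- d[rest, i] <- if (take_sqrt) sqrt(jsd) else jsd
  }
  d
}

#' Partitioning around medoids (deterministic BUILD + SWAP)
#'
#' Classic PAM on a precomputed distance matrix: greedy BUILD initialisation
#' followed by best-improvement SWAP until no swap lowers the total cost
#' (sum of distances to the assigned medoid). All ties are broken toward the
#' lowest sample index, so the result is deterministic. Because single-swap
#' descent can stall in a local optimum (the reference implementations share
#' this), small instances are solved by a deterministic multi-start: BUILD is
#' re-run with every sample forced as the first medoid and the best SWAP
#' result is kept. `n_start = NULL` (default) uses all `n` starts when
#' `n <= 30` and the single canonical BUILD otherwise.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k number of clusters, `2 <= k < n`.
#' @param n_start number of BUILD starts (see above).
#' @return list with `labels` (1..k per sample, in medoid order), `medoids`
#'   (sample ids), `medoid_idx` and `total_cost`.
#' @export
pam_cluster <- function(d, k, n_start = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n_samples")
  if (any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0))
    stop("d must be symmetric with zero diagonal")
  if (is.null(n_start)) n_start <- if (n <= 30) n else 1L

  run_one <- function(first) {
    # BUILD: then greedy gain
    medoids <- first
    nd <- d[, first]                       # distance to nearest medoid
    while (length(medoids) < k) {
      cand <- setdiff(seq_len(n), medoids)
      gains <- vapply(cand, function(c) sum(pmax(nd - d[, c], 0)), numeric(1))
      best <- cand[which.max(gains)]       # which.max: lowest index on ties
      medoids <- c(medoids, best)
      nd <- pmin(nd, d[, best])
    }
    # SWAP: apply the best strictly-improving swap until none remains
    cost <- sum(nd)
    repeat {
      best_delta <- 0
      best_swap <- NULL
      for (mi in seq_along(medoids)) {
        others <- medoids[-mi]
        partial <- if (length(others))
          do.call(pmin, lapply(others, function(j) d[, j])) else rep(Inf, n)
        for (h in setdiff(seq_len(n), medoids)) {
          delta <- sum(pmin(partial, d[, h])) - cost
          if (delta < best_delta - 1e-12) {
            best_delta <- delta
            best_swap <- c(mi, h)
          }
        }
      }
      if (is.null(best_swap)) break
      medoids[best_swap[1]] <- best_swap[2]
      cost <- cost + best_delta
    }
    list(medoids = medoids, cost = cost)
  }

  starts <- if (n_start >= n) seq_len(n)
            else which.min(colSums(d))     # canonical single start
  best <- NULL
  for (s in starts) {
    res <- run_one(s)
    if (is.null(best) || res$cost < best$cost - 1e-12) best <- res
  }
  medoids <- sort(best$medoids)
  labels <- apply(d[, medoids, drop = FALSE], 1, which.min)
  cost <- sum(d[cbind(seq_len(n), medoids[labels])])
  list(labels = as.integer(labels),
       medoids = rownames(d)[medoids],
       medoid_idx = medoids,
       total_cost = cost)
}

#' Distance-based Calinski-Harabasz index
#'
#' Uses the sum-of-squares identity `W = sum_c (1 / 2 n_c) sum_{i,j in c}
#' d_ij^2`, `T = (1 / 2n) sum_{i,j} d_ij^2`, `B = T - W`, so the index equals
#' the classical centroid formula whenever `d` is Euclidean, while remaining
#' well-defined for arbitrary distance matrices (e.g. Jensen-Shannon).
#'
#' @param d symmetric distance matrix.
#' @param labels cluster assignment (>= 2 non-empty clusters).
#' @return CH value; `Inf` when the within-cluster dispersion is zero.
#' @export
calinski_harabasz <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("need at least two clusters")
  d2 <- d^2
  tot <- sum(d2) / (2 * n)
  within <- 0
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    if (!length(idx)) stop("empty cluster")
    within <- within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  between <- tot - within
  if (within <= 1e-12) return(Inf)
  (between / (k - 1)) / (within / (n - k))
}

mean_silhouette_ <- function(d, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = as.matrix(d))
  mean(sil[, "sil_width"])
}

#' Identify enterotypes
#'
#' The full enterotyping procedure: collapse the count table to a taxonomic
#' rank (genus by default), convert to relative abundance, compute all-pairs
#' Jensen-Shannon distances, run PAM for every candidate `k`, score each
#' partition with the distance-based Calinski-Harabasz index (and the mean
#' silhouette width for corroboration), and keep the `k` maximising CH
#' (ties to the smaller `k`).
#'
#' @param ct samples x taxa count matrix.
#' @param tax taxonomy data.frame; `NULL` skips rank collapsing.
#' @param k_range candidate cluster numbers.
#' @param rank rank to collapse to when `tax` is given.
#' @param take_sqrt use the metric square-root JSD (default).
#' @return object of class `enterotype_assignment`: `labels` (named integer
#'   vector), `medoids`, `chosen_k`, `ch_by_k`, `silhouette_by_k`, `distance`.
#' @export
select_enterotypes <- function(ct, tax = NULL, k_range = 2:6, rank = "genus",
                               take_sqrt = TRUE) {
  n <- nrow(ct)
  if (any(k_range < 2) || any(k_range >= n))
    stop("k_range must lie within [2, n_samples - 1]")
  work <- if (!is.null(tax)) collapse_rank(ct, tax, rank) else ct
  rel <- to_relative(work)
  d <- jsd_matrix(rel, take_sqrt = take_sqrt)
  fits <- lapply(k_range, function(k) pam_cluster(d, k))
  ch <- vapply(fits, function(f) calinski_harabasz(d, f$labels), numeric(1))
  sil <- vapply(fits, function(f) mean_silhouette_(d, f$labels), numeric(1))
  names(ch) <- names(sil) <- k_range
  chosen <- which.max(ch)                  # ties -> first, i.e. smaller k
  fit <- fits[[chosen]]
  labels <- stats::setNames(fit$labels, rownames(ct))
  structure(list(labels = labels, medoids = fit$medoids,
                 chosen_k = k_range[chosen], ch_by_k = ch,
                 silhouette_by_k = sil, total_cost = fit$total_cost,
                 distance = d),
            class = "enterotype_assignment")
}

#' @export
print.enterotype_assignment <- function(x, ...) {
  cat("Enterotype assignment over", length(x$labels), "samples\n")
  cat("  chosen k =", x$chosen_k, "(CH-optimal); cluster sizes:",
      paste(table(x$labels), collapse = "/"), "\n")
  cat("  CH by k: ",
      paste(sprintf("k=%s: %.1f", names(x$ch_by_k), x$ch_by_k),
            collapse = ", "), "\n")
  cat("  medoids:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a distance matrix. Negative eigenvalues are
#' retained in the report but excluded from the denominator of the variance
#' explained; the sign of each axis is fixed by making its largest-magnitude
#' coordinate positive.
#'
#' @param d distance matrix or `dist`.
#' @param n_axes number of axes to return.
#' @return list with `coordinates`, `eigenvalues` (all, descending) and
#'   `proportion_explained` (over positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  n_axes <- min(n_axes, n - 1)
  fit <- suppressWarnings(stats::cmdscale(d, k = n_axes, eig = TRUE))
  coords <- fit$points
  for (j in seq_len(ncol(coords))) {
    s <- sign(coords[which.max(abs(coords[, j])), j])
    if (s < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- eig[eig > 0]
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = if (length(pos))
         eig[seq_len(ncol(coords))] / sum(pos) else rep(NA_real_, ncol(coords)))
}
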