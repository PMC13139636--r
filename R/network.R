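#' Build a filtered Spearman co-occurrence network
#'
#' Applies the usual pre-filter (mean relative abundance and prevalence),
#' computes all-pairs Spearman correlations on relative abundances (mid-ranked
#' ties), two-sided p-values by the t approximation, Benjamini-Hochberg
#' correction across all pairs, and keeps edges with `|rho| > rho_min` and
#' `q < q_max`.
#'
#' @param ct samples x taxa count matrix (>= 5 samples).
#' @param min_mean_relabund,min_prevalence pre-filter thresholds
#'   (defaults: 0.01% mean abundance, 30% prevalence).
#' @param rho_min absolute correlation threshold (strict).
#' @param q_max FDR threshold (strict).
#' @return object of class `cooc_network`: `nodes` (taxon ids) and `edges`
#'   data.frame (`u`, `v`, `rho`, `p`, `q`, `sign`).
#' @export
build_network <- function(ct, min_mean_relabund = 1e-4, min_prevalence = 0.3,
                          rho_min = 0.6, q_max = 0.05) {
  if (nrow(ct) < 5) stop("need at least 5 samples")
  kept <- filter_taxa(ct, min_mean_relabund, min_prevalence)
  if (ncol(kept) < 2) {
    warning("fewer than two taxa survive the filter; empty network")
    return(structure(list(nodes = colnames(kept),
                          edges = data.frame(u = character(), v = character(),
                                             rho = numeric(), p = numeric(),
                                             q = numeric(), sign = character(),
                                             stringsAsFactors = FALSE)),
                     class = "cooc_network"))
  }
  rel <- to_relative(kept)
  rho <- stats::cor(rel, method = "spearman")
  n <- nrow(rel)
  iu <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[iu]
  # two-sided p by the t approximation, guarding |rho| = 1
  tstat <- r * sqrt(pmax((n - 2) / pmax(1 - r^2, 1e-12), 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- stats::p.adjust(p, method = "BH")
  pass <- abs(r) > rho_min & q < q_max
  edges <- data.frame(u = colnames(rel)[iu[pass, 1]],
                      v = colnames(rel)[iu[pass, 2]],
                      rho = r[pass], p = p[pass], q = q[pass],
                      sign = ifelse(r[pass] >= 0, "positive", "negative"),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(nodes = colnames(rel), edges = edges), class = "cooc_network")
}

as_igraph_ <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("u", "v")], directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Topological statistics of a co-occurrence network
#'
#' Node-level: degree, closeness (harmonic centrality by default, robust to
#' disconnected graphs; classical closeness behind `closeness = "classic"`),
#' betweenness (Brandes, unnormalised) and eccentricity (within each node's
#' connected component). Network-level: edge counts by sign, average degree,
#' density, average local clustering coefficient (degree < 2 nodes contribute
#' 0), average path length over reachable pairs, and modularity of a
#' deterministic greedy community partition of the unweighted graph.
#'
#' @param net a `cooc_network`.
#' @param closeness `"harmonic"` (default) or `"classic"`.
#' @return list with scalar fields (`n_nodes`, `n_edges`, `positive_edges`,
#'   `negative_edges`, `avg_degree`, `density`, `avg_clustering`,
#'   `avg_path_length`, `modularity`) and a `nodes` data.frame.
#' @export
network_stats <- function(net, closeness = c("harmonic", "classic")) {
  closeness <- match.arg(closeness)
  if (!length(net$nodes)) stop("empty network")
  g <- as_igraph_(net)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  clo <- if (closeness == "harmonic")
    igraph::harmonic_centrality(g, normalized = TRUE)
  else suppressWarnings(igraph::closeness(g, normalized = TRUE))
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  ecc <- igraph::eccentricity(g, mode = "all")
  local_cc <- igraph::transitivity(g, type = "localundirected",
                                   isolates = "zero")
  comm <- igraph::cluster_fast_greedy(igraph::simplify(g))
  list(n_nodes = n, n_edges = m,
       positive_edges = sum(net$edges$sign == "positive"),
       negative_edges = sum(net$edges$sign == "negative"),
       avg_degree = 2 * m / n,
       density = if (n > 1) 2 * m / (n * (n - 1)) else 0,
       avg_clustering = mean(local_cc),
       avg_path_length = igraph::mean_distance(g, unconnected = TRUE),
       modularity = igraph::modularity(comm),
       nodes = data.frame(taxon = igraph::V(g)$name, degree = deg,
                          closeness = clo, betweenness = btw,
                          eccentricity = ecc, row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Export a network as edge-list TSV (and optionally GraphML)
#'
#' @param net a `cooc_network`.
#' @param path TSV output path.
#' @param graphml_path optional GraphML output path.
#' @export
write_network <- function(net, path, graphml_path = NULL) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph_(net), graphml_path, format = "graphml")
  invisible(path)
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("Co-occurrence network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (",
      sum(x$edges$sign == "positive"), "positive /",
      sum(x$edges$sign == "negative"), "negative )\n")
  invisible(x)
}
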