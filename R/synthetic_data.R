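#' Specification for the two-enterotype synthetic dataset
#'
#' Builds the parameter object consumed by [simulate_enterotype_dataset()].
#' Defaults emulate the study design the pipeline targets: 97 wild-rodent gut
#' samples in two compositional clusters of unequal size (63/34), ~2000 ASVs
#' in ~150 genera split across two phyla ("Bacillota_like" favoured by cluster
#' 2, "Bacteroidota_like" by cluster 1), lognormal sequencing depths around
#' 30k reads, cluster-linked host body weight (and hence BMI), and
#' season/habitat labels with cluster-dependent frequencies.
#'
#' @param n_samples integer vector, samples per cluster.
#' @param n_taxa number of ASVs.
#' @param n_genera number of genera the ASVs are binned into.
#' @param theta Dirichlet concentration of per-sample compositions around the
#'   cluster base composition (larger = tighter clusters).
#' @param base_compositions optional list of per-cluster probability vectors
#'   of length `n_taxa`; built from the seed when `NULL`.
#' @param separation_sd lognormal sd of the per-genus cluster tilt used when
#'   base compositions are auto-built.
#' @param phylum_shift multiplicative enrichment of each cluster's favoured
#'   phylum in the auto-built base compositions.
#' @param depth_log_mean,depth_log_sd lognormal read-depth parameters.
#' @param trait_means per-cluster mean body weight (g).
#' @param trait_sd body-weight sd (g).
#' @param seed integer seed; the generator is a pure function of this spec.
#' @return a list of class `enterotype_sim_spec`.
#' @export
enterotype_sim_spec <- function(n_samples = c(63L, 34L), n_taxa = 2000L,
                                n_genera = 150L, theta = 50,
                                base_compositions = NULL,
                                separation_sd = 1.0, phylum_shift = 2.5,
                                depth_log_mean = log(30000),
                                depth_log_sd = 0.3,
                                trait_means = c(230, 270), trait_sd = 35,
                                seed = 1L) {
  stopifnot(length(n_samples) == 2, all(n_samples >= 1), theta > 0,
            n_taxa >= 2, n_genera >= 2, n_genera <= n_taxa,
            length(trait_means) == 2, trait_sd > 0,
            exp(depth_log_mean - 3 * depth_log_sd) >= 100)
  if (!is.null(base_compositions)) {
    stopifnot(length(base_compositions) == 2)
    for (q in base_compositions) {
      if (length(q) != n_taxa)
        stop("base composition length (", length(q),
             ") does not match n_taxa (", n_taxa, ")")
      stopifnot(all(q >= 0), abs(sum(q) - 1) < 1e-9)
    }
  }
  structure(list(n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
                 n_genera = as.integer(n_genera), theta = theta,
                 base_compositions = base_compositions,
                 separation_sd = separation_sd, phylum_shift = phylum_shift,
                 depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
                 trait_means = trait_means, trait_sd = trait_sd,
                 seed = as.integer(seed)),
            class = "enterotype_sim_spec")
}

# Season / habitat frequencies by cluster (cluster 1 occurs in all seasons
# and spreads over habitats; cluster 2 is mostly a spring/woodland type).
SEASON_PROBS <- list(c(spring = 37, summer = 11, autumn = 15) / 63,
                     c(spring = 31, summer = 3, autumn = 0) / 34)
HABITAT_PROBS <- list(c(woodland = 22, farmland = 25, grassland = 16) / 63,
                      c(woodland = 18, farmland = 12, grassland = 4) / 34)

# Shared genus backbone + cluster-specific tilts -> per-cluster ASV weights.
build_base_compositions_ <- function(spec) {
  g_of_taxon <- sort(c(seq_len(spec$n_genera),           # every genus nonempty
                       sample.int(spec$n_genera, spec$n_taxa - spec$n_genera,
                                  replace = TRUE)))
  backbone <- (seq_len(spec$n_genera))^-0.9 * exp(stats::rnorm(spec$n_genera, 0, 0.5))
  phylum <- ifelse(stats::runif(spec$n_genera) < 0.55,
                   "Bacillota_like", "Bacteroidota_like")
  within <- exp(stats::rnorm(spec$n_taxa, 0, 1))          # ASV share of its genus
  qs <- vector("list", 2)
  for (k in 1:2) {
    tilt <- exp(stats::rnorm(spec$n_genera, 0, spec$separation_sd))
    fav <- if (k == 1) "Bacteroidota_like" else "Bacillota_like"
    tilt[phylum == fav] <- tilt[phylum == fav] * spec$phylum_shift
    gw <- backbone * tilt
    w <- gw[g_of_taxon] * within
    qs[[k]] <- w / sum(w)
  }
  list(q = qs, genus = g_of_taxon, phylum = phylum)
}

#' Simulate a two-enterotype ASV dataset
#'
#' Per sample: composition `p ~ Dirichlet(theta * q_k)`, reads
#' `~ Multinomial(depth, p)` with `depth ~ Lognormal`. Body weight is
#' `Normal(trait_means[k], trait_sd)`; body and tail length are
#' cluster-independent; BMI = weight / length^2. Cluster sub-streams are
#' seeded from the cluster's own parameters, so swapping the two clusters'
#' `base_compositions` and `trait_means` (with equal sizes) swaps the
#' generated blocks exactly.
#'
#' @param spec an [enterotype_sim_spec()].
#' @return list with `counts` (samples x taxa), `taxonomy` (data.frame),
#'   `metadata` (data.frame) and `labels` (integer true cluster per sample).
#' @export
simulate_enterotype_dataset <- function(spec) {
  stopifnot(inherits(spec, "enterotype_sim_spec"))
  base <- with_seed_(stage_seed(spec$seed, "base_composition"), {
    if (is.null(spec$base_compositions)) build_base_compositions_(spec)
    else list(q = spec$base_compositions,
              genus = rep(seq_len(spec$n_genera), length.out = spec$n_taxa),
              phylum = rep(c("Bacillota_like", "Bacteroidota_like"),
                           length.out = spec$n_genera))
  })
  taxon_ids <- sprintf("asv_%04d", seq_len(spec$n_taxa))
  genus_names <- sprintf("genus_%03d", seq_len(spec$n_genera))
  taxonomy <- data.frame(
    taxon_id = taxon_ids, domain = "Bacteria",
    phylum = base$phylum[base$genus],
    class = paste0("class_", base$phylum[base$genus]),
    order = paste0("order_", base$genus %% 20L),
    family = paste0("family_", base$genus %% 60L),
    genus = genus_names[base$genus], species = "",
    stringsAsFactors = FALSE)

  n_tot <- sum(spec$n_samples)
  counts <- matrix(0L, n_tot, spec$n_taxa,
                   dimnames = list(sprintf("sample_%03d", seq_len(n_tot)),
                                   taxon_ids))
  labels <- rep(1:2, times = spec$n_samples)
  weight <- length <- tail_len <- numeric(n_tot)
  season <- habitat <- character(n_tot)

  row0 <- 0L
  for (k in 1:2) {
    nk <- spec$n_samples[k]
    qk <- base$q[[k]]
    # sub-stream keyed by the cluster's own parameters -> exact swap symmetry
    key <- paste0("cluster:", format(spec$trait_means[k], digits = 15), ":",
                  format(sum(qk * seq_along(qk)) %% 1e6, digits = 15))
    with_seed_(stage_seed(spec$seed, key), {
      for (i in seq_len(nk)) {
        depth <- max(100, round(stats::rlnorm(1, spec$depth_log_mean,
                                              spec$depth_log_sd)))
        gam <- stats::rgamma(spec$n_taxa, shape = spec$theta * qk)
        if (sum(gam) == 0) gam[which.max(qk)] <- 1
        p <- gam / sum(gam)
        counts[row0 + i, ] <- as.integer(stats::rmultinom(1, depth, p))
        weight[row0 + i] <- stats::rnorm(1, spec$trait_means[k], spec$trait_sd)
        length[row0 + i] <- stats::rnorm(1, 17.5, 1.2)
        tail_len[row0 + i] <- stats::rnorm(1, 4.2, 0.5)
      }
      season[row0 + seq_len(nk)] <- sample(names(SEASON_PROBS[[k]]), nk,
                                            replace = TRUE,
                                            prob = SEASON_PROBS[[k]])
      habitat[row0 + seq_len(nk)] <- sample(names(HABITAT_PROBS[[k]]), nk,
                                             replace = TRUE,
                                             prob = HABITAT_PROBS[[k]])
    })
    row0 <- row0 + nk
  }
  metadata <- data.frame(sample_id = rownames(counts), season = season,
                         habitat = habitat, body_weight = round(weight, 1),
                         body_length = round(length, 1),
                         tail_length = round(tail_len, 1),
                         stringsAsFactors = FALSE)
  metadata$bmi <- metadata$body_weight / metadata$body_length^2
  validate_count_table(counts)
  list(counts = counts, taxonomy = taxonomy, metadata = metadata,
       labels = labels)
}

#' Specification for neutral community simulation
#'
#' @param metacommunity_props probability vector over taxa (source pool).
#' @param local_size individuals per local community.
#' @param migration probability that a death is replaced by an immigrant.
#' @param n_samples number of local communities.
#' @param reads_per_sample multinomial read depth per sample.
#' @param burn_in_steps number of generations (each = `local_size` events).
#' @param seed integer seed.
#' @return a list of class `neutral_sim_spec`.
#' @export
neutral_sim_spec <- function(metacommunity_props, local_size = 1000L,
                             migration = 0.1, n_samples = 50L,
                             reads_per_sample = local_size,
                             burn_in_steps = 200L, seed = 1L) {
  stopifnot(migration > 0, migration <= 1, local_size >= 10,
            abs(sum(metacommunity_props) - 1) < 1e-9,
            all(metacommunity_props >= 0), n_samples >= 1, burn_in_steps >= 1)
  structure(list(metacommunity_props = metacommunity_props,
                 local_size = as.integer(local_size), migration = migration,
                 n_samples = as.integer(n_samples),
                 reads_per_sample = as.integer(reads_per_sample),
                 burn_in_steps = as.integer(burn_in_steps),
                 seed = as.integer(seed)),
            class = "neutral_sim_spec")
}

#' Simulate neutral local communities (Moran dynamics)
#'
#' Each local community starts as a multinomial draw from the metacommunity
#' and is then evolved by serial death-replacement: with probability
#' `migration` the replacement immigrates from the metacommunity, otherwise it
#' copies a random local individual. Read counts are a multinomial subsample
#' of the final community.
#'
#' @param spec a [neutral_sim_spec()].
#' @return samples x taxa count matrix.
#' @export
simulate_neutral_communities <- function(spec) {
  stopifnot(inherits(spec, "neutral_sim_spec"))
  S <- length(spec$metacommunity_props)
  cum <- cumsum(spec$metacommunity_props)
  counts <- with_seed_(spec$seed, {
    out <- matrix(0L, spec$n_samples, S)
    events <- as.numeric(spec$burn_in_steps) * spec$local_size
    for (s in seq_len(spec$n_samples)) {
      comm <- sample.int(S, spec$local_size, replace = TRUE,
                         prob = spec$metacommunity_props) - 1L
      comm <- cpp_moran(comm, cum, spec$migration, events)
      props <- tabulate(comm + 1L, nbins = S) / spec$local_size
      out[s, ] <- as.integer(stats::rmultinom(1, spec$reads_per_sample, props))
    }
    out
  })
  dimnames(counts) <- list(sprintf("sample_%03d", seq_len(spec$n_samples)),
                           sprintf("asv_%04d", seq_len(S)))
  counts
}

#' Specification for selection-structured community simulation
#'
#' Two environmental-filter kernels are available. `filter = "lineage"`
#' (default) models a perfectly phylogenetically conserved habitat affinity:
#' the kernel is `exp(-d(i, focal)^2 / (2 tau^2))` with `d` the patristic
#' distance to a focal lineage, so selected communities are drawn from a
#' clade. `filter = "trait"` evolves a trait by Brownian motion (rate
#' `sigma2`) and uses `exp(-(trait_i - optimum)^2 / (2 tau^2))`; this is the
#' textbook construction but, because a Brownian trait is only loosely tied
#' to tree position, it yields much weaker phylogenetic clustering at small
#' taxon pools.
#'
#' The kernel is applied either as `mode = "occupancy"` (default: presence is
#' Bernoulli(kernel), abundances lognormal among the retained taxa — strong,
#' turnover-rich selection) or `mode = "weight"` (multinomial weight
#' proportional to kernel x base abundance).
#'
#' @param tree rooted `phylo` tree over the taxa (tips become taxon ids).
#' @param sigma2 Brownian-motion rate of the latent trait (`filter="trait"`).
#' @param optima per-sample optimum: trait values (`filter = "trait"`) or
#'   focal tip labels (`filter = "lineage"`); for the lineage filter `NULL`
#'   means one shared focal lineage at the centre of the densest clade.
#' @param tau filter width; small `tau` = strong selection, `tau -> Inf`
#'   recovers neutral weighting. Ignored when `target_richness` is set.
#' @param n_samples number of samples when `optima` is `NULL`.
#' @param target_richness if non-`NULL` (lineage filter), `tau` is calibrated
#'   so the expected number of retained taxa equals this value.
#' @param abundance_sd lognormal sd of per-sample abundance variation.
#' @param depth reads per sample.
#' @param seed integer seed.
#' @return a list of class `selection_sim_spec`.
#' @export
selection_sim_spec <- function(tree, sigma2 = 1, optima = NULL, tau = 0.3,
                               n_samples = 30L, target_richness = NULL,
                               abundance_sd = 0.3, depth = 500L, seed = 1L,
                               filter = c("lineage", "trait"),
                               mode = c("occupancy", "weight")) {
  filter <- match.arg(filter)
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"), sigma2 > 0, tau > 0, depth >= 100)
  if (is.null(optima) && filter == "trait")
    stop("the trait filter requires explicit per-sample optima")
  if (!is.null(optima)) n_samples <- length(optima)
  stopifnot(n_samples >= 2)
  structure(list(tree = tree, sigma2 = sigma2, optima = optima, tau = tau,
                 n_samples = as.integer(n_samples),
                 target_richness = target_richness,
                 abundance_sd = abundance_sd,
                 depth = as.integer(depth), seed = as.integer(seed),
                 filter = filter, mode = mode),
            class = "selection_sim_spec")
}

#' Simulate communities assembled under environmental selection
#'
#' Applies the filter kernel described in [selection_sim_spec()]: samples
#' sharing an optimum share a phylogenetically clustered set of taxa (strong
#' homogeneous-selection signal, betaNTI << 0 for within-group pairs), while
#' samples with divergent optima are phylogenetically overdispersed relative
#' to each other.
#'
#' @param spec a [selection_sim_spec()].
#' @return list with `counts` (samples x tips), `tree` and the realised
#'   per-sample `optima`.
#' @export
simulate_selection_communities <- function(spec) {
  stopifnot(inherits(spec, "selection_sim_spec"))
  tips <- spec$tree$tip.label
  S <- length(tips)
  n <- spec$n_samples
  with_seed_(spec$seed, {
    base <- exp(stats::rnorm(S, 0, spec$abundance_sd))
    if (spec$filter == "trait") {
      trait <- ape::rTraitCont(spec$tree, model = "BM",
                               sigma = sqrt(spec$sigma2))
      kernel <- function(opt) exp(-(trait - opt)^2 / (2 * spec$tau^2))
      optima <- spec$optima
    } else {
      D <- stats::cophenetic(spec$tree)
      optima <- spec$optima
      if (is.null(optima)) {
        # focal lineage at the centre of the densest clade: the tip whose
        # k-th nearest neighbour is closest, k ~ the target community size
        k <- min(S - 1, (if (is.null(spec$target_richness)) 15
                         else spec$target_richness) + 5)
        kth <- apply(D, 1, function(z) sort(z)[k + 1])
        optima <- rep(tips[which.min(kth)], n)
      }
      tau <- spec$tau
      if (!is.null(spec$target_richness)) {
        dfoc <- D[optima[1], ]
        tau <- stats::uniroot(function(t)
          sum(exp(-dfoc^2 / (2 * t^2))) - spec$target_richness,
          c(1e-4, 100) * max(D))$root
      }
      kernel <- function(opt) exp(-D[opt, ]^2 / (2 * tau^2))
    }
    counts <- matrix(0L, n, S,
                     dimnames = list(sprintf("sample_%03d", seq_len(n)), tips))
    for (s in seq_len(n)) {
      kap <- kernel(optima[s])
      if (spec$mode == "occupancy") {
        keep <- stats::runif(S) < kap
        if (sum(keep) < 3) keep[order(-kap)[1:3]] <- TRUE
        w <- base * exp(stats::rnorm(S, 0, spec$abundance_sd)) * keep
      } else {
        w <- base * kap
        if (sum(w) <= 0) w <- base
      }
      counts[s, ] <- as.integer(stats::rmultinom(1, spec$depth, w / sum(w)))
    }
    list(counts = counts, tree = spec$tree, optima = optima)
  })
}

#' Simulate a pure-birth (Yule) tree
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param ultrametric if `TRUE`, keep the birth-process (ultrametric) branch
#'   lengths; otherwise branch lengths are redrawn iid exponential(1).
#' @param tip_labels optional character vector of tip labels.
#' @return a rooted `phylo` tree.
#' @export
simulate_yule_tree <- function(n_tips, seed = 1L, ultrametric = FALSE,
                               tip_labels = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  with_seed_(seed, {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    if (!ultrametric) tr$edge.length <- stats::rexp(nrow(tr$edge))
  })
  tr$tip.label <- if (is.null(tip_labels))
    sprintf("asv_%04d", seq_len(n_tips)) else tip_labels
  tr
}
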