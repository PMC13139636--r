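#' Pipeline configuration
#'
#' Collects inputs, thresholds and stage toggles for [run_pipeline()].
#' Inputs may be in-memory objects (count matrix, taxonomy/metadata
#' data.frames, `phylo` tree) or file paths readable by the core readers.
#' Threshold defaults are the conventional values used throughout the
#' package: prevalence 0.30 and mean relative abundance 1e-4 for the
#' network/niche pre-filter, `|rho| > 0.6` with FDR `q < 0.05` for network
#' edges, LDA score 2.5 with `alpha = 0.05` for biomarkers, candidate
#' `k = 2..6` for enterotyping, 999 permutations for distance-based tests
#' and null models (1000 for the niche null), and a 70/30 classifier split.
#'
#' @param counts count table (samples x taxa matrix) or TSV path.
#' @param taxonomy taxonomy data.frame or TSV path.
#' @param metadata sample metadata data.frame or TSV path (optional).
#' @param tree `phylo` or Newick path (optional; required for the assembly
#'   stage and for Faith PD).
#' @param seed integer seed (mandatory); per-stage streams are derived from
#'   it, so toggling one stage does not shift another stage's randomness.
#' @param k_range candidate numbers of enterotypes.
#' @param min_mean_relabund,min_prevalence network/niche pre-filter.
#' @param assembly_min_relabund abundance-only pre-filter for betaNTI/RC.
#' @param rho_min,q_max network edge thresholds.
#' @param lda_threshold,alpha biomarker thresholds.
#' @param n_perm permutations (PERMANOVA/PERMDISP/RDA and null models).
#' @param n_perm_niche permutations for the niche null.
#' @param split classifier training fraction.
#' @param stages named logical vector/list enabling optional stages
#'   (`diversity`, `differential`, `network`, `assembly`, `niche`,
#'   `association`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, taxonomy, metadata = NULL, tree = NULL,
                            seed, k_range = 2:6,
                            min_mean_relabund = 1e-4, min_prevalence = 0.3,
                            assembly_min_relabund = 1e-4,
                            rho_min = 0.6, q_max = 0.05,
                            lda_threshold = 2.5, alpha = 0.05,
                            n_perm = 999, n_perm_niche = 1000, split = 0.7,
                            stages = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  st <- list(diversity = TRUE, differential = TRUE, network = TRUE,
             assembly = TRUE, niche = TRUE, association = TRUE)
  if (!is.null(stages)) {
    bad <- setdiff(names(stages), names(st))
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    st[names(stages)] <- as.logical(stages)
  }
  stopifnot(min_mean_relabund >= 0, min_mean_relabund <= 1,
            min_prevalence >= 0, min_prevalence <= 1,
            rho_min >= 0, rho_min <= 1, q_max > 0, q_max <= 1,
            lda_threshold >= 0, alpha > 0, alpha <= 1,
            n_perm >= 1, n_perm_niche >= 1, split > 0, split < 1)
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata,
                 tree = tree, seed = as.integer(seed), k_range = k_range,
                 min_mean_relabund = min_mean_relabund,
                 min_prevalence = min_prevalence,
                 assembly_min_relabund = assembly_min_relabund,
                 rho_min = rho_min, q_max = q_max,
                 lda_threshold = lda_threshold, alpha = alpha,
                 n_perm = n_perm, n_perm_niche = n_perm_niche, split = split,
                 stages = st),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; input paths are
#' resolved relative to the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("counts", "taxonomy", "metadata", "tree"))
    if (!is.null(y[[f]]) && !file.exists(y[[f]]))
      y[[f]] <- file.path(base, y[[f]])
  do.call(pipeline_config, y)
}

load_inputs_ <- function(cfg) {
  list(
    counts = if (is.character(cfg$counts)) read_count_table(cfg$counts)
             else validate_count_table(cfg$counts),
    taxonomy = if (is.character(cfg$taxonomy)) read_taxonomy(cfg$taxonomy)
               else cfg$taxonomy,
    metadata = if (is.character(cfg$metadata)) read_sample_metadata(cfg$metadata)
               else cfg$metadata,
    tree = if (is.character(cfg$tree)) read_phylo_tree(cfg$tree) else cfg$tree)
}

stage_ <- function(name, enabled, code) {
  if (!enabled) return(NULL)
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(code), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full enterotype analysis pipeline
#'
#' Orchestrates enterotyping, then (per enterotype where applicable)
#' diversity, biomarker discovery, co-occurrence networks, assembly-process
#' partitioning and niche classification, and finally the trait/diversity
#' redundancy analysis. The run is a pure function of the configuration:
#' repeating it with the same config yields a byte-identical JSON report.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir optional directory for per-stage TSV/JSON outputs.
#' @return the report as a nested list (class `pipeline_report`).
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  inp <- stage_("load", TRUE, load_inputs_(cfg))
  if (cfg$stages$assembly && is.null(inp$tree))
    stop("the assembly stage requires a phylogenetic tree; supply `tree` ",
         "or disable the stage")
  ct <- inp$counts
  report <- list(seed = cfg$seed, n_samples = nrow(ct), n_taxa = ncol(ct))

  ent <- stage_("enterotyping", TRUE,
                select_enterotypes(ct, inp$taxonomy, k_range = cfg$k_range))
  groups <- factor(paste0("E", ent$labels))
  two_groups <- ent$chosen_k == 2
  report$enterotyping <- list(
    chosen_k = ent$chosen_k,
    group_sizes = as.list(table(groups)),
    ch_by_k = as.list(ent$ch_by_k),
    silhouette_by_k = as.list(ent$silhouette_by_k),
    medoids = ent$medoids)

  genus_ct <- collapse_rank(ct, inp$taxonomy, "genus")
  genus_rel <- to_relative(genus_ct)

  report$diversity <- stage_("diversity", cfg$stages$diversity, {
    alpha <- alpha_diversity(ct, inp$tree)
    bc <- bray_curtis(ct)
    pmv <- permanova(bc, groups, cfg$n_perm,
                     seed = stage_seed(cfg$seed, "permanova"))
    pdp <- permdisp(bc, groups, cfg$n_perm,
                    seed = stage_seed(cfg$seed, "permdisp"))
    ord <- pcoa(bc, 2)
    ups <- upset_partition(ct, groups)
    cmp <- if (two_groups)
      compare_groups(alpha[, -1], groups, test = "mannwhitney")
    list(alpha = alpha, permanova = pmv, permdisp = pdp,
         pcoa_prop_explained = ord$proportion_explained[1:2],
         upset = ups, alpha_tests = cmp)
  })

  report$differential <- stage_("differential",
                                cfg$stages$differential && two_groups, {
    lef <- lefse_like(genus_rel, groups, alpha = cfg$alpha,
                      lda_threshold = cfg$lda_threshold,
                      seed = stage_seed(cfg$seed, "lefse"))
    smp <- simper(genus_rel, groups)
    scr <- screen_classifiers(genus_rel, groups, split = cfg$split,
                              seed = stage_seed(cfg$seed, "screen"))
    list(lefse = lef, simper_top = utils::head(smp, 15),
         auc = as.list(scr$auc), best_model = scr$best_model,
         top_importance = utils::head(scr$importance, 15))
  })

  per_group <- function(fun) {
    out <- lapply(levels(groups), function(g)
      fun(ct[groups == g, , drop = FALSE], g))
    stats::setNames(out, levels(groups))
  }

  report$network <- stage_("network", cfg$stages$network, per_group(
    function(sub, g) {
      net <- build_network(sub, cfg$min_mean_relabund, cfg$min_prevalence,
                           cfg$rho_min, cfg$q_max)
      if (!nrow(net$edges))
        return(list(n_nodes = length(net$nodes), n_edges = 0))
      st <- network_stats(net)
      st$nodes <- NULL
      st
    }))

  report$assembly <- stage_("assembly", cfg$stages$assembly, per_group(
    function(sub, g) {
      ncm <- fit_ncm(sub)
      filt <- filter_taxa(sub, cfg$assembly_min_relabund, 0)
      bnti <- beta_nti(filt, inp$tree, n_null = cfg$n_perm,
                       seed = stage_seed(cfg$seed, paste0("bnti_", g)))
      rc <- raup_crick_bray(filt, n_null = cfg$n_perm,
                            seed = stage_seed(cfg$seed, paste0("rc_", g)))
      cls <- classify_processes(bnti$bnti, rc)
      list(ncm = list(m = ncm$m, N = ncm$N, Nm = ncm$Nm, r2 = ncm$r2),
           median_bnti = stats::median(bnti$bnti[upper.tri(bnti$bnti)]),
           process_fractions = as.list(cls$fractions))
    }))

  report$niche <- stage_("niche", cfg$stages$niche, {
    out <- per_group(function(sub, g) {
      filt <- filter_taxa(sub, cfg$min_mean_relabund, cfg$min_prevalence)
      nc <- classify_niche(filt, n_perm = cfg$n_perm_niche,
                           seed = stage_seed(cfg$seed, paste0("niche_", g)))
      list(mean_B = nc$mean_B, fractions = as.list(nc$fractions))
    })
    if (two_groups) {
      cmp <- compare_group_breadth(ct, groups)
      out$breadth_comparison <- list(median_B = as.list(cmp$median_B),
                                     p = cmp$p)
    }
    out
  })

  report$association <- stage_("association",
                               cfg$stages$association && !is.null(inp$metadata), {
    alpha <- alpha_diversity(ct, inp$tree)
    md <- inp$metadata[match(rownames(ct), inp$metadata$sample_id), ]
    cand <- cbind(alpha[, setdiff(names(alpha), "sample_id")],
                  md[, c("body_weight", "body_length", "tail_length", "bmi")])
    retained <- collinearity_filter(cand, r_max = 0.6)
    expl <- data.frame(cand[, retained, drop = FALSE],
                       enterotype = groups)
    rd <- rda_fit(genus_ct, expl, n_perm = cfg$n_perm,
                  seed = stage_seed(cfg$seed, "rda"))
    list(retained_variables = retained, F = rd$F, p = rd$p,
         constrained_fraction = rd$constrained_fraction,
         terms = rd$terms)
  })

  report <- structure(report, class = c("pipeline_report", "list"))
  if (!is.null(outdir)) write_report_(report, ent, outdir)
  report
}

#' Serialise a pipeline report to JSON
#'
#' @param report a `pipeline_report`.
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(strip_classes_(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(path)
}

strip_classes_ <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (is.list(x)) return(lapply(unclass(x), strip_classes_))
  if (is.table(x)) return(as.list(x))
  x
}

write_report_ <- function(report, ent, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  add <- function(f) files <<- c(files, f)
  write_report_json(report, file.path(outdir, "report.json"))
  add("report.json")
  utils::write.table(
    data.frame(sample_id = names(ent$labels),
               enterotype = paste0("E", ent$labels)),
    file.path(outdir, "enterotypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  add("enterotypes.tsv")
  writeLines(files, file.path(outdir, "MANIFEST"))
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report:", x$n_samples, "samples,", x$n_taxa, "taxa\n")
  cat("  enterotypes: k =", x$enterotyping$chosen_k, "; sizes",
      paste(unlist(x$enterotyping$group_sizes), collapse = "/"), "\n")
  if (!is.null(x$assembly))
    for (g in setdiff(names(x$assembly), "breadth_comparison"))
      cat(sprintf("  %s: NCM m = %.3f (R2 = %.2f); homogeneous selection %.1f%%, drift %.1f%%\n",
                  g, x$assembly[[g]]$ncm$m, x$assembly[[g]]$ncm$r2,
                  100 * x$assembly[[g]]$process_fractions$homogeneous_selection,
                  100 * x$assembly[[g]]$process_fractions$drift))
  invisible(x)
}
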