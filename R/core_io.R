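#' @useDynLib enterostrat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Validate a count table
#'
#' A count table is an integer matrix with samples as rows and taxa (ASVs,
#' genera, ...) as columns, unique non-empty dimnames, non-negative integer
#' cells and a positive total per sample.
#'
#' @param ct matrix to validate.
#' @return `ct`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_count_table <- function(ct) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("count table must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("count table must carry sample and taxon identifiers as dimnames")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct)))
    stop("duplicate taxon identifiers: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  if (any(ct < 0)) {
    bad <- which(ct < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(ct)[bad[1]], colnames(ct)[bad[2]]))
  }
  if (any(abs(ct - round(ct)) > 1e-8)) {
    bad <- which(abs(ct - round(ct)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', taxon '%s'",
                 rownames(ct)[bad[1]], colnames(ct)[bad[2]]))
  }
  tot <- rowSums(ct)
  if (any(tot <= 0))
    stop("sample(s) with zero total counts: ",
         paste(rownames(ct)[tot <= 0], collapse = ", "))
  invisible(ct)
}

#' Read a count table from TSV
#'
#' Reads a tab-delimited table of integer counts. By convention files are
#' taxa-as-rows / samples-as-columns (the usual QIIME-style export);
#' set `taxa_as_rows = FALSE` if the file is already samples-as-rows. The
#' returned matrix is always samples x taxa, in file order.
#'
#' @param path path to a TSV file; first column holds row identifiers.
#' @param taxa_as_rows logical; orientation of the file on disk.
#' @return validated samples x taxa integer matrix.
#' @export
read_count_table <- function(path, taxa_as_rows = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, quote = "", comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("count table '", path, "' contains non-numeric cells")
  if (taxa_as_rows) m <- t(m)
  storage.mode(m) <- "double"
  validate_count_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count table to TSV
#'
#' @param ct samples x taxa count matrix.
#' @param path output file.
#' @param taxa_as_rows write taxa-as-rows (default, round-trips with
#'   [read_count_table()]).
#' @export
write_count_table <- function(ct, path, taxa_as_rows = TRUE) {
  validate_count_table(ct)
  m <- if (taxa_as_rows) t(ct) else ct
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (taxa_as_rows) "taxon_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Accepts either a TSV with taxon_id plus seven rank columns
#' (domain..species) or a two-column TSV whose second column is a
#' semicolon-delimited lineage string (`k__...;p__...;...`); the format is
#' auto-detected. Unassigned ranks become empty strings.
#'
#' @param path TSV path.
#' @return data.frame with columns `taxon_id` and the seven ranks.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) == 2) {
    parts <- strsplit(df[[2]], ";", fixed = TRUE)
    lin <- t(vapply(parts, function(p) {
      p <- sub("^\\s*[a-z]__", "", trimws(p))
      length(p) <- length(TAX_RANKS)
      p[is.na(p)] <- ""
      p
    }, character(length(TAX_RANKS))))
    out <- data.frame(taxon_id = df[[1]], lin, stringsAsFactors = FALSE)
    names(out) <- c("taxon_id", TAX_RANKS)
  } else if (ncol(df) == length(TAX_RANKS) + 1) {
    out <- df
    names(out) <- c("taxon_id", TAX_RANKS)
  } else {
    stop("taxonomy file must have 2 or ", length(TAX_RANKS) + 1, " columns")
  }
  if (anyDuplicated(out$taxon_id))
    stop("duplicate taxon_id in taxonomy: ",
         paste(unique(out$taxon_id[duplicated(out$taxon_id)]), collapse = ", "))
  out[is.na(out)] <- ""
  out
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `season` (spring/summer/autumn), `habitat`
#' (woodland/farmland/grassland), `body_weight` (g), `body_length` (cm),
#' `tail_length` (cm) and optionally `bmi` (g/cm^2). BMI is derived as
#' body_weight / body_length^2 when absent, and checked to 1e-9 when present.
#'
#' @param path TSV path.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  need <- c("sample_id", "season", "habitat", "body_weight", "body_length",
            "tail_length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(df$season), c("spring", "summer", "autumn"))
  if (length(bad)) stop("unknown season value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$habitat), c("woodland", "farmland", "grassland"))
  if (length(bad)) stop("unknown habitat value(s): ", paste(bad, collapse = ", "))
  bmi <- df$body_weight / df$body_length^2
  if ("bmi" %in% names(df)) {
    ok <- is.na(df$bmi) | abs(df$bmi - bmi) <= 1e-9
    if (!all(ok)) stop("bmi inconsistent with body_weight/body_length^2 for: ",
                       paste(df$sample_id[!ok], collapse = ", "))
    df$bmi[is.na(df$bmi)] <- bmi[is.na(df$bmi)]
  } else df$bmi <- bmi
  df
}

#' Read a rooted phylogenetic tree (Newick)
#'
#' @param path Newick file.
#' @return an `ape::phylo` tree, validated for unique tips and non-negative
#'   branch lengths.
#' @export
read_phylo_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("tree has duplicate tip labels")
  tr
}

#' Convert counts to relative abundances
#'
#' @param ct samples x taxa count (or abundance) matrix with positive row sums.
#' @return matrix of the same shape whose rows sum to one.
#' @export
to_relative <- function(ct) {
  tot <- rowSums(ct)
  if (any(tot <= 0))
    stop("sample(s) with zero total: ",
         paste(rownames(ct)[tot <= 0], collapse = ", "))
  ct / tot
}

#' Collapse a count table to a taxonomic rank
#'
#' Sums ASV counts into lineage labels at `rank`. Taxa unassigned at that rank
#' are pooled into one `unclassified_<parent>` bucket per parent lineage so
#' per-sample totals are conserved exactly.
#'
#' @param ct samples x taxa count matrix.
#' @param tax taxonomy data.frame from [read_taxonomy()].
#' @param rank one of domain, phylum, class, order, family, genus, species.
#' @return samples x rank-label count matrix.
#' @export
collapse_rank <- function(ct, tax, rank = "genus") {
  rank <- match.arg(rank, TAX_RANKS)
  idx <- match(colnames(ct), tax$taxon_id)
  if (anyNA(idx))
    stop("taxa missing from taxonomy: ",
         paste(utils::head(colnames(ct)[is.na(idx)], 5), collapse = ", "))
  ri <- match(rank, TAX_RANKS)
  lab <- tax[[rank]][idx]
  unassigned <- is.na(lab) | lab == ""
  if (any(unassigned)) {
    parent <- rep("root", sum(unassigned))
    if (ri > 1) {
      anc <- as.matrix(tax[idx[unassigned], TAX_RANKS[seq_len(ri - 1)], drop = FALSE])
      parent <- apply(anc, 1, function(r) {
        r <- r[!is.na(r) & r != ""]
        if (length(r)) r[length(r)] else "root"
      })
    }
    lab[unassigned] <- paste0("unclassified_", parent)
  }
  groups <- factor(lab, levels = unique(lab))
  out <- t(rowsum(t(ct), group = groups, reorder = FALSE))
  storage.mode(out) <- "integer"
  out
}

#' Filter taxa on mean relative abundance and prevalence
#'
#' Keeps taxa whose mean per-sample relative abundance is at least
#' `min_mean_relabund` and which are present (count > 0) in at least a
#' `min_prevalence` fraction of samples. Defaults reproduce the usual network
#' pre-filter (mean abundance >= 0.01%, prevalence >= 30%).
#'
#' @param ct samples x taxa count matrix.
#' @param min_mean_relabund fraction in \[0,1\].
#' @param min_prevalence fraction in \[0,1\].
#' @return the filtered count matrix (possibly with zero columns).
#' @export
filter_taxa <- function(ct, min_mean_relabund = 1e-4, min_prevalence = 0.3) {
  stopifnot(min_mean_relabund >= 0, min_mean_relabund <= 1,
            min_prevalence >= 0, min_prevalence <= 1)
  rel <- to_relative(ct)
  keep <- colMeans(rel) >= min_mean_relabund &
    colMeans(ct > 0) >= min_prevalence
  ct[, keep, drop = FALSE]
}

#' Rarefy samples to even depth
#'
#' Optional pre-processing (off by default throughout the pipeline): subsamples
#' each sample without replacement to `depth` reads.
#'
#' @param ct samples x taxa count matrix.
#' @param depth target reads per sample; defaults to the minimum sample total.
#' @param seed integer seed.
#' @return rarefied count matrix (samples below `depth` are dropped).
#' @export
rarefy_counts <- function(ct, depth = min(rowSums(ct)), seed = 1L) {
  keep <- rowSums(ct) >= depth
  ct <- ct[keep, , drop = FALSE]
  with_seed_(seed, {
    out <- vegan::rrarefy(ct, depth)
  })
  storage.mode(out) <- "integer"
  out
}

# Evaluate `code` under a temporary RNG state seeded with `seed`
# (restores any pre-existing .Random.seed afterwards).
with_seed_ <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stage-specific 31-bit seed from a global seed, so toggling one
# pipeline stage does not shift another stage's random stream.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * (seq_along(utf8ToInt(stage)) * 131))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
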