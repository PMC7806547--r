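# End-to-end orchestration: rarefy -> prevalence filter -> SparCC ->
# distance -> Ward tree -> PERMANOVA tree-cut -> guild abundances/network,
# plus community diversity statistics and guild-phenotype association.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the analysis constants:
#' rarefaction depth 16,500, prevalence threshold 0.2, SparCC with 20
#' Dirichlet draws and 100 bootstrap permutations, tree-cut at alpha 0.001
#' with 999 permutations (min node size 2), network display threshold
#' |r| >= 0.6, community PERMANOVA with 9,999 permutations. Any field can be
#' overridden via `...` (nested lists are merged shallowly per section).
#'
#' @param ... Named sections to override (`preprocess`, `sparcc`, `guilds`,
#'   `community`, `association`, `seed`, `out_dir`).
#' @return Nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    preprocess = list(rarefaction_depth = 16500, prevalence = 0.2,
                      order = c("rarefy", "filter")),
    sparcc = list(n_dirichlet_draws = 20, n_exclusion_iters = Inf,
                  exclusion_threshold = 0.1, n_bootstrap = 100,
                  compute_pvalues = TRUE),
    guilds = list(alpha = 0.001, n_perm = 999, min_node_size = 2,
                  min_abs_r = 0.6, ward_dialect = "ward.D2"),
    community = list(n_perm = 9999, run = TRUE),
    association = list(timepoint = NULL, spearman_family = "global",
                       mw_family = "per_pair", run = TRUE),
    seed = 1L, out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' @keywords internal
#' @noRd
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full guild-analysis pipeline
#'
#' Consumes a count table plus metadata (and optionally phenotypes), or a
#' [generate_dataset()] object, and executes every stage, writing plain-text
#' outputs and a JSON manifest when `out_dir` is set.
#'
#' @param counts Feature table (samples x ASVs), or a `synthetic_dataset`.
#' @param metadata Sample metadata (ignored when `counts` is a dataset).
#' @param phenotypes Optional phenotype table (idem).
#' @param config Configuration from [pipeline_config()].
#' @param taxonomy Optional named ASV -> lineage vector for network
#'   annotation.
#' @return List with every stage's result: `rarefied`, `filter`, `rel`,
#'   `sparcc`, `pvalues`, `dist`, `tree`, `assignment`, `guild_abundance`,
#'   `guild_summary`, `network`, `alpha`, `bray_curtis`, `pcoa`,
#'   `kruskal`, `pairwise_permanova`, `association`, `differential`,
#'   `zscores`, `manifest`.
#' @export
run_pipeline <- function(counts, metadata = NULL, phenotypes = NULL,
                         config = pipeline_config(), taxonomy = NULL) {
  if (inherits(counts, "synthetic_dataset")) {
    metadata <- counts$metadata
    phenotypes <- counts$phenotypes
    counts <- counts$counts
  }
  if (is.null(metadata)) stop("metadata is required", call. = FALSE)
  seed <- config$seed
  res <- list(config = config)

  pp <- config$preprocess
  filter_first <- all(c("filter", "rarefy") %in% pp$order) &&
    match("filter", pp$order) < match("rarefy", pp$order)
  tab <- counts
  if (filter_first) {
    res$filter <- .stage("prevalence_filter",
                         prevalence_filter(tab, pp$prevalence))
    tab <- res$filter$table
  }
  res$rarefied <- .stage("rarefy", rarefy(tab, pp$rarefaction_depth,
                                          seed = .child_seed(seed, "rarefy")))
  if (filter_first) {
    filtered <- res$rarefied
  } else {
    res$filter <- .stage("prevalence_filter",
                         prevalence_filter(res$rarefied, pp$prevalence))
    filtered <- res$filter$table
  }
  res$rel <- .stage("to_relative", to_relative(res$rarefied))
  rel_filtered <- res$rel[, colnames(filtered), drop = FALSE]

  sp <- config$sparcc
  res$sparcc <- .stage("sparcc", sparcc(
    filtered, n_dirichlet_draws = sp$n_dirichlet_draws,
    n_exclusion_iters = sp$n_exclusion_iters,
    exclusion_threshold = sp$exclusion_threshold,
    seed = .child_seed(seed, "sparcc")))
  if (isTRUE(sp$compute_pvalues))
    res$pvalues <- .stage("sparcc_pvalues", sparcc_pvalues(
      filtered, res$sparcc, n_bootstrap = sp$n_bootstrap,
      seed = .child_seed(seed, "sparcc_boot"),
      n_dirichlet_draws = sp$n_dirichlet_draws,
      n_exclusion_iters = sp$n_exclusion_iters,
      exclusion_threshold = sp$exclusion_threshold))

  gd <- config$guilds
  res$dist <- .stage("to_distance", to_distance(res$sparcc))
  res$tree <- .stage("ward_linkage",
                     ward_linkage(res$dist, dialect = gd$ward_dialect))
  res$assignment <- .stage("cut_tree_by_permanova", cut_tree_by_permanova(
    res$tree, res$dist, alpha = gd$alpha, n_perm = gd$n_perm,
    seed = .child_seed(seed, "cut"), min_node_size = gd$min_node_size))
  res$guild_abundance <- .stage("guild_abundance",
                                guild_abundance(rel_filtered, res$assignment))
  res$guild_summary <- .stage("guild_summary",
                              guild_summary(res$guild_abundance, metadata))
  res$network <- .stage("build_network", build_network(
    res$sparcc, res$assignment, rel_filtered, min_abs_r = gd$min_abs_r,
    taxonomy = taxonomy))

  cm <- config$community
  if (isTRUE(cm$run)) {
    res$alpha <- .stage("alpha_diversity", alpha_diversity(res$rarefied))
    res$bray_curtis <- .stage("bray_curtis", bray_curtis(res$rarefied))
    res$pcoa <- .stage("pcoa", pcoa(res$bray_curtis))
    md_sub <- metadata[metadata$sample_id %in% rownames(res$rarefied), ,
                       drop = FALSE]
    res$kruskal <- .stage("kruskal_by_timepoint",
                          kruskal_by_timepoint(res$alpha, md_sub))
    res$pairwise_permanova <- .stage("pairwise_permanova", pairwise_permanova(
      res$bray_curtis, md_sub, n_perm = cm$n_perm,
      seed = .child_seed(seed, "ppermanova")))
  }

  as_ <- config$association
  if (isTRUE(as_$run)) {
    tp <- as_$timepoint
    if (is.null(tp) && "timepoint" %in% names(metadata) &&
        !is.null(phenotypes)) {
      with_ph <- metadata$timepoint[metadata$sample_id %in%
                                      phenotypes$sample_id]
      if (length(with_ph)) tp <- utils::tail(unique(as.character(with_ph)), 1L)
    }
    res$differential <- .stage("mann_whitney_da", mann_whitney_da(
      res$guild_abundance, metadata, timepoint = tp, family = as_$mw_family))
    res$zscores <- .stage("zscore_table",
                          zscore_table(res$guild_abundance, metadata,
                                       timepoint = tp))
    if (!is.null(phenotypes)) {
      gab_ph <- res$guild_abundance[
        rownames(res$guild_abundance) %in% phenotypes$sample_id, ,
        drop = FALSE]
      if (nrow(gab_ph) >= 3L)
        res$association <- .stage("spearman_assoc", spearman_assoc(
          gab_ph, phenotypes, family = as_$spearman_family))
    }
  }

  res$manifest <- list(
    package = "guildscan",
    version = as.character(utils::packageVersion("guildscan")),
    r_version = R.version.string,
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    n_samples_in = nrow(counts), n_asvs_in = ncol(counts),
    n_samples_rarefied = nrow(res$rarefied),
    dropped_samples = attr(res$rarefied, "dropped"),
    n_asvs_retained = length(res$filter$retained),
    reads_retained_mean = mean(res$filter$reads_retained, na.rm = TRUE),
    n_cags = length(unique(res$assignment$cag)))

  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, config$out_dir)
  invisible(res)
}

#' @keywords internal
#' @noRd
.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  wtsv <- function(x, f, rn = "id") {
    df <- if (is.matrix(x)) data.frame(rownames(x), x, check.names = FALSE)
    else x
    if (is.matrix(x)) names(df)[1L] <- rn
    utils::write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_feature_table(res$rarefied, p("rarefied.tsv"))
  wtsv(res$sparcc$r, "sparcc_correlations.tsv", "asv_id")
  if (!is.null(res$pvalues)) wtsv(res$pvalues, "sparcc_pvalues.tsv", "asv_id")
  wtsv(res$dist, "sparcc_distance.tsv", "asv_id")
  write_tree_newick(res$tree, p("cluster_tree.nwk"))
  wtsv(res$assignment, "cag_assignment.tsv")
  wtsv(res$guild_abundance, "guild_abundance.tsv", "sample_id")
  wtsv(res$guild_summary, "guild_summary.tsv")
  write_network(res$network, p("network.graphml"), "graphml")
  write_network(res$network, p("network.sif"), "sif")
  write_network(res$network, p("network_edges.tsv"), "edge-tsv")
  if (!is.null(res$alpha)) {
    wtsv(res$alpha, "alpha_diversity.tsv")
    wtsv(as.matrix(res$bray_curtis), "bray_curtis.tsv", "sample_id")
    wtsv(res$pcoa$points, "pcoa_coordinates.tsv", "sample_id")
    wtsv(res$kruskal, "alpha_tests.tsv")
    wtsv(res$pairwise_permanova, "pairwise_permanova.tsv")
  }
  if (!is.null(res$association)) wtsv(res$association, "association.tsv")
  if (!is.null(res$differential)) wtsv(res$differential, "differential.tsv")
  if (!is.null(res$zscores)) wtsv(res$zscores, "zscores.tsv", "cag")
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
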