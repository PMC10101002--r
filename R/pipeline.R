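#' Run the full fermentation-community analysis pipeline
#'
#' Executes filtering, co-occurrence network construction and module
#' detection (combined and, when a grouping column is given, per group),
#' Zi/Pi keystone classification, robustness simulation, module-diversity
#' vs metabolite regressions, Sloan neutral-model fitting, NST, and
#' indicator-metabolite selection, writing every stage result plus a
#' machine-readable manifest (inputs, parameters, seeds, checksums) to
#' `out_dir`. One global seed spawns fixed per-stage seeds
#' (`stage_seed(seed, stage_number)`), so any stage can be re-run
#' independently with identical results; no stage consumes wall-clock
#' entropy.
#'
#' @param bacteria,fungi [abundance_table()]s of counts sharing a sample set.
#' @param metabolites a [metabolite_table()] (optional; `NULL` skips the
#'   metabolite stages).
#' @param metadata data.frame with rownames = sample IDs.
#' @param group_factor metadata column used for per-group networks,
#'   enrichment, NST, and indicator selection (`NULL` to skip those).
#' @param out_dir output directory (created if missing); `NULL` writes
#'   nothing.
#' @param seed global seed.
#' @param rho_min,p_max network edge thresholds.
#' @param min_prevalence,min_mean_ra taxon filter thresholds.
#' @param n_sim,n_boot,n_rand,n_perm,n_trees simulation sizes for
#'   robustness, neutral bootstrap, NST nulls, PERMANOVA, random forest.
#' @param robustness_fractions removal-fraction grid.
#' @return list of class `pipeline_result` with elements `filtered`,
#'   `network`, `summary`, `roles`, `keystone`, `robustness`, `profiles`,
#'   `regression`, `neutral`, `nst`, `permanova`, `enrichment`,
#'   `indicators`, `manifest` (entries are `NULL` where inputs were not
#'   supplied).
#' @export
run_pipeline <- function(bacteria, fungi, metabolites = NULL, metadata,
                         group_factor = "group", out_dir = NULL, seed = 1,
                         rho_min = 0.8, p_max = 0.01,
                         min_prevalence = 0.20, min_mean_ra = 1e-4,
                         n_sim = 200, n_boot = 1000, n_rand = 1000,
                         n_perm = 999, n_trees = 500,
                         robustness_fractions = seq(0.01, 1, by = 0.01)) {
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                             sprintf(...)))
  res <- list()
  params <- list(seed = seed, rho_min = rho_min, p_max = p_max,
                 min_prevalence = min_prevalence, min_mean_ra = min_mean_ra,
                 n_sim = n_sim, n_boot = n_boot, n_rand = n_rand,
                 n_perm = n_perm, n_trees = n_trees)

  log_stage("stage filter: %d bacterial + %d fungal taxa", nrow(bacteria$counts),
            nrow(fungi$counts))
  merged_counts <- merge_domains(bacteria, fungi, normalize = "none")
  res$filtered <- filter_taxa(merged_counts, min_prevalence, min_mean_ra)
  merged_ra <- merge_domains(bacteria, fungi, normalize = "domain")
  filtered_ra <- abundance_table(
    merged_ra$counts[taxa_ids(res$filtered), , drop = FALSE],
    merged_ra$domain[taxa_ids(res$filtered)], is_relative = FALSE)

  log_stage("stage network: %d taxa retained", nrow(res$filtered$counts))
  net <- build_network(filtered_ra, rho_min = rho_min, p_max = p_max)
  net <- detect_modules(net, seed = stage_seed(seed, 2))
  res$network <- net
  res$summary <- summarize_network(net)

  log_stage("stage keystone")
  res$roles <- zi_pi(net)
  res$keystone <- keystone_set(res$roles)

  log_stage("stage robustness: %d simulations", n_sim)
  res$robustness <- robustness(net, fractions = robustness_fractions,
                               n_sim = n_sim, seed = stage_seed(seed, 3))

  if (!is.null(metabolites)) {
    log_stage("stage module_function")
    # profile only the main ecological clusters (modules with >= 5 nodes)
    res$profiles <- module_profiles(merged_ra, net, min_module_size = 5L)
    res$regression <- diversity_metabolite_regression(res$profiles, metabolites)
  }

  log_stage("stage assembly: neutral model + NST")
  res$neutral <- fit_neutral_model(merged_counts, n_boot = n_boot,
                                   seed = stage_seed(seed, 4))
  groups <- if (!is.null(group_factor)) {
    metadata[sample_ids(merged_counts), group_factor]
  } else NULL
  res$nst <- nst(merged_counts, groups = groups, metric = "jaccard",
                 abundance_weighted = TRUE, n_rand = n_rand,
                 seed = stage_seed(seed, 5))

  if (!is.null(group_factor)) {
    log_stage("stage community_stats: PERMANOVA + enrichment")
    D <- dissimilarity(merged_ra, metric = "bray")
    f <- stats::reformulate(group_factor)
    res$permanova <- permanova(f, D, metadata, n_perm = n_perm,
                               seed = stage_seed(seed, 6))
    res$enrichment <- differential_enrichment(res$filtered, metadata,
                                              group_factor)
    if (!is.null(metabolites)) {
      log_stage("stage indicators: %d trees", n_trees)
      res$indicators <- indicator_select(metabolites, metadata, group_factor,
                                         n_trees = n_trees,
                                         seed = stage_seed(seed, 7))
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name) if (!is.null(obj)) write_results(obj, file.path(out_dir, name))
    wr(res$filtered, "filtered_table.tsv")
    wr(res$network, "network.graphml")
    wr(as.data.frame(res$roles), "node_roles.tsv")
    wr(as.data.frame(res$robustness), "robustness_curve.tsv")
    wr(res$neutral, "neutral_fit.json")
    wr(as.data.frame(res$nst), "nst.tsv")
    if (!is.null(res$regression)) wr(as.data.frame(res$regression), "module_metabolite_regression.tsv")
    if (!is.null(res$permanova)) wr(as.data.frame(res$permanova), "permanova.tsv")
    if (!is.null(res$enrichment)) wr(as.data.frame(res$enrichment), "enrichment.tsv")
    if (!is.null(res$indicators)) {
      wr(res$indicators$importance, "indicator_importance.tsv")
      wr(res$indicators$cv_curve, "indicator_cv_curve.tsv")
    }
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("fermnet")),
      created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      stage_seeds = stats::setNames(
        as.list(vapply(2:7, function(o) stage_seed(seed, o), numeric(1))),
        c("modules", "robustness", "neutral", "nst", "permanova", "indicators")),
      parameters = params,
      outputs = lapply(stats::setNames(files, basename(files)),
                       function(f) list(md5 = unname(tools::md5sum(f)),
                                        bytes = file.size(f)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$manifest <- manifest
  }
  log_stage("pipeline complete")
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("fermnet pipeline result\n")
  cat(sprintf("  filtered taxa: %d\n", nrow(x$filtered$counts)))
  cat(sprintf("  network: %d nodes, %d edges, Q = %.3f\n",
              x$summary$nodes, x$summary$edges, x$summary$modularity))
  cat(sprintf("  keystone taxa: %d (%d connectors)\n",
              length(x$keystone$keystone), x$keystone$n_connectors))
  cat(sprintf("  neutral model: m = %.3g, R2 = %.3f\n", x$neutral$m, x$neutral$R2))
  for (i in seq_len(nrow(x$nst))) {
    cat(sprintf("  NST[%s] = %.1f%%\n", x$nst$group[i], x$nst$NST[i]))
  }
  invisible(x)
}
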