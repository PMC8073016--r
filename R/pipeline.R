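#' Run the full analysis pipeline on a synthetic study
#'
#' Chains every stage end to end: synthetic study generation, per-cell
#' quantification from the rendered nuclei tables (with attenuation fit and
#' cutoff), replicate integration into a consensus landscape, divergence
#' analyses (lineage-distance stratification, transition points,
#' lineage-normalized cell clustering, tissue and L-R comparisons), and
#' genomic co-dynamics with enrichment. The imaged integrants are
#' quantified through the imaging pipeline; all integrants enter the
#' landscape through the generator's replicate expression tables.
#'
#' @param config A [sim_config()] (or a YAML path readable by
#'   [read_pipeline_config()]).
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @param imaging_integrants How many sites to push through the full
#'   imaging + quantification route.
#' @param transition_alpha,cell_threshold,position_threshold,window Stage
#'   parameters (published defaults).
#' @return A `pipeline_report` list with all stage outputs and a `summary`
#'   of counts; written as `report.json` plus stage TSVs when `out_dir` is
#'   given.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         imaging_integrants = 2L,
                         transition_alpha = 0.05, cell_threshold = 4.5,
                         position_threshold = 65, window = 1e5) {
  if (is.character(config)) config <- read_pipeline_config(config)
  study <- simulate_embryo_study(
    config, imaging = imaging_integrants > 0,
    n_imaging_integrants = imaging_integrants,
    embryos_per_orientation = 2L)

  quantified <- quantify_cells(study$nuclei, study$meta, alpha = "auto")
  landscape <- build_landscape(
    filter(study$replicates, .data$cell %in% tree_leaves(study$tree)),
    sites = study$sites)
  dm <- normalize_by_lineage_distance(divergence_matrix(landscape))
  by_distance <- divergence_by_lineage_distance(dm)
  transitions <- detect_transition_points(study$tree, dm,
                                          min_leaves = 2L,
                                          alpha = transition_alpha)
  clusters <- cluster_cells(dm, threshold = cell_threshold)
  tissue <- tissue_divergence_analysis(dm, study$tree, seed = config$seed)
  lr_pairs <- expand_symmetric_pairs(study$registry, study$tree)
  lr <- lr_divergence_analysis(dm, lr_pairs, study$tree)
  codyn <- position_codynamic_clusters(landscape,
                                       threshold = position_threshold)
  geometry <- codynamic_pair_geometry(codyn$pairs, study$sites)
  clonal <- identify_clonal_tissue_lineages(study$tree)
  enrichment <- pairwise_functional_enrichment(
    codyn$pairs, study$sites, study$annotations$genes,
    study$annotations$coexpressed, window = window)
  clonal_enrichment <- clonal_lineage_activity_enrichment(
    landscape, clonal, codyn$sites, study$tree)
  tissue_gene <- tissue_gene_activity_enrichment(
    landscape, clonal, study$annotations$tissue_genes,
    study$annotations$genes, study$tree, window = window)

  report <- list(
    seed = config$seed,
    alpha_fitted = attr(quantified, "alpha"),
    cutoff = attr(quantified, "cutoff"),
    study = study,
    quantified = quantified,
    landscape = landscape,
    divergence = dm,
    by_distance = by_distance,
    transitions = transitions,
    clusters = clusters,
    tissue = tissue,
    lr = lr,
    codynamics = codyn,
    geometry = geometry,
    clonal = clonal,
    enrichment = enrichment,
    clonal_enrichment = clonal_enrichment,
    tissue_gene = tissue_gene,
    summary = list(
      seed = config$seed,
      n_cells = length(landscape$cells),
      n_sites = ncol(landscape$activity),
      alpha_fitted = attr(quantified, "alpha"),
      n_transitions = sum(transitions$is_transition),
      n_mothers_tested = nrow(transitions),
      n_cell_clusters = max(clusters$cluster),
      n_codynamic_clusters =
        length(unique(codyn$sites$cluster[codyn$sites$cluster_size >= 2])),
      n_codynamic_pairs = nrow(codyn$pairs),
      lr_fraction_below = lr$fraction_below,
      coexpression_oe = enrichment$oe,
      n_clonal_lineages = nrow(clonal)
    )
  )
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(as_tibble(transitions), file.path(out_dir, "transitions.tsv"))
    readr::write_tsv(clusters, file.path(out_dir, "cell_clusters.tsv"))
    readr::write_tsv(codyn$sites, file.path(out_dir, "codynamic_clusters.tsv"))
    readr::write_tsv(tissue, file.path(out_dir, "tissue_divergence.tsv"))
    readr::write_tsv(lr$pairs, file.path(out_dir, "lr_pairs.tsv"))
    write_landscape(landscape, file.path(out_dir, "landscape"))
    jsonlite::write_json(report$summary, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "Pipeline report (seed %d)\n",
    "  %d cells x %d sites; fitted alpha = %.3f\n",
    "  transitions: %d of %d mothers; %d cell clusters; ",
    "%d co-dynamic clusters (%d pairs)\n",
    "  L-R pairs below matched controls: %.0f%%; co-expression O/E = %.2f\n"),
    s$seed, s$n_cells, s$n_sites, s$alpha_fitted, s$n_transitions,
    s$n_mothers_tested, s$n_cell_clusters, s$n_codynamic_clusters,
    s$n_codynamic_pairs, 100 * s$lr_fraction_below, s$coexpression_oe))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [sim_config()]; unknown keys are
#' rejected. Data-frame arguments (`clonal_lineages`, `lr_pairs`,
#' `transitions`) are given as lists of records.
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  for (k in c("clonal_lineages", "lr_pairs", "transitions")) {
    if (!is.null(y[[k]])) y[[k]] <- bind_rows(lapply(y[[k]], as_tibble))
  }
  for (k in c("founder_depths", "chrom_lengths")) {
    if (!is.null(y[[k]])) y[[k]] <- unlist(y[[k]])
  }
  do.call(sim_config, y)
}
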