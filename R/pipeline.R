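# End-to-end wrapper: from a phosphosite table (plus library and annotation
# tables) to kinase activities, interaction scores, pathway scores and the
# exportable network.

#' Run the full kinase-substrate inference pipeline
#'
#' Executes, per treatment comparison: differential calling and regulation
#' scoring, PSSM scoring with percentile ranking and the top-25 kinase
#' filter, kinase-motif enrichment with signed relative activities,
#' KLS-based interaction scoring with evidence augmentation and the top-3
#' per-site filter, kinase-substrate and pathway aggregation, dependency-
#' partitioned overrepresentation analysis of co-regulated phosphoproteins,
#' and network assembly.
#'
#' @param sites phosphosite data.frame (see [read_phosphosite_table()])
#' @param library named list of [kinase_model()] objects
#' @param evidence curated evidence data.frame or `NULL`
#' @param interactions reference-count data.frame or `NULL`
#' @param gene_sets named list of pathways or `NULL`
#' @param dependency dependency data.frame or `NULL`
#' @param config a [run_config()]
#' @return a named list per comparison; each element holds `regulated`,
#'   `top_scores`, `enrichment`, `activities`, `interaction_scores`,
#'   `kinase_substrate_scores`, `pathway_scores`, `ora`, `network`
#' @export
run_pipeline <- function(sites, library, evidence = NULL, interactions = NULL,
                         gene_sets = NULL, dependency = NULL,
                         config = run_config()) {
  sites <- regulation_scores(sites, config)
  scored <- score_phosphosites(sites, library)
  top <- top_kinases_for_site(scored, config$top_kinase_percentile_count)
  detected <- unique(sites$protein)

  results <- list()
  for (cmp in unique(sites$comparison)) {
    cs <- sites[sites$comparison == cmp, ]
    enr <- kinase_enrichment(top, cs)
    act <- relative_kinase_activity(enr, config)
    isc <- interaction_scores(top, act, cs, evidence, interactions, config)
    kss <- kinase_substrate_scores(isc)
    pws <- if (!is.null(gene_sets)) {
      pathway_interaction_scores(gene_sets, isc, detected, config)
    }
    ora <- if (!is.null(gene_sets) && !is.null(dependency)) {
      coreg <- select_phosphoproteins(cs, "co-regulated")
      dependency_partition_ora(coreg, dependency, gene_sets, detected, config)
    }
    net <- if (nrow(kss) > 0) build_network(kss, dependency, config)
    results[[cmp]] <- list(regulated = cs, top_scores = top, enrichment = enr,
                           activities = act, interaction_scores = isc,
                           kinase_substrate_scores = kss,
                           pathway_scores = pws, ora = ora, network = net)
  }
  results
}
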