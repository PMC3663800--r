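#' Compute the regulated interaction set from paired expression matrices
#'
#' Chains the per-probe state classification, the probe score filter, the
#' gene-level aggregation of mRNA probe states, the medium-ratio filter on
#' both the miRNA and the gene rows, interaction-state construction over the
#' catalog, and the undefined-frequency filter. The survivors are the set of
#' regulated interactions.
#'
#' @param mirna_expr log-normalized miRNA matrix (rownames are miRNA ids).
#' @param mrna_expr log-normalized mRNA matrix (rownames are probe ids).
#' @param probe_gene_map data.frame `probe_id`, `gene_id`.
#' @param catalog data.frame `mirna_id`, `gene_id`.
#' @param config a [cape_config()].
#' @return list with `mirna_states`, `gene_states` (filtered state matrices),
#'   `regulated` (an `interaction_states` object) and the per-probe score
#'   tables `mirna_stats`, `mrna_stats`.
#' @export
regulated_interactions <- function(mirna_expr, mrna_expr, probe_gene_map,
                                   catalog, config = cape_config()) {
  n_samp <- ncol(mirna_expr)
  if (!identical(colnames(mirna_expr), colnames(mrna_expr)))
    stop("miRNA and mRNA matrices must share the same samples")
  mir_cls <- filter_probes_by_score(classify_matrix(mirna_expr, config),
                                    config$probe_score_factor, n_samp)
  mrna_cls <- filter_probes_by_score(classify_matrix(mrna_expr, config),
                                     config$probe_score_factor, n_samp)
  if (nrow(mir_cls$states) == 0L || nrow(mrna_cls$states) == 0L)
    stop("no probe survived the score filter")
  gene_states <- aggregate_gene_states(mrna_cls$states, probe_gene_map)
  mirna_states <- filter_by_medium_ratio(mir_cls$states,
                                         config$medium_ratio_max)
  gene_states <- filter_by_medium_ratio(gene_states, config$medium_ratio_max)
  tab <- build_interaction_states(mirna_states, gene_states, catalog)
  regulated <- filter_by_undefined_frequency(tab, config$undefined_freq_max)
  list(mirna_states = mirna_states, gene_states = gene_states,
       regulated = regulated,
       mirna_stats = mir_cls$stats, mrna_stats = mrna_cls$stats)
}

#' Full differential-regulation analysis
#'
#' Runs [regulated_interactions()], selects the differentially regulated
#' interactions between the two predefined groups and ranks them by the
#' pair-counting Jaccard agreement with the experimental partition.
#'
#' @inheritParams regulated_interactions
#' @param groups data.frame `sample_id`, `group` with exactly two groups.
#' @return list with everything [regulated_interactions()] returns plus
#'   `differential` and `ranked` data.frames.
#' @export
cape_pipeline <- function(mirna_expr, mrna_expr, probe_gene_map, catalog,
                          groups, config = cape_config()) {
  parts <- regulated_interactions(mirna_expr, mrna_expr, probe_gene_map,
                                  catalog, config)
  differential <- select_differential(parts$regulated, groups)
  ranked <- rank_interactions(differential, parts$regulated, groups)
  c(parts, list(differential = differential, ranked = ranked))
}
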