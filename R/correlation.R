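#' Per-group Spearman correlation between miRNA and target expression
#'
#' For each interaction, the rank correlation between the miRNA and the target
#' gene's log-normalized expression is computed separately within each
#' experimental group (2 or 3 groups, mirroring tumor-only vs full
#' collectives). Ties use midranks (the standard Spearman convention); a
#' constant vector within a group leaves that group's coefficient undefined
#' (`NA`).
#'
#' Gene-level expression is the per-sample mean of the gene's probe rows on
#' the log scale.
#'
#' @param interactions data.frame with columns `mirna_id`, `gene_id` (e.g. a
#'   ranked list).
#' @param mirna_expr log-normalized miRNA matrix (probes x samples; rownames
#'   are miRNA ids).
#' @param mrna_expr log-normalized mRNA matrix (probes x samples).
#' @param probe_gene_map data.frame `probe_id`, `gene_id` covering
#'   `mrna_expr`'s rows.
#' @param groups data.frame `sample_id`, `group` covering the samples.
#' @return numeric matrix (interactions x groups) of Spearman rho.
#' @export
spearman_by_group <- function(interactions, mirna_expr, mrna_expr,
                              probe_gene_map, groups) {
  if (!identical(colnames(mirna_expr), colnames(mrna_expr)))
    stop("miRNA and mRNA matrices must share the same samples")
  samp <- colnames(mirna_expr)
  gl <- groups$group[match(samp, groups$sample_id)]
  if (anyNA(gl)) stop("sample(s) without group label")
  labs <- unique(groups$group)
  if (!length(labs) %in% 2:3)
    stop("correlation filtering expects 2 or 3 experimental groups")

  gene_expr <- rowsum(mrna_expr,
                      group = probe_gene_map$gene_id[
                        match(rownames(mrna_expr), probe_gene_map$probe_id)])
  gene_n <- table(probe_gene_map$gene_id[
    match(rownames(mrna_expr), probe_gene_map$probe_id)])
  gene_expr <- gene_expr / as.numeric(gene_n[rownames(gene_expr)])

  mi <- match(interactions$mirna_id, rownames(mirna_expr))
  gi <- match(interactions$gene_id, rownames(gene_expr))
  if (anyNA(mi) || anyNA(gi))
    stop("interaction(s) reference miRNAs or genes absent from the matrices")

  rho <- matrix(NA_real_, nrow = nrow(interactions), ncol = length(labs),
                dimnames = list(NULL, labs))
  for (g in seq_along(labs)) {
    cols <- gl == labs[g]
    if (sum(cols) < 3L)
      stop("group '", labs[g], "' has fewer than 3 samples")
    x <- mirna_expr[mi, cols, drop = FALSE]
    y <- gene_expr[gi, cols, drop = FALSE]
    rho[, g] <- vapply(seq_len(nrow(x)), function(i) {
      if (stats::sd(x[i, ]) == 0 || stats::sd(y[i, ]) == 0) return(NA_real_)
      stats::cor(x[i, ], y[i, ], method = "spearman")
    }, numeric(1))
  }
  rho
}

#' Filter ranked interactions by negative per-group correlation
#'
#' Keeps the interactions with `rho <= cutoff` (inclusive) in at least one
#' experimental group; undefined coefficients never satisfy the criterion.
#'
#' @param ranked data.frame of interactions (e.g. from [rank_interactions()]).
#' @param rho matrix from [spearman_by_group()], rows aligned with `ranked`.
#' @param cutoff correlation cutoff, default `-0.4`.
#' @return `ranked` restricted to the survivors, with one `rho_<group>` column
#'   appended per group.
#' @export
filter_negative_correlation <- function(ranked, rho, cutoff = -0.4) {
  if (nrow(rho) != nrow(ranked))
    stop("'rho' rows must align with 'ranked'")
  keep <- apply(rho, 1L, function(r) any(r <= cutoff, na.rm = TRUE))
  out <- ranked
  for (g in colnames(rho)) out[[paste0("rho_", g)]] <- rho[, g]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
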