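#' Simulate paired miRNA/mRNA expression with planted regulated interactions
#'
#' Generates log-scale expression for a catalog of putative miRNA-target
#' pairs. Each planted pair is bimodal: the miRNA sits at a high level and the
#' target gene at a low level in one side of the contrast, reversed on the
#' other side, the two levels separated by `log_fold` natural-log units.
#' Within a level, samples scatter with additive Gaussian noise of total sd
#' `noise_sd`; for planted pairs a fraction `anticorr_share` of that noise
#' variance is a shared per-sample latent shift, added to the miRNA and
#' subtracted from the target, so planted pairs carry a negative within-group
#' correlation (as the miRNA-target hypothesis predicts) without exceeding
#' the stated within-state noise sd. `flip_fraction` flips samples'
#' side
#' assignment per planted pair, modelling per-sample biological
#' heterogeneity; at 0.5 all group structure is erased. Decoy miRNAs and
#' genes have a single expression level plus noise.
#'
#' The default group layout (8 invasive, 8 non-invasive, 8 normal samples,
#' contrast tumor vs normal) mirrors a three-group bladder-collective design;
#' the defaults plant 50 of 500 catalog pairs.
#'
#' @param n_per_group named integer vector of samples per experimental group.
#' @param contrast list of two character vectors of group names defining the
#'   two sides of the differential contrast; names give the contrast labels.
#' @param n_catalog total catalog pairs (planted + decoys).
#' @param n_planted number of planted pairs.
#' @param log_fold level separation on the natural-log scale.
#' @param noise_sd within-level noise sd (log scale).
#' @param anticorr_share fraction of the planted pairs' noise variance carried
#'   by the anti-correlated per-sample latent shift, in \[0,1\].
#' @param flip_fraction probability that a sample's side assignment is flipped
#'   to the opposite side for a planted pair (0.5 erases the association).
#' @param n_decoy_mirna,n_decoy_gene sizes of the decoy probe pools from
#'   which decoy pairs are drawn.
#' @param probes_per_gene mRNA probes per gene (all genes).
#' @param base_range range of per-probe baseline levels (log scale).
#' @param seed integer seed; fully determines the dataset.
#' @return list with `mirna`, `mrna` (log-scale matrices), `probe_gene_map`,
#'   `catalog`, `groups` (all experimental groups), `diff_groups` (two-level
#'   contrast labels), and `truth` (list: `planted` with `direction`
#'   (`A_down` = miRNA up / target down on the first contrast side), `decoys`,
#'   `params`).
#' @export
simulate_dataset <- function(n_per_group = c(invasive = 8, noninvasive = 8,
                                             normal = 8),
                             contrast = list(tumor = c("invasive",
                                                       "noninvasive"),
                                             normal = "normal"),
                             n_catalog = 500, n_planted = 50,
                             log_fold = 2, noise_sd = 0.2,
                             anticorr_share = 0.5, flip_fraction = 0,
                             n_decoy_mirna = 150, n_decoy_gene = 200,
                             probes_per_gene = 1, base_range = c(4, 10),
                             seed = 1L) {
  stopifnot(all(n_per_group >= 2), log_fold > 0, noise_sd >= 0,
            anticorr_share >= 0, anticorr_share <= 1,
            flip_fraction >= 0, flip_fraction <= 1,
            n_planted >= 1, n_catalog > n_planted, probes_per_gene >= 1,
            length(contrast) == 2L,
            setequal(unlist(contrast), names(n_per_group)))
  if (n_catalog - n_planted > n_decoy_mirna * n_decoy_gene)
    stop("decoy pools too small for the requested catalog size")
  set.seed(seed)

  grp <- rep(names(n_per_group), n_per_group)
  n_samp <- length(grp)
  samp <- sprintf("S%02d", seq_len(n_samp))
  groups <- data.frame(sample_id = samp, group = grp, stringsAsFactors = FALSE)
  side_labels <- names(contrast)
  side1 <- grp %in% contrast[[1L]]
  diff_groups <- data.frame(sample_id = samp,
                            group = ifelse(side1, side_labels[1L],
                                           side_labels[2L]),
                            stringsAsFactors = FALSE)

  mir_p <- sprintf("mir-P%03d", seq_len(n_planted))
  gene_p <- sprintf("GP%04d", seq_len(n_planted))
  mir_d <- sprintf("mir-D%03d", seq_len(n_decoy_mirna))
  gene_d <- sprintf("GD%04d", seq_len(n_decoy_gene))

  n_decoy_pairs <- n_catalog - n_planted
  grid_idx <- sample.int(n_decoy_mirna * n_decoy_gene, n_decoy_pairs)
  decoys <- data.frame(
    mirna_id = mir_d[(grid_idx - 1L) %% n_decoy_mirna + 1L],
    gene_id = gene_d[(grid_idx - 1L) %/% n_decoy_mirna + 1L],
    stringsAsFactors = FALSE)
  planted <- data.frame(mirna_id = mir_p, gene_id = gene_p,
                        direction = sample(c("A_down", "A_up"), n_planted,
                                           replace = TRUE),
                        stringsAsFactors = FALSE)
  catalog <- rbind(planted[, c("mirna_id", "gene_id")], decoys)

  rlevel <- function(k) stats::runif(k, base_range[1L], base_range[2L])

  ## planted pairs: per-sample side assignment (possibly flipped), a shared
  ## anti-correlated latent shift, then miRNA/gene levels; the latent and the
  ## independent residual split the within-state variance so the total
  ## within-state sd equals noise_sd
  sd_u <- noise_sd * sqrt(anticorr_share)
  sd_e <- noise_sd * sqrt(1 - anticorr_share)
  mir_rows_p <- matrix(0, n_planted, n_samp)
  gene_lat_p <- matrix(0, n_planted, n_samp)
  for (k in seq_len(n_planted)) {
    s1 <- side1
    if (flip_fraction > 0) {
      flip <- stats::runif(n_samp) < flip_fraction
      s1[flip] <- !s1[flip]
    }
    mir_high <- if (planted$direction[k] == "A_down") s1 else !s1
    u <- if (sd_u > 0) stats::rnorm(n_samp, 0, sd_u) else 0
    e <- if (sd_e > 0) stats::rnorm(n_samp, 0, sd_e) else 0
    mir_rows_p[k, ] <- rlevel(1) + log_fold * mir_high + u + e
    gene_lat_p[k, ] <- rlevel(1) + log_fold * (!mir_high) - u
  }

  noise <- function(nr, sd = noise_sd) if (sd > 0)
    matrix(stats::rnorm(nr * n_samp, 0, sd), nr, n_samp) else 0

  mirna <- rbind(mir_rows_p,
                 matrix(rlevel(n_decoy_mirna), n_decoy_mirna, n_samp) +
                   noise(n_decoy_mirna))
  dimnames(mirna) <- list(c(mir_p, mir_d), samp)
  attr(mirna, "entity") <- "miRNA"

  gene_lat <- rbind(gene_lat_p,
                    matrix(rlevel(n_decoy_gene), n_decoy_gene, n_samp))
  genes <- c(gene_p, gene_d)
  n_genes <- length(genes)
  ## per-probe residual: planted genes already carry the latent share, so
  ## their probes get the residual sd; decoy probes get the full noise sd
  probe_sd <- rep(c(sd_e, noise_sd), c(n_planted, n_decoy_gene))
  probe_sd <- rep(probe_sd, each = probes_per_gene)
  n_probes <- n_genes * probes_per_gene
  probe_noise <- if (noise_sd > 0)
    matrix(stats::rnorm(n_probes * n_samp, 0, rep(probe_sd, n_samp)),
           n_probes, n_samp) else 0
  probe_rows <- gene_lat[rep(seq_len(n_genes), each = probes_per_gene), ,
                         drop = FALSE] + probe_noise
  probe_ids <- paste0(rep(genes, each = probes_per_gene), "_p",
                      rep(seq_len(probes_per_gene), n_genes))
  dimnames(probe_rows) <- list(probe_ids, samp)
  attr(probe_rows, "entity") <- "mRNA"
  probe_gene_map <- data.frame(probe_id = probe_ids,
                               gene_id = rep(genes, each = probes_per_gene),
                               stringsAsFactors = FALSE)

  list(mirna = mirna, mrna = probe_rows, probe_gene_map = probe_gene_map,
       catalog = catalog, groups = groups, diff_groups = diff_groups,
       truth = list(planted = planted, decoys = decoys,
                    params = list(n_per_group = n_per_group,
                                  contrast = contrast,
                                  n_catalog = n_catalog,
                                  n_planted = n_planted,
                                  log_fold = log_fold, noise_sd = noise_sd,
                                  anticorr_share = anticorr_share,
                                  flip_fraction = flip_fraction,
                                  probes_per_gene = probes_per_gene,
                                  seed = as.integer(seed))))
}

#' Write a simulated dataset in the package's TSV formats
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(sim$mirna, file.path(dir, "mirna_expression.tsv"))
  write_expression(sim$mrna, file.path(dir, "mrna_expression.tsv"))
  write_tsv(sim$probe_gene_map, file.path(dir, "probe_gene_map.tsv"))
  write_tsv(sim$catalog, file.path(dir, "catalog.tsv"))
  write_tsv(sim$groups, file.path(dir, "groups.tsv"))
  write_tsv(sim$diff_groups, file.path(dir, "diff_groups.tsv"))
  write_tsv(sim$truth$planted, file.path(dir, "planted_truth.tsv"))
  invisible(dir)
}
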