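#' Expected sample partition induced by one interaction's states
#'
#' Samples are grouped into three blocks by the comp set of their interaction
#' state: `G_HL` (state HL, HM or ML — miRNA up, target down), `G_LH` (LH, LM
#' or MH) and `G_undef` (HH, MM, LL). Blocks may be empty; together they
#' partition the samples.
#'
#' @param states character vector of one interaction's per-sample states.
#' @return list with integer index vectors `G_HL`, `G_LH`, `G_undef`.
#' @export
expected_partition <- function(states) {
  comp <- comp_set_of(states)
  list(G_HL = which(comp == "S_compHL"),
       G_LH = which(comp == "S_compLH"),
       G_undef = which(comp == "S_undef"))
}

#' Pair-counting Jaccard similarity between two partitions
#'
#' Over all unordered sample pairs, let `N11` be the pairs co-clustered in
#' both partitions, and `N10`/`N01` the pairs co-clustered in only one. The
#' Jaccard index is `N11 / (N11 + N10 + N01)`, the standard cluster-validity
#' agreement between partitions (block counts may differ). It is symmetric,
#' lies in \[0, 1\], and equals 1 for identical partitions with at least one
#' co-clustered pair. When no partition co-clusters any pair the index is
#' defined as 0 (no agreement evidence).
#'
#' @param p,q partitions of the same `n >= 2` samples, each given either as a
#'   label vector of length `n` or as a list of index blocks.
#' @return the Jaccard index in \[0, 1\].
#' @export
jaccard_partition_similarity <- function(p, q) {
  p <- partition_labels(p)
  q <- partition_labels(q)
  if (length(p) != length(q))
    stop("partitions must cover the same samples")
  if (length(p) < 2L) stop("partition similarity needs at least 2 samples")
  tab <- table(p, q)
  n11 <- sum(choose(tab, 2))
  pairs_p <- sum(choose(rowSums(tab), 2))
  pairs_q <- sum(choose(colSums(tab), 2))
  denom <- pairs_p + pairs_q - n11  # N11 + N10 + N01
  if (denom == 0) return(0)
  n11 / denom
}

## normalize a partition (block list or label vector) to integer labels
partition_labels <- function(p) {
  if (is.list(p)) {
    n <- sum(lengths(p))
    lab <- integer(n)
    for (b in seq_along(p)) {
      if (any(lab[p[[b]]] != 0L)) stop("partition blocks overlap")
      lab[p[[b]]] <- b
    }
    if (any(lab == 0L)) stop("partition blocks do not cover all samples")
    lab
  } else {
    as.integer(factor(p))
  }
}

#' Rank differentially regulated interactions by Jaccard agreement
#'
#' Each interaction's expected partition (from its states) is compared with
#' the two predefined experimental groups by the pair-counting Jaccard index;
#' interactions are sorted by decreasing index, ties broken lexicographically
#' by `(mirna_id, gene_id)`.
#'
#' @param differential data.frame from [select_differential()].
#' @param table the `interaction_states` object the selection was made from.
#' @param groups data.frame with columns `sample_id`, `group` (two groups).
#' @return `differential` with a `jaccard_index` column, sorted.
#' @export
rank_interactions <- function(differential, table, groups) {
  stopifnot(inherits(table, "interaction_states"))
  if (length(unique(groups$group)) != 2L)
    stop("ranking needs exactly two experimental groups")
  samp <- colnames(table$states)
  expt <- groups$group[match(samp, groups$sample_id)]
  if (anyNA(expt)) stop("sample(s) without group label")
  key_tab <- paste(table$interactions$mirna_id, table$interactions$gene_id,
                   sep = "\r")
  key_diff <- paste(differential$mirna_id, differential$gene_id, sep = "\r")
  rows <- match(key_diff, key_tab)
  if (anyNA(rows)) stop("differential interaction(s) missing from the table")
  ji <- vapply(rows, function(r) {
    jaccard_partition_similarity(expected_partition(table$states[r, ]), expt)
  }, numeric(1))
  out <- differential
  out$jaccard_index <- ji
  ord <- order(-out$jaccard_index, out$mirna_id, out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_labels") <- attr(differential, "group_labels")
  out
}
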