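## key used to match interactions across tables
interaction_key <- function(mirna_id, gene_id) paste(mirna_id, gene_id, sep = "::")

#' Build a vote-counting classification model from ranked interactions
#'
#' The model contains every interaction with Jaccard index at or above
#' `ji_threshold`. Each interaction carries a model state set: the comp set
#' (`S_compHL` or `S_compLH`) containing the reference ("first") group's modal
#' state, i.e. the direction of regulation expected for a reference-group
#' sample.
#'
#' @param ranked data.frame from [rank_interactions()] (columns
#'   `jaccard_index`, `modal_state_A`, `modal_state_B`, and the
#'   `group_labels` attribute).
#' @param ji_threshold minimum Jaccard index for inclusion.
#' @param reference_group the group the model votes for; defaults to the
#'   first group label.
#' @return object of class `cape_model`: list with `interactions` (data.frame
#'   `mirna_id`, `gene_id`, `comp_set`), `reference_group`, `other_group`,
#'   `ji_threshold`.
#' @export
build_model <- function(ranked, ji_threshold,
                        reference_group = attr(ranked, "group_labels")[1L]) {
  labs <- attr(ranked, "group_labels")
  if (is.null(labs) || !reference_group %in% labs)
    stop("'ranked' must carry its two group labels and 'reference_group' ",
         "must be one of them")
  sel <- ranked[ranked$jaccard_index >= ji_threshold, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no interaction reaches Jaccard index ", ji_threshold,
         "; lower the threshold")
  modal_ref <- if (reference_group == labs[1L]) sel$modal_state_A else
    sel$modal_state_B
  structure(
    list(interactions = data.frame(mirna_id = sel$mirna_id,
                                   gene_id = sel$gene_id,
                                   comp_set = comp_set_of(modal_ref),
                                   stringsAsFactors = FALSE),
         reference_group = reference_group,
         other_group = setdiff(labs, reference_group),
         ji_threshold = ji_threshold),
    class = "cape_model")
}

#' Build a model from randomized interactions within a Jaccard range
#'
#' Samples `n_interactions` uniformly without replacement from the ranked
#' interactions whose Jaccard index falls inside `ji_range` (inclusive);
#' model state sets are assigned as in [build_model()]. Reproducible under
#' `seed`.
#'
#' @inheritParams build_model
#' @param n_interactions model size.
#' @param ji_range numeric `c(lo, hi)`.
#' @param seed integer seed.
#' @return a `cape_model`.
#' @export
build_random_model <- function(ranked, n_interactions, ji_range, seed,
                               reference_group = attr(ranked, "group_labels")[1L]) {
  stopifnot(length(ji_range) == 2L, ji_range[1L] <= ji_range[2L])
  in_range <- ranked$jaccard_index >= ji_range[1L] &
    ranked$jaccard_index <= ji_range[2L]
  pool <- ranked[in_range, , drop = FALSE]
  if (nrow(pool) < n_interactions)
    stop("only ", nrow(pool), " interaction(s) inside the Jaccard range [",
         ji_range[1L], ", ", ji_range[2L], "]; cannot draw ", n_interactions)
  set.seed(seed)
  pick <- sort(sample.int(nrow(pool), n_interactions))
  sel <- pool[pick, , drop = FALSE]
  attr(sel, "group_labels") <- attr(ranked, "group_labels")
  build_model(sel, ji_threshold = -Inf, reference_group = reference_group)
}

#' @export
print.cape_model <- function(x, ...) {
  cat(sprintf("capeRNA vote model: %d interactions, reference group '%s'\n",
              nrow(x$interactions), x$reference_group))
  invisible(x)
}

#' Classify a sample by interaction-state votes
#'
#' For each model interaction with a state available for the sample, a vote
#' for the reference group is cast when the sample's state lies in the model's
#' comp set, a vote for the other group when it lies in the opposite comp set,
#' and no vote when it is undefined (HH/LL/MM). The predicted label is the
#' reference group iff the reference votes strictly outnumber the others; a
#' tie (including the all-undefined case) predicts the other group. Model
#' interactions without a state for the sample are skipped.
#'
#' @param model a `cape_model`.
#' @param states named character vector of the sample's interaction states;
#'   names are `"<mirna_id>::<gene_id>"`.
#' @return the predicted group label, with attributes `c_first`, `c_second`,
#'   `n_skipped`.
#' @export
classify_sample <- function(model, states) {
  keys <- interaction_key(model$interactions$mirna_id,
                          model$interactions$gene_id)
  idx <- match(keys, names(states))
  present <- !is.na(idx)
  s <- states[idx[present]]
  comp <- comp_set_of(s)
  mod_comp <- model$interactions$comp_set[present]
  opp <- ifelse(mod_comp == "S_compHL", "S_compLH", "S_compHL")
  c_first <- sum(comp == mod_comp)
  c_second <- sum(comp == opp)
  label <- if (c_first > c_second) model$reference_group else model$other_group
  structure(label, c_first = c_first, c_second = c_second,
            n_skipped = sum(!present))
}

#' Classify all samples of an interaction-state table
#'
#' @param model a `cape_model`.
#' @param table an `interaction_states` object.
#' @return character vector of predicted labels, one per sample.
#' @export
classify_samples <- function(model, table) {
  stopifnot(inherits(table, "interaction_states"))
  keys <- interaction_key(table$interactions$mirna_id,
                          table$interactions$gene_id)
  vapply(seq_len(ncol(table$states)), function(j) {
    st <- table$states[, j]
    names(st) <- keys
    as.character(classify_sample(model, st))
  }, character(1))
}

#' Split samples into training and test halves, per group
#'
#' Each group is halved without replacement; odd groups put the extra sample
#' in the training set (a group of 7 gives 4 training and 3 test samples).
#' Training and test sets are disjoint and jointly exhaustive.
#'
#' @param groups data.frame `sample_id`, `group`; every group `>= 2` samples.
#' @param seed integer seed.
#' @return list with `train` and `test` group data.frames.
#' @export
bootstrap_split <- function(groups, seed) {
  set.seed(seed)
  train_idx <- unlist(lapply(split(seq_len(nrow(groups)), groups$group),
                             function(idx) {
                               if (length(idx) < 2L)
                                 stop("every group needs >= 2 samples to split")
                               sample(idx, ceiling(length(idx) / 2))
                             }), use.names = FALSE)
  train_idx <- sort(train_idx)
  list(train = groups[train_idx, , drop = FALSE],
       test = groups[-train_idx, , drop = FALSE])
}

#' Bootstrap evaluation of Jaccard-ranked vote models
#'
#' For each replicate, the samples are split half/half per group with
#' [bootstrap_split()] (replicate `r` uses seed `seed + r`), the full analysis
#' (state classification, interaction states, differential selection, Jaccard
#' ranking) is run independently on the training and on the test samples, a
#' model is built per Jaccard threshold from the training ranking, and the
#' test samples are classified from their own interaction states (model
#' interactions absent from the test-side regulated set are skipped in
#' voting). With the reference group as "positive", sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and the false-positive rate
#' `1 - specificity` are accumulated; the summary reports unweighted means
#' over the non-skipped replicates per threshold. A replicate is skipped for
#' a threshold when its training set yields no model (or either half yields
#' no regulated interactions).
#'
#' @inheritParams regulated_interactions
#' @param groups data.frame `sample_id`, `group` with exactly two groups.
#' @param n_replicates number of random splits.
#' @param ji_thresholds numeric vector of Jaccard thresholds to evaluate.
#' @param reference_group the "positive" group; defaults to the first label.
#' @param seed base integer seed.
#' @return data.frame of class `bootstrap_summary`: one row per threshold
#'   with `ji_threshold`, `mean_sensitivity`, `mean_specificity`, `mean_fpr`,
#'   `mean_model_size`, `n_replicates`, `n_skipped`.
#' @export
run_bootstrap <- function(mirna_expr, mrna_expr, probe_gene_map, catalog,
                          groups, config = cape_config(),
                          n_replicates = 100, ji_thresholds = c(0.8, 0.9, 1),
                          reference_group = unique(groups$group)[1L],
                          seed = config$rng_seed) {
  labs <- unique(groups$group)
  if (length(labs) != 2L) stop("bootstrapping needs exactly two groups")
  stopifnot(n_replicates >= 1)
  nt <- length(ji_thresholds)
  sens <- spec <- msize <- matrix(NA_real_, nrow = n_replicates, ncol = nt)

  for (r in seq_len(n_replicates)) {
    split <- bootstrap_split(groups, seed = seed + r)
    halves <- tryCatch({
      train <- suppressMessages(cape_pipeline(
        mirna_expr[, split$train$sample_id, drop = FALSE],
        mrna_expr[, split$train$sample_id, drop = FALSE],
        probe_gene_map, catalog, split$train, config))
      test <- suppressMessages(regulated_interactions(
        mirna_expr[, split$test$sample_id, drop = FALSE],
        mrna_expr[, split$test$sample_id, drop = FALSE],
        probe_gene_map, catalog, config))
      list(train = train, test = test)
    }, error = function(e) NULL)
    if (is.null(halves)) next
    truth <- split$test$group
    for (k in seq_len(nt)) {
      model <- tryCatch(build_model(halves$train$ranked, ji_thresholds[k],
                                    reference_group),
                        error = function(e) NULL)
      if (is.null(model)) next
      pred <- classify_samples(model, halves$test$regulated)
      pos <- truth == reference_group
      tp <- sum(pred[pos] == reference_group)
      fn <- sum(pos) - tp
      tn <- sum(pred[!pos] != reference_group)
      fp <- sum(!pos) - tn
      sens[r, k] <- tp / (tp + fn)
      spec[r, k] <- tn / (tn + fp)
      msize[r, k] <- nrow(model$interactions)
    }
  }

  out <- data.frame(
    ji_threshold = ji_thresholds,
    mean_sensitivity = colMeans(sens, na.rm = TRUE),
    mean_specificity = colMeans(spec, na.rm = TRUE),
    mean_fpr = 1 - colMeans(spec, na.rm = TRUE),
    mean_model_size = colMeans(msize, na.rm = TRUE),
    n_replicates = n_replicates,
    n_skipped = colSums(is.na(sens)))
  class(out) <- c("bootstrap_summary", "data.frame")
  out
}
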