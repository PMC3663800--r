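#' Read / write L/M/H state matrices
#'
#' State matrices are TSV with first column `id` and one column per sample;
#' cells are `L`, `M` or `H`. [write_probe_states()] additionally writes a
#' sidecar TSV of per-probe classification statistics next to the states.
#'
#' @param path TSV path.
#' @return [read_state_matrix()] returns a character matrix.
#' @export
read_state_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  bad <- setdiff(unique(as.vector(m)), c("L", "M", "H"))
  if (length(bad)) stop("invalid state(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  m
}

#' @rdname read_state_matrix
#' @param classified a `probe_states` object from [classify_matrix()].
#' @param states_path,stats_path output paths for the state matrix and the
#'   per-probe statistics.
#' @export
write_probe_states <- function(classified, states_path, stats_path = NULL) {
  stopifnot(inherits(classified, "probe_states"))
  df <- data.frame(id = rownames(classified$states), classified$states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, states_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(stats_path)) write_tsv(classified$stats, stats_path)
  invisible(states_path)
}

#' Read / write interaction-state tables
#'
#' Interaction-state TSVs have columns `mirna_id`, `gene_id`, then one column
#' per sample with cells from the nine-state alphabet.
#'
#' @param path TSV path.
#' @return [read_interaction_states()] returns an `interaction_states` object.
#' @export
read_interaction_states <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("interaction-state table needs sample columns")
  states <- as.matrix(tab[, -(1:2), drop = FALSE])
  alpha <- interaction_state_alphabet()
  bad <- setdiff(unique(as.vector(states)), alpha$S)
  if (length(bad)) stop("invalid interaction state(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  structure(list(interactions = data.frame(mirna_id = tab[[1L]],
                                           gene_id = tab[[2L]],
                                           stringsAsFactors = FALSE),
                 states = states),
            class = "interaction_states")
}

#' @rdname read_interaction_states
#' @param table an `interaction_states` object.
#' @export
write_interaction_states <- function(table, path) {
  stopifnot(inherits(table, "interaction_states"))
  df <- data.frame(table$interactions, table$states, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
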