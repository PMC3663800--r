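#' The nine-state interaction alphabet and its biological grouping
#'
#' An interaction state is the two-letter concatenation of the miRNA state and
#' the gene state, giving the alphabet
#' `S = {LH, HL, LM, HM, MH, ML, HH, LL, MM}`. The states group by biological
#' meaning: `S_compHL = {HL, ML, HM}` (miRNA up, hypothetical mRNA
#' down-regulation), `S_compLH = {LH, MH, LM}` (miRNA down, hypothetical mRNA
#' up-regulation) and `S_undef = {HH, LL, MM}` (combinations without that
#' interpretation). The three groups partition the alphabet.
#'
#' @format `interaction_state_alphabet()` returns a list with elements
#'   `S`, `S_compHL`, `S_compLH`, `S_undef`.
#' @export
interaction_state_alphabet <- function() {
  list(S = c("LH", "HL", "LM", "HM", "MH", "ML", "HH", "LL", "MM"),
       S_compHL = c("HL", "ML", "HM"),
       S_compLH = c("LH", "MH", "LM"),
       S_undef = c("HH", "LL", "MM"))
}

## comp-set membership of a state vector: "S_compHL", "S_compLH" or "S_undef"
comp_set_of <- function(states) {
  alpha <- interaction_state_alphabet()
  out <- rep(NA_character_, length(states))
  out[states %in% alpha$S_compHL] <- "S_compHL"
  out[states %in% alpha$S_compLH] <- "S_compLH"
  out[states %in% alpha$S_undef] <- "S_undef"
  if (anyNA(out)) stop("unknown interaction state(s): ",
                       paste(unique(states[is.na(out)]), collapse = ", "))
  out
}

#' Aggregate mRNA probe states to gene states
#'
#' For each sample, probes mapped to the same gene (EntrezGeneID-style) are
#' summarized by their most frequent state; ties are broken by the preference
#' order low (`L`), high (`H`), then medium (`M`).
#'
#' @param probe_states character matrix (probes x samples) over `L`/`M`/`H`.
#' @param probe_gene_map data.frame with columns `probe_id`, `gene_id`
#'   covering every probe row (unmapped probes are a hard error).
#' @return character matrix (genes x samples), gene order following first
#'   appearance in the probe rows.
#' @export
aggregate_gene_states <- function(probe_states, probe_gene_map) {
  probes <- rownames(probe_states)
  idx <- match(probes, probe_gene_map$probe_id)
  if (anyNA(idx))
    stop("probe(s) without gene mapping: ",
         paste(probes[is.na(idx)], collapse = ", "))
  gene <- probe_gene_map$gene_id[idx]
  genes <- unique(gene)
  pref <- c("L", "H", "M")
  out <- matrix(NA_character_, nrow = length(genes), ncol = ncol(probe_states),
                dimnames = list(genes, colnames(probe_states)))
  rows_by_gene <- split(seq_along(gene), factor(gene, levels = genes))
  for (g in seq_along(genes)) {
    sub <- probe_states[rows_by_gene[[g]], , drop = FALSE]
    out[g, ] <- apply(sub, 2L, function(col) {
      counts <- vapply(pref, function(s) sum(col == s), integer(1))
      pref[which.max(counts)]  # which.max takes the first max => L, H, M order
    })
  }
  out
}

#' Filter state rows by the ratio of medium-classified samples
#'
#' Removes every miRNA or gene row whose fraction of `M` states strictly
#' exceeds `r_M`; surviving rows keep their order. Rows with many medium
#' calls carry little level information and would flood the interaction table
#' with ambiguous states.
#'
#' @param state_matrix character matrix over `L`/`M`/`H` (rows: miRNAs at the
#'   probe level, or genes after aggregation — the filter applies to whatever
#'   level feeds [build_interaction_states()]).
#' @param r_M maximum tolerated medium fraction in \[0,1\].
#' @return the filtered state matrix.
#' @export
filter_by_medium_ratio <- function(state_matrix, r_M) {
  stopifnot(r_M >= 0, r_M <= 1)
  keep <- rowMeans(state_matrix == "M") <= r_M
  state_matrix[keep, , drop = FALSE]
}

#' Build per-sample interaction states
#'
#' For each catalog pair and each sample, the interaction state is the
#' concatenation of the miRNA state and the gene state in that order (miRNA
#' `L` with gene `H` gives `LH`). Catalog pairs whose miRNA or gene did not
#' survive the upstream filters are dropped with a message reporting the
#' count.
#'
#' @param mirna_states character matrix (miRNAs x samples) over `L`/`M`/`H`.
#' @param gene_states character matrix (genes x samples) over `L`/`M`/`H`,
#'   same samples in the same order.
#' @param catalog data.frame with columns `mirna_id`, `gene_id`.
#' @return object of class `interaction_states`: list with `interactions`
#'   (data.frame `mirna_id`, `gene_id`) and `states` (character matrix,
#'   interactions x samples, cells in the nine-state alphabet).
#' @export
build_interaction_states <- function(mirna_states, gene_states, catalog) {
  if (!identical(colnames(mirna_states), colnames(gene_states)))
    stop("miRNA and gene state matrices must share the same samples")
  mi <- match(catalog$mirna_id, rownames(mirna_states))
  gi <- match(catalog$gene_id, rownames(gene_states))
  ok <- !is.na(mi) & !is.na(gi)
  if (any(!ok))
    message(sum(!ok), " catalog pair(s) dropped: miRNA or gene not in the ",
            "filtered state matrices")
  if (!any(ok)) stop("no catalog pair is resolvable after filtering")
  states <- matrix(paste0(mirna_states[mi[ok], , drop = FALSE],
                          gene_states[gi[ok], , drop = FALSE]),
                   nrow = sum(ok),
                   dimnames = list(NULL, colnames(mirna_states)))
  structure(list(interactions = data.frame(mirna_id = catalog$mirna_id[ok],
                                           gene_id = catalog$gene_id[ok],
                                           stringsAsFactors = FALSE),
                 states = states),
            class = "interaction_states")
}

#' @export
print.interaction_states <- function(x, ...) {
  cat(sprintf("interaction states: %d interactions x %d samples\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' Filter interactions by the frequency of undefined states
#'
#' Removes interactions whose fraction of samples in `S_undef = {HH, LL, MM}`
#' strictly exceeds `u`. The survivors form the set of regulated
#' interactions.
#'
#' @param table an `interaction_states` object.
#' @param u maximum tolerated undefined fraction in \[0,1\].
#' @return the filtered `interaction_states` object.
#' @export
filter_by_undefined_frequency <- function(table, u) {
  stopifnot(inherits(table, "interaction_states"), u >= 0, u <= 1)
  alpha <- interaction_state_alphabet()
  undef_frac <- rowMeans(matrix(table$states %in% alpha$S_undef,
                                nrow = nrow(table$states)))
  keep <- undef_frac <= u
  structure(list(interactions = table$interactions[keep, , drop = FALSE],
                 states = table$states[keep, , drop = FALSE]),
            class = "interaction_states")
}

## modal interaction state of a character vector. Undefined states carry no
## biological interpretation, so a tie between a comp state and an undefined
## state resolves toward the comp state; a tie spanning both comp sets is
## genuinely ambiguous and disqualifies the interaction. Returns
## list(state, comp): comp is NA when ambiguous.
modal_state <- function(states) {
  tab <- table(states)
  top <- names(tab)[tab == max(tab)]
  comps <- comp_set_of(top)
  defined <- setdiff(unique(comps), "S_undef")
  if (length(defined) > 1L)
    return(list(state = NA_character_, comp = NA_character_))
  if (length(defined) == 1L)
    return(list(state = sort(top[comps == defined])[1L], comp = defined))
  list(state = sort(top)[1L], comp = "S_undef")
}

#' Select differentially regulated interactions between two groups
#'
#' An interaction is differentially regulated when the state with maximum
#' frequency in group A lies in `S_compHL` and the one in group B lies in
#' `S_compLH`, or reciprocally. On a modal tie, undefined states (which carry
#' no biological interpretation) yield to a tied comp state; a tie spanning
#' both comp sets is genuinely ambiguous and disqualifies the interaction.
#'
#' @param table an `interaction_states` object (normally the regulated set
#'   from [filter_by_undefined_frequency()]).
#' @param groups data.frame with columns `sample_id`, `group`; exactly two
#'   groups covering the table's samples.
#' @return data.frame with columns `mirna_id`, `gene_id`, `modal_state_A`,
#'   `modal_state_B`, `direction` (`A_down` when group A's modal state is in
#'   `S_compHL`, i.e. the miRNA is up and the target down in A; `A_up`
#'   reciprocally). Group A is the first group label in `groups` order.
#' @export
select_differential <- function(table, groups) {
  stopifnot(inherits(table, "interaction_states"))
  labs <- unique(groups$group)
  if (length(labs) != 2L)
    stop("differential selection needs exactly two groups, got ",
         length(labs))
  samp <- colnames(table$states)
  gidx <- match(samp, groups$sample_id)
  if (anyNA(gidx)) stop("sample(s) without group label: ",
                        paste(samp[is.na(gidx)], collapse = ", "))
  gl <- groups$group[gidx]
  a_cols <- gl == labs[1L]
  b_cols <- gl == labs[2L]
  n <- nrow(table$states)
  keep <- logical(n)
  mA <- mB <- dir <- character(n)
  for (i in seq_len(n)) {
    ma <- modal_state(table$states[i, a_cols])
    mb <- modal_state(table$states[i, b_cols])
    if (is.na(ma$comp) || is.na(mb$comp)) next
    if (ma$comp == "S_compHL" && mb$comp == "S_compLH") {
      keep[i] <- TRUE; dir[i] <- "A_down"
    } else if (ma$comp == "S_compLH" && mb$comp == "S_compHL") {
      keep[i] <- TRUE; dir[i] <- "A_up"
    } else next
    mA[i] <- ma$state; mB[i] <- mb$state
  }
  out <- data.frame(table$interactions[keep, , drop = FALSE],
                    modal_state_A = mA[keep], modal_state_B = mB[keep],
                    direction = dir[keep], stringsAsFactors = FALSE)
  attr(out, "group_labels") <- labs
  rownames(out) <- NULL
  out
}
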