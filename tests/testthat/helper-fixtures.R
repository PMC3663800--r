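# Reduced-size simulated dataset for unit tests (two groups, small catalog).
small_sim <- function(seed = 101, ...) {
  simulate_dataset(n_per_group = c(tumor = 6, normal = 6),
                   contrast = list(tumor = "tumor", normal = "normal"),
                   n_catalog = 80, n_planted = 15,
                   n_decoy_mirna = 40, n_decoy_gene = 50,
                   seed = seed, ...)
}

# ranked-interactions fixture with known Jaccard indices and modal states
ranked_fixture <- function(ji = c(1, 1, 0.8, 0.6, 0.4),
                           labs = c("tumor", "normal")) {
  n <- length(ji)
  out <- data.frame(mirna_id = sprintf("mir-%02d", seq_len(n)),
                    gene_id = sprintf("G%02d", seq_len(n)),
                    modal_state_A = rep("HL", n),
                    modal_state_B = rep("LH", n),
                    direction = rep("A_down", n),
                    jaccard_index = ji,
                    stringsAsFactors = FALSE)
  attr(out, "group_labels") <- labs
  out
}

interaction_key_str <- function(m, g) paste(m, g, sep = "::")
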