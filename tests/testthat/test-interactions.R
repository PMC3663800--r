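test_that("gene aggregation takes the modal probe state with L, H, M preference", {
  st <- rbind(p1 = c("L", "L", "M"),
              p2 = c("L", "H", "H"),
              p3 = c("H", "M", "M"),
              p4 = c("H", "M", "H"))
  colnames(st) <- paste0("S", 1:3)
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    gene_id = c("g1", "g1", "g1", "g2"))
  out <- aggregate_gene_states(st, map)
  # g1 per sample: {L,L,H} -> L; {L,H,M} tie -> L; {M,H,M} -> M
  expect_identical(out["g1", ], c(S1 = "L", S2 = "L", S3 = "M"))
  expect_identical(out["g2", ], c(S1 = "H", S2 = "M", S3 = "H"))
  # pairwise ties follow the stated preference order
  st2 <- rbind(a = c("L", "M"), b = c("H", "H"))
  colnames(st2) <- c("S1", "S2")
  map2 <- data.frame(probe_id = c("a", "b"), gene_id = c("g", "g"))
  expect_identical(aggregate_gene_states(st2, map2)["g", ],
                   c(S1 = "L", S2 = "H"))
  expect_error(aggregate_gene_states(st, map[1:3, ]), "p4")
})

test_that("the medium-ratio filter removes rows strictly above the threshold", {
  st <- rbind(allM = rep("M", 8),
              noM = rep(c("L", "H"), 4),
              threeM = c(rep("M", 3), rep("L", 5)))
  colnames(st) <- paste0("S", 1:8)
  out <- filter_by_medium_ratio(st, 0.5)
  expect_identical(rownames(out), c("noM", "threeM"))
  # 3/8 = 0.375 is not strictly greater than 0.375 -> kept
  expect_true("threeM" %in% rownames(filter_by_medium_ratio(st, 0.375)))
  expect_identical(rownames(filter_by_medium_ratio(st, 0)), "noM")
})

test_that("interaction states concatenate miRNA then gene state", {
  mir <- rbind(m1 = c("L", "H", "M"))
  gene <- rbind(g1 = c("H", "L", "M"))
  colnames(mir) <- colnames(gene) <- paste0("S", 1:3)
  tab <- build_interaction_states(mir, gene,
                                  data.frame(mirna_id = "m1", gene_id = "g1"))
  expect_identical(unname(tab$states[1, ]), c("LH", "HL", "MM"))
  # unresolvable pairs are dropped with a message, not an error
  cat2 <- data.frame(mirna_id = c("m1", "mX"), gene_id = c("g1", "g1"))
  expect_message(tab2 <- build_interaction_states(mir, gene, cat2), "dropped")
  expect_identical(nrow(tab2$states), 1L)
})

test_that("the nine-state alphabet partitions into the three comp groups", {
  alpha <- interaction_state_alphabet()
  expect_length(alpha$S, 9)
  expect_setequal(alpha$S,
                  as.vector(outer(c("L", "M", "H"), c("L", "M", "H"), paste0)))
  expect_setequal(c(alpha$S_compHL, alpha$S_compLH, alpha$S_undef), alpha$S)
  expect_length(intersect(alpha$S_compHL, alpha$S_compLH), 0)
})

test_that("the undefined-frequency filter uses a strict threshold", {
  mk <- function(states) structure(
    list(interactions = data.frame(mirna_id = paste0("m", seq_len(nrow(states))),
                                   gene_id = paste0("g", seq_len(nrow(states)))),
         states = states),
    class = "interaction_states")
  st <- rbind(rep("MM", 8),
              rep(c("HL", "LH"), 4),
              c(rep("HH", 4), rep("HL", 4)))
  colnames(st) <- paste0("S", 1:8)
  out <- filter_by_undefined_frequency(mk(st), 0.5)
  expect_identical(out$interactions$mirna_id, c("m2", "m3"))  # 4/8 kept at 0.5
  expect_identical(filter_by_undefined_frequency(mk(st), 0.4)$
                     interactions$mirna_id, "m2")
})

test_that("differential selection requires opposite modal comp sets", {
  groups <- data.frame(sample_id = paste0("S", 1:8),
                       group = rep(c("A", "B"), each = 4))
  mk <- function(...) {
    st <- rbind(...)
    colnames(st) <- paste0("S", 1:8)
    structure(list(interactions = data.frame(
      mirna_id = paste0("m", seq_len(nrow(st))),
      gene_id = paste0("g", seq_len(nrow(st)))), states = st),
      class = "interaction_states")
  }
  tab <- mk(c(rep("HL", 4), rep("LH", 4)),   # A_down
            c(rep("LH", 4), rep("HL", 4)),   # A_up
            c(rep("HL", 4), rep("HL", 4)),   # same side: not differential
            c(rep("MM", 4), rep("LH", 4)),   # A modal undefined: not selected
            c("HL", "HL", "HH", "HH", rep("LH", 4)),  # tie comp/undef -> comp
            c("HL", "HL", "LH", "LH", rep("LH", 4)))  # tie across comps -> out
  out <- select_differential(tab, groups)
  expect_identical(out$mirna_id, c("m1", "m2", "m5"))
  expect_identical(out$direction, c("A_down", "A_up", "A_down"))
  expect_identical(out$modal_state_A[3], "HL")
  expect_error(select_differential(tab, transform(groups, group = "A")),
               "two groups")
})
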