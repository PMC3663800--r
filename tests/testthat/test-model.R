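test_that("models include interactions at or above the Jaccard threshold", {
  ranked <- ranked_fixture(ji = c(1, 1, 1, 1, 1, 0.8, 0.6))
  expect_equal(nrow(build_model(ranked, 1)$interactions), 5)
  expect_equal(nrow(build_model(ranked, 0)$interactions), 7)
  m9 <- build_model(ranked, 0.9)$interactions
  m6 <- build_model(ranked, 0.6)$interactions
  expect_true(all(paste(m9$mirna_id, m9$gene_id) %in%
                    paste(m6$mirna_id, m6$gene_id)))  # lowering never shrinks
  expect_error(build_model(ranked_fixture(ji = c(0.3, 0.2)), 0.9),
               "lower the threshold")
  expect_identical(unique(build_model(ranked, 0)$interactions$comp_set),
                   "S_compHL")
  # reference group on the B side flips the model comp sets
  mB <- build_model(ranked, 0, reference_group = "normal")
  expect_identical(unique(mB$interactions$comp_set), "S_compLH")
})

test_that("randomized models are reproducible and range-validated", {
  ranked <- ranked_fixture(ji = c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1))
  a <- build_random_model(ranked, 3, c(0.4, 0.9), seed = 5)
  b <- build_random_model(ranked, 3, c(0.4, 0.9), seed = 5)
  expect_identical(a$interactions, b$interactions)
  full <- build_random_model(ranked, 6, c(0.4, 0.9), seed = 1)
  expect_equal(nrow(full$interactions), 6)  # range population 0.4..0.9
  expect_error(build_random_model(ranked, 7, c(0.4, 0.9), seed = 1),
               "only 6")
  draws <- vapply(1:20, function(s)
    paste(build_random_model(ranked, 3, c(0.1, 1), seed = s)$
            interactions$mirna_id, collapse = ","), character(1))
  expect_gt(length(unique(draws)), 1)
})

test_that("sample classification counts votes and breaks ties conservatively", {
  ranked <- ranked_fixture(ji = rep(1, 7))
  model <- build_model(ranked, 1)  # 7 interactions, all expect S_compHL
  keys <- interaction_key_str(model$interactions$mirna_id,
                              model$interactions$gene_id)
  st <- setNames(c("HL", "ML", "HM", "HL", "HL", "LH", "LH"), keys)
  lab <- classify_sample(model, st)
  expect_identical(as.character(lab), "tumor")
  expect_identical(attr(lab, "c_first"), 5L)
  expect_identical(attr(lab, "c_second"), 2L)
  # undefined states vote for neither side; a tie predicts the other group
  st_undef <- setNames(rep("MM", 7), keys)
  expect_identical(as.character(classify_sample(model, st_undef)), "normal")
  st_tie <- setNames(c("HL", "LH", "MM", "MM", "MM", "MM", "MM"), keys)
  expect_identical(as.character(classify_sample(model, st_tie)), "normal")
  # interactions missing from the sample are skipped
  lab2 <- classify_sample(model, st[1:3])
  expect_identical(attr(lab2, "n_skipped"), 4L)
  # invariant to the order of model interactions
  shuffled <- model
  shuffled$interactions <- model$interactions[c(4, 2, 7, 1, 3, 6, 5), ]
  expect_identical(as.character(classify_sample(shuffled, st)),
                   as.character(lab))
})

test_that("bootstrap splits halve each group, extra sample to training", {
  groups <- data.frame(sample_id = paste0("S", 1:16),
                       group = rep(c("inv", "noninv"), each = 8))
  sp <- bootstrap_split(groups, seed = 3)
  expect_equal(as.integer(table(sp$train$group)), c(4L, 4L))
  expect_equal(as.integer(table(sp$test$group)), c(4L, 4L))
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), groups$sample_id)
  # odd group of 7: 4 train / 3 test
  g7 <- data.frame(sample_id = paste0("T", 1:7), group = "only")
  sp7 <- bootstrap_split(g7, seed = 1)
  expect_equal(nrow(sp7$train), 4L)
  expect_equal(nrow(sp7$test), 3L)
  # colon-collective layout: groups of 4 and 7 -> train 2+4, test 2+3
  gc <- data.frame(sample_id = paste0("C", 1:11),
                   group = rep(c("healthy", "tumor"), c(4, 7)))
  spc <- bootstrap_split(gc, seed = 2)
  expect_equal(as.integer(table(spc$train$group)), c(2L, 4L))
  expect_equal(as.integer(table(spc$test$group)), c(2L, 3L))
  expect_identical(bootstrap_split(gc, seed = 2), spc)  # reproducible
})

test_that("bootstrap summaries are reproducible with rates in [0, 1]", {
  sim <- small_sim(seed = 5)
  bs <- run_bootstrap(sim$mirna, sim$mrna, sim$probe_gene_map, sim$catalog,
                      sim$diff_groups, n_replicates = 5,
                      ji_thresholds = c(0.5, 1), seed = 9)
  bs2 <- run_bootstrap(sim$mirna, sim$mrna, sim$probe_gene_map, sim$catalog,
                       sim$diff_groups, n_replicates = 5,
                       ji_thresholds = c(0.5, 1), seed = 9)
  expect_identical(as.data.frame(bs), as.data.frame(bs2))
  ok <- !is.nan(bs$mean_sensitivity)
  expect_true(all(bs$mean_sensitivity[ok] >= 0 & bs$mean_sensitivity[ok] <= 1))
  expect_true(all(bs$mean_specificity[ok] >= 0 &
                    bs$mean_specificity[ok] <= 1))
  expect_equal(bs$mean_fpr[ok], 1 - bs$mean_specificity[ok])
  expect_true(all(bs$n_skipped >= 0 & bs$n_skipped <= 5))
})

test_that("a perfect-Jaccard model classifies its own training samples perfectly", {
  sim <- small_sim(seed = 13, noise_sd = 0)
  res <- suppressMessages(cape_pipeline(sim$mirna, sim$mrna,
                                        sim$probe_gene_map, sim$catalog,
                                        sim$diff_groups))
  perfect <- res$ranked[res$ranked$jaccard_index == 1, , drop = FALSE]
  expect_gt(nrow(perfect), 0)
  model <- build_model(res$ranked, 1)
  pred <- classify_samples(model, res$regulated)
  truth <- sim$diff_groups$group[match(colnames(res$regulated$states),
                                       sim$diff_groups$sample_id)]
  expect_identical(pred, truth)
})
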