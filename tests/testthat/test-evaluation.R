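test_that("accuracy follows the confusion-matrix formula", {
  # all correct
  t1 <- prediction_table("q", sprintf("p%d", 1:4), c(1, 1, 0, 0),
                         c(0.9, 0.8, 0.1, 0.2))
  expect_identical(accuracy(t1), 1)
  # TP=3, TN=4, FP=2, FN=1 -> 0.7
  lab <- c(rep(1, 3), rep(0, 4), rep(0, 2), rep(1, 1))
  sc <- c(rep(0.9, 3), rep(0.1, 4), rep(0.9, 2), rep(0.1, 1))
  t2 <- prediction_table("q", sprintf("p%d", 1:10), lab, sc)
  expect_identical(accuracy(t2), 0.7)
  # counting oracle on random tables
  t3 <- rand_pred_table(500, seed = 71)
  expect_identical(accuracy(t3), ref_accuracy(t3))
  expect_error(accuracy(t2[0, ]), "empty")
})

test_that("AUC is the tie-aware pair-ranking statistic", {
  t1 <- prediction_table("q", sprintf("p%d", 1:6), c(1, 1, 1, 0, 0, 0),
                         c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  expect_identical(auc(t1), 1)
  t2 <- prediction_table("q", sprintf("p%d", 1:6), c(1, 1, 1, 0, 0, 0),
                         rep(0.5, 6))
  expect_identical(auc(t2), 0.5)
  # brute-force O(n^2) oracle, including deliberate ties
  tab <- rand_pred_table(200, seed = 73)
  tab$score <- round(tab$score, 2)
  expect_equal(auc(tab), ref_auc(tab$score, tab$label), tolerance = 1e-12)
  # independent library oracle
  expect_equal(auc(tab),
               as.numeric(pROC::auc(pROC::roc(tab$label, tab$score,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  # invariant under strictly monotone transforms of the scores
  tab2 <- tab; tab2$score <- plogis(5 * qlogis(tab$score) + 1)
  expect_equal(auc(tab2), auc(tab), tolerance = 1e-12)
  t3 <- prediction_table("q", "p1", 1, 0.5)
  expect_error(auc(t3), "single class")
})

test_that("top-K metrics match their counting oracles", {
  # trivial cases
  recs1 <- data.frame(query_id = "q1", rank = 1:10,
                      physician_id = sprintf("p%d", 1:10),
                      score = seq(0.9, 0.1, length.out = 10),
                      relevant = rep(1L, 10))
  expect_identical(precision_at_k(recs1, 10), 1)
  expect_identical(as.numeric(recall_at_k(recs1, 10)), 1)
  expect_identical(as.numeric(ndcg_at_k(recs1, 10)), 1)
  # 3 relevant in the top 10 -> precision 0.3
  recs2 <- recs1; recs2$relevant <- c(1L, 1L, 1L, rep(0L, 7))
  expect_identical(precision_at_k(recs2, 10), 0.3)
  # 2 of 4 relevant in the top 10 -> recall 0.5
  recs3 <- data.frame(query_id = "q1", rank = 1:12,
                      physician_id = sprintf("p%d", 1:12),
                      score = seq(0.95, 0.1, length.out = 12),
                      relevant = c(1L, 1L, rep(0L, 8), 1L, 1L))
  expect_identical(as.numeric(recall_at_k(recs3, 10)), 0.5)
  # single relevant item at rank 2: NDCG = log2(2)/log2(3)
  recs4 <- data.frame(query_id = "q1", rank = 1:5,
                      physician_id = sprintf("p%d", 1:5),
                      score = seq(0.9, 0.5, length.out = 5),
                      relevant = c(0L, 1L, 0L, 0L, 0L))
  expect_equal(as.numeric(ndcg_at_k(recs4, 10)), log(2) / log(3),
               tolerance = 1e-12)
  # macro-averaged counting oracles on 100 random queries
  recs <- rand_rec_table(nq = 100, nc = 15, seed = 75)
  expect_equal(precision_at_k(recs, 10), ref_precision_at_k(recs, 10),
               tolerance = 1e-12)
  expect_equal(as.numeric(recall_at_k(recs, 10)),
               ref_recall_at_k(recs, 10), tolerance = 1e-12)
  expect_equal(as.numeric(ndcg_at_k(recs, 10)), ref_ndcg_at_k(recs, 10),
               tolerance = 1e-12)
})

test_that("ranking metrics are invariant to relabeling physician ids", {
  recs <- rand_rec_table(nq = 30, nc = 12, seed = 77)
  # bijective relabeling (scores are distinct almost surely)
  ids <- unique(recs$physician_id)
  remap <- setNames(sprintf("z%03d", seq_along(ids)), ids)
  recs2 <- recs; recs2$physician_id <- unname(remap[recs$physician_id])
  expect_equal(precision_at_k(recs2, 10), precision_at_k(recs, 10))
  expect_equal(as.numeric(recall_at_k(recs2, 10)),
               as.numeric(recall_at_k(recs, 10)))
  expect_equal(as.numeric(ndcg_at_k(recs2, 10)),
               as.numeric(ndcg_at_k(recs, 10)))
})

test_that("exposure and coverage are exact slot/set fractions", {
  tiers <- structure(c(p1 = "head", p2 = "head", p3 = "middle",
                       p4 = "tail", p5 = "tail", p6 = "tail"),
                     class = "tier_assignment")
  # 2 queries x top-10 with 4 head slots -> head exposure 0.2
  mk <- function(q, ids) data.frame(query_id = q, rank = seq_along(ids),
                                    physician_id = ids, score = 0.5,
                                    relevant = 0L)
  recs <- rbind(mk("q1", c("p1", "p2", rep(c("p3", "p4"), 4))),
                mk("q2", c("p1", "p2", rep(c("p5", "p6"), 4))))
  er <- exposure_rate(recs, tiers, 10)
  expect_identical(unname(er["head"]), 0.2)
  expect_equal(sum(er), 1, tolerance = 1e-12)
  # all recommendations from one physician: its tier covers everything
  recs1 <- mk("q1", rep("p4", 10))
  expect_identical(unname(coverage_contribution(recs1, tiers, 10)["tail"]),
                   1)
  # distinct sets {2 head, 3 tail} -> coverage 0.4 / 0.6
  recs2 <- mk("q1", c("p1", "p2", "p4", "p5", "p6"))
  cc <- coverage_contribution(recs2, tiers, 10)
  expect_identical(unname(cc["head"]), 0.4)
  expect_identical(unname(cc["tail"]), 0.6)
  # random slot/set-counting oracle
  recs3 <- rand_rec_table(nq = 40, nc = 12, seed = 79)
  tiers3 <- rand_tiers(unique(recs3$physician_id), seed = 80)
  expect_equal(exposure_rate(recs3, tiers3, 10),
               ref_exposure(recs3, tiers3, 10), tolerance = 1e-12)
  expect_equal(coverage_contribution(recs3, tiers3, 10),
               ref_coverage(recs3, tiers3, 10), tolerance = 1e-12)
  expect_equal(sum(exposure_rate(recs3, tiers3, 10)), 1, tolerance = 1e-12)
  expect_equal(sum(coverage_contribution(recs3, tiers3, 10)), 1,
               tolerance = 1e-12)
  # unassigned physician is an error
  expect_error(exposure_rate(mk("q1", "zz"), tiers, 10), "without a tier")
})

test_that("evaluate_model reports every split and tier", {
  gen <- tiny_gen(seed = 81, n_interactions = 200)
  sp <- split_dataset(gen$corpus$interactions, gen$corpus$physicians,
                      seed = 81)
  m <- train_matcher(gen$corpus, sp, tiny_cfg(batch_size = 128L,
                                              epochs = 1L), seed = 9)
  rep <- evaluate_model(m, gen$corpus, sp$test, seed = 3)
  expect_s3_class(rep, "metric_report")
  expect_identical(rep$splits$split, c("cold", "warm", "all"))
  expect_identical(rep$tiers$tier, c("head", "middle", "tail"))
  expect_true(all(c("acc", "auc", "precision_at_k", "recall_at_k",
                    "ndcg_at_k") %in% names(rep$splits)))
  ok <- !is.na(rep$splits$acc)
  expect_true(all(rep$splits$acc[ok] >= 0 & rep$splits$acc[ok] <= 1))
  expect_equal(sum(rep$tiers$exposure_rate), 1, tolerance = 1e-9)
  expect_equal(sum(rep$tiers$coverage_contribution), 1, tolerance = 1e-9)
})

test_that("the ablation harness reports one summary row per variant", {
  gen <- tiny_gen(seed = 83, n_interactions = 150)
  sp <- split_dataset(gen$corpus$interactions, gen$corpus$physicians,
                      seed = 83)
  out <- run_ablation(gen$corpus, sp,
                      variants = ablation_variants()["E3"],
                      seeds = 1, config = tiny_cfg(batch_size = 128L,
                                                   epochs = 1L))
  expect_identical(nrow(out$summary), 1L)
  expect_identical(out$summary$variant, "E3")
  expect_identical(nrow(out$runs), 1L)
  expect_error(run_ablation(gen$corpus, sp, variants = list(), seeds = 1),
               "no variants")
})
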