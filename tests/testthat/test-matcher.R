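mk_model <- function(seed = 51, cfg = tiny_cfg(), gen = NULL) {
  gen <- gen %||% tiny_gen(seed = seed, n_interactions = 40)
  vocab <- build_vocab(gen$corpus$queries, gen$corpus$physicians)
  init_model(vocab, cfg, seed = seed)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("score_pair is the logistic of the head output", {
  cfg <- tiny_cfg(fc_depth = 1L, inner_product_term = FALSE)
  model <- mk_model(cfg = cfg)
  e <- rnorm(cfg$d_match); r <- rnorm(cfg$d_match)
  # all-zero head: score exactly 0.5
  model$params$fc1_W[] <- 0; model$params$fc1_b[] <- 0
  expect_identical(score_pair(e, r, model), 0.5)
  # closed-form logistic of the bias
  for (u in c(-2, 0, 3)) {
    model$params$fc1_b[] <- u
    expect_equal(score_pair(e, r, model), 1 / (1 + exp(-u)),
                 tolerance = 1e-12)
  }
  expect_error(score_pair(e[-1], r, model), "d_match")
})

test_that("depth-4 head matches a straight-line forward oracle", {
  set.seed(52)
  cfg <- tiny_cfg(fc_depth = 4L)
  model <- mk_model(cfg = cfg)
  for (i in 1:20) {
    e <- rnorm(cfg$d_match); r <- rnorm(cfg$d_match)
    ref <- ref_fc_score(c(e, r), model$params, 4L,
                        inner_product = TRUE, e = e, r = r)
    expect_equal(score_pair(e, r, model), ref, tolerance = 1e-6)
  }
  # scores strictly inside (0, 1) over many random pairs
  Z <- matrix(rnorm(2000 * 2 * cfg$d_match), 2000)
  logit <- ohcmatch:::fc_fwd(Z, model$params, cfg)$logit
  s <- ohcmatch:::sigmoid(logit +
    rowSums(Z[, 1:cfg$d_match] * Z[, cfg$d_match + 1:cfg$d_match]))
  expect_true(all(s > 0 & s < 1))
})

test_that("rank_candidates orders by score with the id tie rule", {
  gen <- tiny_gen(seed = 53, n_interactions = 40)
  model <- mk_model(gen = gen)
  q <- gen$corpus$queries[[1]]
  # candidates with replies inside the query's recent window, so the
  # single-physician encoding oracle is defined for all of them
  active <- vapply(gen$corpus$physicians, function(p)
    length(select_recent(p$reply_history, q$timestamp)) > 0, logical(1))
  cands <- gen$corpus$physicians[active][1:min(20, sum(active))]
  expect_gte(length(cands), 5)
  # singleton
  one <- rank_candidates(q, cands[1], model)
  expect_identical(nrow(one), 1L)
  expect_identical(one$rank, 1L)
  # equal scores (zeroed model) fall back to id-ascending order
  m0 <- model
  for (nm in names(m0$params)) m0$params[[nm]][] <- 0
  m0$config$inner_product_term <- FALSE
  tied <- rank_candidates(q, cands, m0)
  expect_identical(tied$physician_id, sort(names(cands)))
  # sort oracle on independently computed scores
  rk <- rank_candidates(q, cands, model)
  e <- encode_patient(q, model)$e
  sc <- vapply(cands, function(p)
    score_pair(e, encode_physician(p, q$timestamp, model,
                                   augmenter = NULL)$r, model),
    numeric(1))
  expect_equal(rk$score, unname(sort(sc, decreasing = TRUE)),
               tolerance = 1e-10)
  expect_identical(rk$physician_id[1],
                   names(sc)[order(-sc, names(sc))][1])
})

test_that("cold augmenter looks up, falls back, and tracks specialty", {
  gen <- make_cold_corpus(generator_config(
    n_interactions = 300, n_patients = 120, n_physicians = 500,
    content_len_mean = 20, reply_len_mean = 10, mean_replies = 25,
    seed = 57), fraction = 0.3)
  cfg <- tiny_cfg()
  vocab <- build_vocab(gen$corpus$queries, gen$corpus$physicians)
  model <- init_model(vocab, cfg, seed = 59)
  augm <- build_cold_augmenter(model, gen$corpus)
  cold <- gen$corpus$physicians[gen$cold_ids]
  p <- cold[[1]]
  # exact key lookup
  k3 <- paste(p$specialty_id, p$title_rank, p$hospital_tier, sep = "|")
  if (k3 %in% rownames(augm$kb_exact))
    expect_equal(augment_cold_physician(p, augm),
                 as.vector(augm$kb_exact[k3, ]))
  # unseen key falls back to the specialty mean
  p2 <- p; p2$hospital_tier <- 99L
  expect_equal(augment_cold_physician(p2, augm),
               as.vector(augm$kb_spec[p2$specialty_id, ]))
  # unseen specialty falls back to the global mean
  p3 <- p; p3$specialty_id <- "sX"
  expect_equal(augment_cold_physician(p3, augm), augm$global)
  # warm physician violates the precondition
  counts <- vapply(gen$corpus$physicians, `[[`, integer(1), "reply_count")
  warm1 <- gen$corpus$physicians[[which.max(counts)]]
  expect_error(augment_cold_physician(warm1, augm), "not cold")
  # nearest-centroid oracle: the surrogate sits closer (cosine) to the
  # same-specialty warm centroid than to other specialties' centroids
  warm_ids <- setdiff(names(gen$corpus$physicians), gen$cold_ids)
  rd <- ohcmatch:::encode_rd_batch(model, gen$corpus$physicians[warm_ids],
                                   augm$now)
  spec <- vapply(gen$corpus$physicians[warm_ids], `[[`, character(1),
                 "specialty_id")
  keep <- rowSums(rd != 0) > 0
  cent <- rowsum(rd[keep, ], spec[keep]) /
    as.vector(table(spec[keep])[sort(unique(spec[keep]))])
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  hits <- 0
  for (pc in cold[1:10]) {
    sur <- augment_cold_physician(pc, augm)
    cs <- apply(cent, 1, cosine, a = sur)
    if (names(which.max(cs)) == pc$specialty_id) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("sparse-query expansion adds lexicon tokens monotonically", {
  q <- patient_query("q1", c("fever", "cough"), c("cough", "bad", "pain"),
                     timestamp = 1)
  augm <- structure(list(lexicon = list(), cold_threshold = 5L),
                    class = "cold_augmenter")
  # empty lexicon: identity
  expect_identical(augment_sparse_query(q, augm), q)
  # toy lexicon appends the expansion
  augm$lexicon <- list(cough = "tussis")
  q2 <- augment_sparse_query(q, augm)
  expect_identical(q2$content_tokens, c("cough", "bad", "pain", "tussis"))
  expect_identical(q2$title_tokens, q$title_tokens)
  # expansion never shrinks the content
  augm$lexicon <- list(cough = c("tussis", "pain"), fever = "pyrexia")
  q3 <- augment_sparse_query(q, augm)
  expect_gte(length(q3$content_tokens), length(q$content_tokens))
  expect_true(all(q$content_tokens %in% q3$content_tokens))
  # above the sparse threshold the query is unchanged
  qlong <- patient_query("q2", "t", rep("w", 20), timestamp = 1)
  expect_identical(augment_sparse_query(qlong, augm), qlong)
})

test_that("training is seed-reproducible and learns an easy corpus", {
  gen <- generate_corpus(generator_config(
    n_interactions = 800, n_patients = 200, n_physicians = 50,
    signal_strength = 1, match_prob_same = 1, match_prob_diff = 0,
    content_len_mean = 20, reply_len_mean = 10, mean_replies = 20,
    seed = 61))
  sp <- split_dataset(gen$corpus$interactions, gen$corpus$physicians,
                      seed = 61)
  cfg <- ohc_config(d_emb = 32L, d_conv = 32L, d_h = 32L, d_match = 64L,
                    max_title_len = 8L, max_content_len = 24L,
                    max_tag_len = 4L, max_profile_len = 8L,
                    max_reply_len = 12L, fc_depth = 3L, batch_size = 64L,
                    epochs = 10L, patience = 10L)
  m1 <- train_matcher(gen$corpus, sp, cfg, seed = 7)
  m2 <- train_matcher(gen$corpus, sp, cfg, seed = 7)
  expect_identical(m1$log$train_loss[1], m2$log$train_loss[1])
  expect_identical(m1$params, m2$params)
  # an easy, fully separable corpus is learned well above chance
  sc <- predict_pairs(m1, gen$corpus, sp$test)
  expect_true(all(sc > 0 & sc < 1))
  expect_gt(ohcmatch:::auc_scores(sc, sp$test$label), 0.9)
  # training loss decreases on the easy corpus
  expect_lt(m1$log$train_loss[nrow(m1$log)], m1$log$train_loss[1])
})

test_that("cold interactions are scorable with augmentation enabled", {
  gen <- make_cold_corpus(generator_config(
    n_interactions = 200, n_patients = 100, n_physicians = 40,
    content_len_mean = 15, reply_len_mean = 8, mean_replies = 20,
    seed = 63), fraction = 0.4)
  sp <- split_dataset(gen$corpus$interactions, gen$corpus$physicians,
                      seed = 63)
  cfg <- tiny_cfg(batch_size = 128L, epochs = 1L)
  m <- train_matcher(gen$corpus, sp, cfg, seed = 5)
  augm <- build_cold_augmenter(m, gen$corpus)
  cold_inter <- rbind(sp$train[sp$train$cold, ], sp$test[sp$test$cold, ])
  expect_gt(nrow(cold_inter), 0)
  sc <- predict_pairs(m, gen$corpus, cold_inter, augmenter = augm)
  expect_true(all(is.finite(sc) & sc > 0 & sc < 1))
})

test_that("checkpoints round-trip bit-exactly", {
  model <- mk_model(seed = 65)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back, model)
})

test_that("ablation variants gate the inputs they name", {
  expect_error(init_model(mk_model()$vocab, tiny_cfg(),
                          variant = list(patient_fields = character(),
                                         physician_sources = character())),
               "no input fields")
  expect_error(init_model(mk_model()$vocab, tiny_cfg(),
                          variant = list(patient_fields = "bogus")),
               "unknown field")
  # disabled fields collapse to the null token sequence
  gen <- tiny_gen(seed = 67, n_interactions = 40)
  toks <- ohcmatch:::query_field_tokens(gen$corpus$queries[[1]],
                                        fields = "title")
  expect_identical(toks$content, "<null>")
  expect_identical(toks$tags, "<null>")
  expect_false(identical(toks$title, "<null>"))
})
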