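test_that("embedding lookup honours the pad convention", {
  tab <- embedding_table(5, d_emb = 2, seed = 1)
  expect_identical(embed_tokens(c(0L, 0L), tab), matrix(0, 2, 2))
  out <- embed_tokens(c(3L, 3L, 1L), tab)
  expect_identical(out[1, ], out[2, ])
  # direct lookup oracle against a hand-written table
  hand <- matrix(as.numeric(1:10), 5, 2)
  hand[1, ] <- 0
  expect_identical(embed_tokens(c(2L, 4L, 1L), hand),
                   hand[c(3L, 5L, 2L), ])
  expect_error(embed_tokens(5L, tab), "out of range")
})

test_that("conv_window implements the width-3 window with ReLU", {
  ps <- conv_attn_params(d_emb = 2, d_conv = 3, seed = 2)
  W <- matrix(rnorm(8), 4, 2)
  # zero weights: every position is relu(bc)
  ps0 <- ps; ps0$Wc[] <- 0; ps0$bc <- c(-1, 0.5, 2)
  out0 <- conv_window(W, ps0)
  expect_equal(out0, matrix(rep(c(0, 0.5, 2), each = 4), 4, 3))
  # ReLU is one-sided: negative pre-activations are exactly zero
  psn <- ps; psn$Wc[] <- 0; psn$bc <- rep(-3, 3)
  expect_identical(conv_window(W, psn), matrix(0, 4, 3))
  # brute-force sliding-window oracle
  out <- conv_window(W, ps)
  expect_identical(dim(out), c(4L, 3L))
  for (i in 1:4) {
    prev <- if (i == 1) c(0, 0) else W[i - 1, ]
    nxt <- if (i == 4) c(0, 0) else W[i + 1, ]
    win <- c(prev, W[i, ], nxt)
    for (j in 1:3)
      expect_equal(out[i, j], max(0, sum(ps$Wc[, j] * win) + ps$bc[j]),
                   tolerance = 1e-12)
  }
  expect_error(conv_window(W, conv_attn_params(d_emb = 3, d_conv = 2)),
               "does not match")
})

test_that("attention_pool normalizes, pools convexly and masks", {
  ps <- conv_attn_params(d_emb = 2, d_conv = 3, seed = 3)
  # equal scores: uniform weights, pooled = mean
  C <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  ap <- attention_pool(C, ps)
  expect_equal(ap$weights, rep(0.25, 4))
  expect_equal(ap$pooled, colMeans(C))
  # closed-form softmax: alpha = (ln 2, 0) -> weights (2/3, 1/3)
  ps1 <- list(v = 1, vb = 0)
  C1 <- matrix(c(atanh(log(2)), 0), 2, 1)
  ap1 <- attention_pool(C1, ps1)
  expect_equal(ap1$weights, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # brute-force weighted-sum oracle on random features
  set.seed(4)
  C2 <- matrix(rnorm(15), 5, 3)
  ap2 <- attention_pool(C2, ps)
  alpha <- tanh(C2 %*% ps$v + ps$vb)
  a <- exp(alpha) / sum(exp(alpha))
  expect_equal(ap2$pooled, as.vector(t(C2) %*% a), tolerance = 1e-12)
  # permuting masked positions leaves the output unchanged
  mask <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  apm <- attention_pool(C2, ps, mask)
  C3 <- C2[c(1, 2, 4, 3, 5), ]
  apm2 <- attention_pool(C3, ps, mask[c(1, 2, 4, 3, 5)])
  expect_equal(apm$pooled, apm2$pooled)
  expect_equal(sum(apm$weights), 1)
  expect_identical(apm$weights[!mask], c(0, 0))
  expect_error(attention_pool(C2, ps, rep(FALSE, 5)), "masked")
})

test_that("encode_field equals the manual composition and the oracle", {
  tab <- embedding_table(12, d_emb = 4, seed = 5)
  ps <- conv_attn_params(d_emb = 4, d_conv = 6, seed = 6)
  ids <- c(3L, 7L, 2L, 0L, 0L)
  fe <- encode_field(ids, tab, ps)
  manual <- attention_pool(conv_window(embed_tokens(ids, tab), ps), ps,
                           mask = ids > 0L)
  expect_equal(fe$pooled, manual$pooled)
  ref <- ref_encode_field(ids, tab, ps$Wc, ps$bc, ps$v, ps$vb)
  expect_equal(fe$pooled, ref$pooled, tolerance = 1e-10)
  expect_equal(fe$weights, ref$weights, tolerance = 1e-10)
  # single real token: pooled equals that position's features exactly
  fe1 <- encode_field(c(9L, 0L), tab, ps)
  expect_equal(fe1$pooled, fe1$features[1, ])
  expect_equal(sum(fe1$weights), 1)
})

test_that("attention weights are a distribution and pooling is convex", {
  tab <- embedding_table(30, d_emb = 5, seed = 7)
  ps <- conv_attn_params(d_emb = 5, d_conv = 4, seed = 8)
  set.seed(9)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    ids <- c(sample(2:29, n, replace = TRUE),
             rep(0L, sample(0:3, 1)))
    fe <- encode_field(ids, tab, ps)
    expect_lt(abs(sum(fe$weights) - 1), 1e-6)
    expect_true(all(fe$weights >= 0))
    real <- fe$features[seq_len(n), , drop = FALSE]
    expect_true(all(fe$pooled >= apply(real, 2, min) - 1e-12))
    expect_true(all(fe$pooled <= apply(real, 2, max) + 1e-12))
  }
})

test_that("batched field encoder agrees with the single-sequence ops", {
  gen <- tiny_gen(seed = 23, n_interactions = 40)
  cfg <- tiny_cfg()
  vocab <- build_vocab(gen$corpus$queries, gen$corpus$physicians)
  params <- ohcmatch:::init_params(vocab, cfg, 31)
  qs <- gen$corpus$queries[1:8]
  ids <- ohcmatch:::id_matrix(lapply(qs, `[[`, "title_tokens"), vocab,
                              cfg$max_title_len)
  batched <- ohcmatch:::enc_field_fwd(
    ids, ohcmatch:::fpars(params, "title"), params$emb)$pooled
  for (b in seq_len(8)) {
    single <- encode_field(ids[b, ], params$emb,
                           ohcmatch:::fpars(params, "title"))
    expect_equal(batched[b, ], single$pooled, tolerance = 1e-12)
  }
})

test_that("encode_patient fuses fields independently", {
  gen <- tiny_gen(seed = 25, n_interactions = 40)
  cfg <- tiny_cfg()
  vocab <- build_vocab(gen$corpus$queries, gen$corpus$physicians)
  model <- init_model(vocab, cfg, seed = 33)
  q1 <- gen$corpus$queries[[1]]
  q2 <- q1
  q2$content_tokens <- rev(gen$corpus$queries[[2]]$content_tokens)
  e1 <- encode_patient(q1, model)
  e2 <- encode_patient(q2, model)
  # only the content encoding may differ
  expect_equal(e1$fields$title$pooled, e2$fields$title$pooled)
  expect_equal(e1$fields$tags$pooled, e2$fields$tags$pooled)
  expect_equal(e1$fields$profile$pooled, e2$fields$profile$pooled)
  expect_false(isTRUE(all.equal(e1$fields$content$pooled,
                                e2$fields$content$pooled)))
  expect_length(e1$e, cfg$d_match)
  # identity-like projection: d_match = 4 d_conv and identity matrix
  cfg2 <- tiny_cfg(d_match = 40L)  # 4 * d_conv
  model2 <- init_model(vocab, cfg2, seed = 33)
  model2$params$proj_p_W <- diag(40)
  model2$params$proj_p_b <- numeric(40)
  e3 <- encode_patient(q1, model2)
  expect_equal(e3$e, c(e3$fields$title$pooled, e3$fields$content$pooled,
                       e3$fields$tags$pooled, e3$fields$profile$pooled))
})

test_that("encode_credentials is deterministic in the credential fields", {
  gen <- tiny_gen(seed = 27, n_interactions = 40)
  vocab <- build_vocab(gen$corpus$queries, gen$corpus$physicians)
  model <- init_model(vocab, tiny_cfg(), seed = 35)
  p1 <- gen$corpus$physicians[[1]]
  p2 <- p1
  p2$physician_id <- "other"
  p2$reply_history <- list()
  expect_equal(encode_credentials(p1, model)$r_s,
               encode_credentials(p2, model)$r_s)
})
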