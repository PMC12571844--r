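# Straight-line reference implementations used as independent oracles.
# Everything here is deliberately naive (scalar loops, O(n^2) counting)
# and shares no code with the package internals.

ref_relu <- function(x) ifelse(x > 0, x, 0)
ref_sigmoid <- function(x) 1 / (1 + exp(-x))

# field encoder: embedding lookup -> width-3 convolution -> masked
# tanh-score softmax attention pooling, one scalar at a time
ref_encode_field <- function(ids, table, Wc, bc, v, vb) {
  n <- length(ids)
  de <- ncol(table)
  dc <- length(bc)
  emb <- function(i) if (i < 1L || i > n) rep(0, de) else table[ids[i] + 1L, ]
  C <- matrix(0, n, dc)
  for (i in seq_len(n)) {
    win <- c(emb(i - 1L), emb(i), emb(i + 1L))
    for (j in seq_len(dc)) C[i, j] <- ref_relu(sum(Wc[, j] * win) + bc[j])
  }
  alpha <- numeric(n)
  for (i in seq_len(n)) alpha[i] <- tanh(sum(v * C[i, ]) + vb)
  mask <- ids > 0L
  ex <- ifelse(mask, exp(alpha), 0)
  a <- ex / sum(ex)
  pooled <- rep(0, dc)
  for (i in seq_len(n)) pooled <- pooled + a[i] * C[i, ]
  list(C = C, weights = a, pooled = pooled)
}

ref_gru_step <- function(h_prev, x, Wz, Wr, W) {
  d_h <- length(h_prev)
  cat_hx <- c(h_prev, x)
  z <- r <- numeric(d_h)
  for (j in seq_len(d_h)) {
    z[j] <- ref_sigmoid(sum(Wz[, j] * cat_hx))
    r[j] <- ref_sigmoid(sum(Wr[, j] * cat_hx))
  }
  cat2 <- c(r * h_prev, x)
  htil <- numeric(d_h)
  for (j in seq_len(d_h)) htil[j] <- tanh(sum(W[, j] * cat2))
  (1 - z) * h_prev + z * htil
}

ref_bigru <- function(E, pf, pb) {
  k <- nrow(E); d_h <- pf$d_h
  Hf <- matrix(0, k, d_h); Hb <- matrix(0, k, d_h)
  h <- rep(0, d_h)
  for (t in seq_len(k)) {
    h <- ref_gru_step(h, E[t, ], pf$Wz, pf$Wr, pf$W)
    Hf[t, ] <- h
  }
  h <- rep(0, d_h)
  for (t in rev(seq_len(k))) {
    h <- ref_gru_step(h, E[t, ], pb$Wz, pb$Wr, pb$W)
    Hb[t, ] <- h
  }
  (Hf + Hb) / 2
}

ref_fc_score <- function(z, params, depth, inner_product = FALSE,
                         e = NULL, r = NULL) {
  a <- z
  for (i in seq_len(depth)) {
    W <- params[[paste0("fc", i, "_W")]]
    b <- params[[paste0("fc", i, "_b")]]
    out <- numeric(ncol(W))
    for (j in seq_len(ncol(W))) out[j] <- sum(W[, j] * a) + b[j]
    a <- if (i < depth) ref_relu(out) else out
  }
  u <- a[1L]
  if (inner_product) u <- u + sum(e * r)
  ref_sigmoid(u)
}

# --- metric oracles -------------------------------------------------------

ref_accuracy <- function(tab) {
  tp <- sum(tab$predicted == 1 & tab$label == 1)
  tn <- sum(tab$predicted == 0 & tab$label == 0)
  fp <- sum(tab$predicted == 1 & tab$label == 0)
  fn <- sum(tab$predicted == 0 & tab$label == 1)
  (tp + tn) / (tp + tn + fp + fn)
}

ref_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

ref_precision_at_k <- function(recs, k) {
  per <- sapply(unique(recs$query_id), function(q) {
    d <- recs[recs$query_id == q, ]
    d <- d[order(d$rank), ]
    kk <- min(k, nrow(d))
    sum(d$relevant[seq_len(kk)]) / kk
  })
  mean(per)
}

ref_recall_at_k <- function(recs, k) {
  per <- sapply(unique(recs$query_id), function(q) {
    d <- recs[recs$query_id == q, ]
    nrel <- sum(d$relevant)
    if (nrel == 0) return(NA_real_)
    sum(d$relevant[d$rank <= k]) / nrel
  })
  mean(per, na.rm = TRUE)
}

ref_ndcg_at_k <- function(recs, k) {
  per <- sapply(unique(recs$query_id), function(q) {
    d <- recs[recs$query_id == q, ]
    nrel <- sum(d$relevant)
    if (nrel == 0) return(NA_real_)
    d <- d[order(d$rank), ]
    dcg <- 0
    for (i in seq_len(min(k, nrow(d))))
      dcg <- dcg + d$relevant[i] / log2(i + 1)
    idcg <- 0
    for (i in seq_len(min(k, nrel))) idcg <- idcg + 1 / log2(i + 1)
    dcg / idcg
  })
  mean(per, na.rm = TRUE)
}

ref_exposure <- function(recs, tiers, k) {
  top <- recs[recs$rank <= k, ]
  out <- c(head = 0, middle = 0, tail = 0)
  for (t in names(out))
    out[t] <- sum(tiers[top$physician_id] == t) / nrow(top)
  out
}

ref_coverage <- function(recs, tiers, k) {
  ids <- unique(recs$physician_id[recs$rank <= k])
  out <- c(head = 0, middle = 0, tail = 0)
  for (t in names(out)) out[t] <- sum(tiers[ids] == t) / length(ids)
  out
}

# --- random fixtures ------------------------------------------------------

rand_pred_table <- function(n, seed) {
  withr::with_seed(seed, {
    prediction_table(
      query_id = sample(sprintf("q%d", 1:20), n, replace = TRUE),
      physician_id = sprintf("p%d", seq_len(n)),
      label = rbinom(n, 1, 0.4),
      score = runif(n, 0.01, 0.99))
  })
}

# random recommendation table: nq queries, each with nc ranked candidates
rand_rec_table <- function(nq, nc, seed, tie_scores = FALSE) {
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nq), function(q) {
      sc <- if (tie_scores) sample(c(0.3, 0.6, 0.9), nc, replace = TRUE)
        else runif(nc, 0.01, 0.99)
      pid <- sample(sprintf("p%02d", 1:(3 * nc)), nc)
      ord <- order(-sc, pid)
      data.frame(query_id = sprintf("q%02d", q), rank = seq_len(nc),
                 physician_id = pid[ord], score = sc[ord],
                 relevant = rbinom(nc, 1, 0.3),
                 stringsAsFactors = FALSE)
    }))
    class(rows) <- c("rec_table", "data.frame")
    rows
  })
}

rand_tiers <- function(ids, seed) {
  withr::with_seed(seed, {
    structure(setNames(sample(c("head", "middle", "tail"), length(ids),
                              replace = TRUE, prob = c(0.1, 0.4, 0.5)),
                       ids),
              class = "tier_assignment")
  })
}

# small generated corpus for pipeline tests
tiny_gen <- function(seed = 1L, n_interactions = 300L, ...) {
  generate_corpus(generator_config(
    n_interactions = n_interactions, n_patients = 120L, n_physicians = 40L,
    content_len_mean = 20, reply_len_mean = 10, mean_replies = 20L,
    seed = seed, ...))
}

# a small config that keeps encoder tests fast
tiny_cfg <- function(...) {
  ohc_config(d_emb = 8L, d_conv = 10L, d_h = 6L, d_match = 16L,
             max_title_len = 6L, max_content_len = 12L, max_tag_len = 4L,
             max_profile_len = 6L, max_reply_len = 8L, fc_depth = 3L, ...)
}
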