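# Batched neural engine: forward and backward passes for the dual-channel
# matching model. All heavy operations are dense matrix products so the
# work is done by BLAS; sequences are flattened column-major (position
# index p = (l-1)*B + b) and pooled with rowsum() over owner groups.
#
# Orientation conventions:
#   field conv:  S = Xw %*% Wc + bc,  Xw: N x 3*d_emb, Wc: 3*d_emb x d_conv
#   GRU gates:   g = sigmoid(cbind(h, x) %*% Wg),  Wg: (d_h + d_in) x d_h
#   FC layers:   A = relu(Z %*% W + b),            W: in x out
# Biases are added with rep(b, each = N) (column-major broadcast).

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

add_rowvec <- function(S, b) S + rep(b, each = nrow(S))

sigmoid <- function(x) 1 / (1 + exp(-x))

fc_widths <- function(cfg) {
  if (cfg$fc_depth < 1L || cfg$fc_depth > 6L)
    stop("fc_depth must be between 1 and 6")
  hidden <- c(128L, 64L, 32L, 16L, 8L)[seq_len(cfg$fc_depth - 1L)]
  c(2L * cfg$d_match, hidden, 1L)
}

field_names <- c("title", "content", "tags", "profile", "cred", "reply")

field_key <- function(cfg, field) {
  if (isTRUE(cfg$shared_field_params)) "shared" else field
}

# flat named parameter list for the whole model
init_params <- function(vocab, cfg, seed) {
  if (isTRUE(cfg$bigru_concat))
    stop("concatenation of the directional GRU states is available in ",
         "bigru(); the training engine uses the averaged form, which ",
         "keeps the physician vector at d_conv + d_h")
  with_seed(seed, {
    p <- list()
    p$emb <- matrix(stats::runif(vocab$size * cfg$d_emb,
                                 -cfg$init_scale, cfg$init_scale),
                    vocab$size, cfg$d_emb)
    p$emb[vocab$pad_id + 1L, ] <- 0
    keys <- if (isTRUE(cfg$shared_field_params)) "shared" else field_names
    for (k in keys) {
      p[[paste0("f_", k, "_Wc")]] <- glorot(3L * cfg$d_emb, cfg$d_conv)
      p[[paste0("f_", k, "_bc")]] <- numeric(cfg$d_conv)
      p[[paste0("f_", k, "_v")]]  <- as.vector(glorot(cfg$d_conv, 1L))
      p[[paste0("f_", k, "_vb")]] <- 0
    }
    din <- cfg$d_h + cfg$d_conv
    for (d in c("gf", "gb")) for (g in c("Wz", "Wr", "W"))
      p[[paste0(d, "_", g)]] <- glorot(din, cfg$d_h)
    p$ha_v <- as.vector(glorot(cfg$d_h, 1L))
    p$ha_vb <- 0
    p$proj_p_W <- glorot(4L * cfg$d_conv, cfg$d_match)
    p$proj_p_b <- numeric(cfg$d_match)
    if (cfg$d_conv + cfg$d_h != cfg$d_match) {
      p$proj_r_W <- glorot(cfg$d_conv + cfg$d_h, cfg$d_match)
      p$proj_r_b <- numeric(cfg$d_match)
    }
    w <- fc_widths(cfg)
    for (i in seq_len(length(w) - 1L)) {
      p[[paste0("fc", i, "_W")]] <- glorot(w[i], w[i + 1L])
      p[[paste0("fc", i, "_b")]] <- numeric(w[i + 1L])
    }
    p
  })
}

new_grads <- function(params) {
  g <- lapply(params, function(x) if (is.matrix(x)) x * 0 else x * 0)
  list2env(g, hash = TRUE)
}

# ---- field encoder -------------------------------------------------------

# ids: B x L integer matrix (0 = pad). Returns pooled B x d_conv plus the
# cache needed for the backward pass.
#
# The window concat(W[l-1], W[l], W[l+1]) %*% Wc is computed as shifted
# partial products: with Wc split into its prev/cur/next row blocks,
# S = shift(E %*% Wc1) + E %*% Wc2 + shift(E %*% Wc3), which needs a
# single embedding gather instead of three.
enc_field_fwd <- function(ids, pf, emb, train = FALSE, drop_rate = 0) {
  B <- nrow(ids); L <- ncol(ids); N <- B * L
  flat <- as.vector(ids)
  de <- ncol(emb); dc <- ncol(pf$Wc)
  E <- emb[flat + 1L, , drop = FALSE]
  # one fused product against all three window blocks of Wc; the window
  # shifts become in-place block additions (rows p of the prev-block
  # product contribute at p + B, next-block at p - B; vacated rows see
  # the boundary zero padding)
  W3 <- cbind(pf$Wc[seq_len(de), , drop = FALSE],
              pf$Wc[de + seq_len(de), , drop = FALSE],
              pf$Wc[2L * de + seq_len(de), , drop = FALSE])
  P <- E %*% W3  # N x (3 dc), blocks [prev | cur | next]
  S <- add_rowvec(P[, dc + seq_len(dc), drop = FALSE], pf$bc)
  if (N > B) {
    lo <- seq_len(N - B); hi <- (B + 1L):N
    S[hi, ] <- S[hi, , drop = FALSE] + P[lo, seq_len(dc), drop = FALSE]
    S[lo, ] <- S[lo, , drop = FALSE] +
      P[hi, 2L * dc + seq_len(dc), drop = FALSE]
  }
  C <- S; C[C < 0] <- 0
  alpha <- tanh(as.vector(C %*% pf$v) + pf$vb)
  mask <- flat > 0L
  am <- alpha
  am[!mask] <- -Inf
  am <- matrix(am, B, L)
  mx <- am[cbind(seq_len(B), max.col(am, ties.method = "first"))]
  am <- exp(am - mx)
  a <- as.vector(am / rowSums(am))
  a[!mask] <- 0
  rep_b <- rep.int(seq_len(B), L)
  pooled <- unname(rowsum(C * a, rep_b))
  dropmask <- NULL
  if (train && drop_rate > 0) {
    dropmask <- matrix(stats::runif(B * ncol(pooled)) >= drop_rate,
                       B, ncol(pooled))
    pooled <- pooled * dropmask / (1 - drop_rate)
  }
  list(pooled = pooled,
       cache = list(ids = ids, flat = flat, E = E,
                    C = C, alpha = alpha, a = a, mask = mask,
                    B = B, L = L, rep_b = rep_b, dropmask = dropmask,
                    drop_rate = drop_rate))
}

# dpooled: B x d_conv. Accumulates parameter grads into `gr` (an
# environment) under the given key prefix and returns nothing; embedding
# grads are added densely into gr$emb.
enc_field_bwd <- function(dpooled, cache, pf, key, emb, gr) {
  B <- cache$B; rep_b <- cache$rep_b
  if (!is.null(cache$dropmask))
    dpooled <- dpooled * cache$dropmask / (1 - cache$drop_rate)
  DP <- dpooled[rep_b, , drop = FALSE]
  C <- cache$C
  dC <- DP * cache$a
  da <- rowSums(C * DP)
  sb <- as.vector(rowsum(cache$a * da, rep_b))
  dalpha <- cache$a * (da - sb[rep_b])
  dpre <- dalpha * (1 - cache$alpha^2)
  gr[[paste0("f_", key, "_v")]] <- gr[[paste0("f_", key, "_v")]] +
    as.vector(crossprod(C, dpre))
  gr[[paste0("f_", key, "_vb")]] <- gr[[paste0("f_", key, "_vb")]] +
    sum(dpre)
  dC <- dC + tcrossprod(dpre, pf$v)
  dS <- dC * (C > 0)
  de <- ncol(emb)
  N <- nrow(dS)
  E <- cache$E
  # window-block gradients; the shifts of dS are expressed as products
  # over row-offset views (dU1[q] = dS[q+B], dU3[q] = dS[q-B])
  Wc <- pf$Wc
  gkey <- paste0("f_", key, "_Wc")
  if (N > B) {
    lo <- seq_len(N - B); hi <- (B + 1L):N
    gr[[gkey]] <- gr[[gkey]] + rbind(
      crossprod(E[lo, , drop = FALSE], dS[hi, , drop = FALSE]),
      crossprod(E, dS),
      crossprod(E[hi, , drop = FALSE], dS[lo, , drop = FALSE]))
    T1 <- tcrossprod(dS, Wc[seq_len(de), , drop = FALSE])
    dE <- tcrossprod(dS, Wc[de + seq_len(de), , drop = FALSE])
    T3 <- tcrossprod(dS, Wc[2L * de + seq_len(de), , drop = FALSE])
    dE[lo, ] <- dE[lo, , drop = FALSE] + T1[hi, , drop = FALSE]
    dE[hi, ] <- dE[hi, , drop = FALSE] + T3[lo, , drop = FALSE]
  } else {
    gr[[gkey]] <- gr[[gkey]] + rbind(
      matrix(0, de, ncol(dS)), crossprod(E, dS), matrix(0, de, ncol(dS)))
    dE <- tcrossprod(dS, Wc[de + seq_len(de), , drop = FALSE])
  }
  gr[[paste0("f_", key, "_bc")]] <- gr[[paste0("f_", key, "_bc")]] +
    colSums(dS)
  acc_emb_grad(gr, cache$flat, dE)
  invisible(NULL)
}

acc_emb_grad <- function(gr, ids, rows) {
  keep <- ids > 0L
  if (!any(keep)) return(invisible(NULL))
  g <- rowsum(rows[keep, , drop = FALSE], ids[keep])
  uid <- as.integer(rownames(g))
  gr$emb[uid + 1L, ] <- gr$emb[uid + 1L, , drop = FALSE] + g
  invisible(NULL)
}

fpars <- function(params, key) {
  list(Wc = params[[paste0("f_", key, "_Wc")]],
       bc = params[[paste0("f_", key, "_bc")]],
       v = params[[paste0("f_", key, "_v")]],
       vb = params[[paste0("f_", key, "_vb")]])
}

# ---- GRU over ragged histories ------------------------------------------

# E: Rtot x d_in reply vectors grouped by owner (chronological within
# owner); offsets[b] + t is the row of owner b's step t; ks[b] its length.
# reverse = TRUE runs over each owner's sequence back-to-front, storing the
# state at the original position so forward/backward rows stay aligned.
gru_seq_fwd <- function(E, offsets, ks, gp, d_h, reverse = FALSE) {
  B <- length(ks); Tmax <- if (B) max(ks) else 0L
  H <- matrix(0, B, d_h)
  Hseq <- matrix(0, nrow(E), d_h)
  steps <- vector("list", Tmax)
  Wzr <- cbind(gp$Wz, gp$Wr)  # both sigmoid gates in one product
  for (t in seq_len(Tmax)) {
    active <- which(ks >= t)
    pos <- if (reverse) ks[active] - t + 1L else t
    rows <- offsets[active] + pos
    x <- E[rows, , drop = FALSE]
    h_prev <- H[active, , drop = FALSE]
    G <- sigmoid(cbind(h_prev, x) %*% Wzr)
    z <- G[, seq_len(d_h), drop = FALSE]
    r <- G[, d_h + seq_len(d_h), drop = FALSE]
    htil <- tanh(cbind(r * h_prev, x) %*% gp$W)
    h <- (1 - z) * h_prev + z * htil
    H[active, ] <- h
    Hseq[rows, ] <- h
    steps[[t]] <- list(active = active, rows = rows, h_prev = h_prev,
                       z = z, r = r, htil = htil)
  }
  list(Hseq = Hseq, steps = steps, Tmax = Tmax)
}

# dHseq: Rtot x d_h grads on the per-position states of this direction.
# Returns dE (Rtot x d_in) and accumulates gate-weight grads under prefix.
gru_seq_bwd <- function(dHseq, fwd, E, offsets, ks, gp, prefix, gr, d_in) {
  B <- length(ks); d_h <- ncol(dHseq)
  dE <- matrix(0, nrow(E), d_in)
  dh_acc <- matrix(0, B, d_h)
  Wzr <- cbind(gp$Wz, gp$Wr)
  gWz <- gr[[paste0(prefix, "_Wz")]]
  gWr <- gr[[paste0(prefix, "_Wr")]]
  gW <- gr[[paste0(prefix, "_W")]]
  for (t in rev(seq_len(fwd$Tmax))) {
    st <- fwd$steps[[t]]
    active <- st$active; rows <- st$rows
    dh <- dHseq[rows, , drop = FALSE] + dh_acc[active, , drop = FALSE]
    h_prev <- st$h_prev; z <- st$z; r <- st$r; htil <- st$htil
    x <- E[rows, , drop = FALSE]
    dz <- dh * (htil - h_prev)
    dhtil <- dh * z
    dh_prev <- dh * (1 - z)
    dpre_h <- dhtil * (1 - htil^2)
    gW <- gW + crossprod(cbind(r * h_prev, x), dpre_h)
    dcat <- tcrossprod(dpre_h, gp$W)
    drh <- dcat[, seq_len(d_h), drop = FALSE]
    dx <- dcat[, d_h + seq_len(d_in), drop = FALSE]
    dr <- drh * h_prev
    dh_prev <- dh_prev + drh * r
    # both sigmoid-gate backward products fused
    dpre_zr <- cbind(dz * z * (1 - z), dr * r * (1 - r))
    hx <- cbind(h_prev, x)
    gZR <- crossprod(hx, dpre_zr)
    gWz <- gWz + gZR[, seq_len(d_h), drop = FALSE]
    gWr <- gWr + gZR[, d_h + seq_len(d_h), drop = FALSE]
    dcat2 <- tcrossprod(dpre_zr, Wzr)
    dh_prev <- dh_prev + dcat2[, seq_len(d_h), drop = FALSE]
    dx <- dx + dcat2[, d_h + seq_len(d_in), drop = FALSE]
    dE[rows, ] <- dE[rows, , drop = FALSE] + dx
    dh_acc[active, ] <- dh_prev
  }
  gr[[paste0(prefix, "_Wz")]] <- gWz
  gr[[paste0(prefix, "_Wr")]] <- gWr
  gr[[paste0(prefix, "_W")]] <- gW
  dE
}

gpars <- function(params, dir)
  list(Wz = params[[paste0(dir, "_Wz")]],
       Wr = params[[paste0(dir, "_Wr")]],
       W = params[[paste0(dir, "_W")]])

# ---- step attention over averaged Bi-GRU states --------------------------

# Scaled tanh-score softmax attention over each owner's positions.
# Havg: Rtot x d_h; owner: Rtot integer owner ids in 1..B. Owners without
# rows get a zero pooled vector.
hist_attn_fwd <- function(Havg, owner, B, v, vb) {
  d_h <- ncol(Havg)
  if (nrow(Havg) == 0L)
    return(list(pooled = matrix(0, B, d_h), cache = NULL))
  alpha <- tanh(as.vector(Havg %*% v) / sqrt(d_h) + vb)
  ex <- exp(alpha - stats::ave(alpha, owner, FUN = max))
  rs <- rowsum(ex, owner)
  denom_full <- numeric(B)
  denom_full[as.integer(rownames(rs))] <- as.vector(rs)
  a <- ex / denom_full[owner]
  pooled <- matrix(0, B, d_h)
  pl <- rowsum(Havg * a, owner)
  pooled[as.integer(rownames(pl)), ] <- pl
  list(pooled = pooled,
       cache = list(alpha = alpha, a = a, owner = owner, B = B))
}

hist_attn_bwd <- function(dpooled, cache, Havg, v, gr) {
  if (is.null(cache)) return(matrix(0, 0L, length(v)))
  owner <- cache$owner; a <- cache$a; d_h <- ncol(Havg)
  DP <- dpooled[owner, , drop = FALSE]
  dH <- DP * a
  da <- rowSums(Havg * DP)
  sb <- rowsum(a * da, owner)
  sfull <- numeric(cache$B); sfull[as.integer(rownames(sb))] <- sb
  dalpha <- a * (da - sfull[owner])
  dpre <- dalpha * (1 - cache$alpha^2)
  gr$ha_v <- gr$ha_v + as.vector(crossprod(Havg, dpre)) / sqrt(d_h)
  gr$ha_vb <- gr$ha_vb + sum(dpre)
  dH + tcrossprod(dpre, v / sqrt(d_h))
}

# ---- scoring head --------------------------------------------------------

fc_fwd <- function(Z, params, cfg, train = FALSE) {
  nlayer <- cfg$fc_depth
  acts <- vector("list", nlayer + 1L)
  drops <- vector("list", nlayer)
  acts[[1L]] <- Z
  for (i in seq_len(nlayer)) {
    A <- add_rowvec(acts[[i]] %*% params[[paste0("fc", i, "_W")]],
                    params[[paste0("fc", i, "_b")]])
    if (i < nlayer) {
      A[A < 0] <- 0
      if (train && cfg$dropout > 0) {
        dm <- matrix(stats::runif(length(A)) >= cfg$dropout,
                     nrow(A), ncol(A))
        A <- A * dm / (1 - cfg$dropout)
        drops[[i]] <- dm
      }
    }
    acts[[i + 1L]] <- A
  }
  list(logit = as.vector(acts[[nlayer + 1L]]), acts = acts, drops = drops)
}

fc_bwd <- function(dlogit, cache, params, cfg, gr) {
  nlayer <- cfg$fc_depth
  dA <- matrix(dlogit, ncol = 1L)
  for (i in rev(seq_len(nlayer))) {
    if (i < nlayer) {
      if (!is.null(cache$drops[[i]]))
        dA <- dA * cache$drops[[i]] / (1 - cfg$dropout)
      dA <- dA * (cache$acts[[i + 1L]] > 0)
    }
    gr[[paste0("fc", i, "_W")]] <- gr[[paste0("fc", i, "_W")]] +
      crossprod(cache$acts[[i]], dA)
    gr[[paste0("fc", i, "_b")]] <- gr[[paste0("fc", i, "_b")]] + colSums(dA)
    dA <- tcrossprod(dA, params[[paste0("fc", i, "_W")]])
  }
  dA  # gradient on the fused input Z
}

# ---- batch preparation and full forward/backward -------------------------

# Assemble the id matrices and ragged history structure for a set of
# interactions, once; batches are then row subsets (subset_batch).
# `variant` controls ablation (patient fields / physician sources).
prepare_dataset <- function(corpus, inter, vocab, cfg, variant = NULL) {
  pf <- variant$patient_fields %||% c("title", "content", "tags", "profile")
  ps <- variant$physician_sources %||% c("credentials", "history")
  B <- nrow(inter)
  qs <- corpus$queries[inter$query_id]
  phys <- corpus$physicians[inter$physician_id]
  ftoks <- lapply(qs, query_field_tokens, fields = pf)
  lens <- c(title = cfg$max_title_len, content = cfg$max_content_len,
            tags = cfg$max_tag_len, profile = cfg$max_profile_len)
  qmats <- lapply(names(lens), function(f)
    id_matrix(lapply(ftoks, `[[`, f), vocab, lens[[f]]))
  names(qmats) <- names(lens)
  cred_tok <- if ("credentials" %in% ps)
    lapply(phys, credential_tokens) else rep(list("<null>"), B)
  cred <- id_matrix(cred_tok, vocab, cfg$max_cred_len)
  # ragged recent histories, window anchored at each interaction's day
  use_hist <- "history" %in% ps
  reps <- vector("list", B)
  if (use_hist) {
    for (b in seq_len(B)) {
      reps[[b]] <- select_recent(phys[[b]]$reply_history,
                                 now = inter$timestamp[b],
                                 window_days = cfg$window_days,
                                 max_history = cfg$max_history)
    }
  }
  ks <- vapply(reps, length, integer(1L))
  offsets <- c(0L, cumsum(ks))[seq_len(B)]
  all_replies <- unlist(reps, recursive = FALSE)
  rmat <- if (length(all_replies))
    id_matrix(lapply(all_replies, `[[`, "tokens"), vocab, cfg$max_reply_len)
  else matrix(vocab$pad_id, 0L, cfg$max_reply_len)
  list(n = B, qmats = qmats, cred = cred, rmat = rmat,
       ks = ks, offsets = offsets, labels = inter$label,
       use_hist = use_hist)
}

# extract the batch structure for rows `idx` of a prepared dataset
subset_batch <- function(ds, idx) {
  B <- length(idx)
  ks <- ds$ks[idx]
  src <- sequence(ks) + rep.int(ds$offsets[idx], ks)
  list(B = B,
       qmats = lapply(ds$qmats, function(m) m[idx, , drop = FALSE]),
       cred = ds$cred[idx, , drop = FALSE],
       rmat = ds$rmat[src, , drop = FALSE],
       ks = ks, offsets = c(0L, cumsum(ks))[seq_len(B)],
       owner = rep.int(seq_len(B), ks),
       labels = ds$labels[idx], use_hist = ds$use_hist)
}

prepare_batch <- function(corpus, inter, vocab, cfg, variant = NULL) {
  ds <- prepare_dataset(corpus, inter, vocab, cfg, variant)
  subset_batch(ds, seq_len(ds$n))
}

# Full forward pass over a prepared batch. Returns scores and (if
# keep_cache) everything the backward pass needs.
model_fwd <- function(params, batch, cfg, train = FALSE,
                      keep_cache = FALSE, rd_override = NULL) {
  B <- batch$B
  dr <- if (train) cfg$dropout else 0
  fcache <- list()
  pooled <- list()
  for (f in c("title", "content", "tags", "profile")) {
    r <- enc_field_fwd(batch$qmats[[f]], fpars(params, field_key(cfg, f)),
                       params$emb, train, dr)
    pooled[[f]] <- r$pooled
    if (keep_cache) fcache[[f]] <- r$cache
  }
  e_cat <- cbind(pooled$title, pooled$content, pooled$tags, pooled$profile)
  e <- add_rowvec(e_cat %*% params$proj_p_W, params$proj_p_b)

  rcred <- enc_field_fwd(batch$cred, fpars(params, field_key(cfg, "cred")),
                         params$emb, train, dr)
  r_s <- rcred$pooled
  if (nrow(batch$rmat) > 0L) {
    rrep <- enc_field_fwd(batch$rmat, fpars(params, field_key(cfg, "reply")),
                          params$emb, train, dr)
    E <- rrep$pooled
    gf <- gru_seq_fwd(E, batch$offsets, batch$ks, gpars(params, "gf"),
                      cfg$d_h, reverse = FALSE)
    gb <- gru_seq_fwd(E, batch$offsets, batch$ks, gpars(params, "gb"),
                      cfg$d_h, reverse = TRUE)
    Havg <- (gf$Hseq + gb$Hseq) / 2
    ha <- hist_attn_fwd(Havg, batch$owner, B, params$ha_v, params$ha_vb)
    r_d <- ha$pooled
  } else {
    rrep <- NULL; gf <- gb <- NULL; Havg <- NULL
    ha <- list(pooled = matrix(0, B, cfg$d_h), cache = NULL)
    E <- matrix(0, 0L, cfg$d_conv)
    r_d <- ha$pooled
  }
  override_rows <- integer()
  if (!is.null(rd_override)) {
    override_rows <- which(!is.na(rd_override[, 1L]))
    r_d[override_rows, ] <- rd_override[override_rows, , drop = FALSE]
  }
  rd_drop <- NULL
  if (train && dr > 0) {
    rd_drop <- matrix(stats::runif(B * cfg$d_h) >= dr, B, cfg$d_h)
    r_d <- r_d * rd_drop / (1 - dr)
  }
  r_cat <- cbind(r_s, r_d)
  r <- if (is.null(params$proj_r_W)) r_cat
    else add_rowvec(r_cat %*% params$proj_r_W, params$proj_r_b)

  Z <- cbind(e, r)
  fc <- fc_fwd(Z, params, cfg, train)
  logit <- fc$logit
  if (isTRUE(cfg$inner_product_term)) logit <- logit + rowSums(e * r)
  score <- sigmoid(logit)
  out <- list(score = score, logit = logit, e = e, r = r)
  if (keep_cache) {
    out$cache <- list(fcache = fcache, rcred = rcred$cache,
                      rrep = if (!is.null(rrep)) rrep$cache else NULL,
                      E = E, gf = gf, gb = gb, Havg = Havg, ha = ha$cache,
                      e_cat = e_cat, r_cat = r_cat, r_s = r_s, r_d = r_d,
                      rd_drop = rd_drop, fc = fc, Z = Z, e = e, r = r,
                      override_rows = override_rows)
  }
  out
}

# Backward pass from BCE loss; returns the gradient environment.
model_bwd <- function(params, batch, cfg, fwd) {
  B <- batch$B
  ca <- fwd$cache
  gr <- new_grads(params)
  dlogit <- (fwd$score - batch$labels) / B
  dZ <- fc_bwd(dlogit, ca$fc, params, cfg, gr)
  de <- dZ[, seq_len(cfg$d_match), drop = FALSE]
  dr <- dZ[, cfg$d_match + seq_len(cfg$d_match), drop = FALSE]
  if (isTRUE(cfg$inner_product_term)) {
    de <- de + dlogit * ca$r
    dr <- dr + dlogit * ca$e
  }
  # physician projection
  if (is.null(params$proj_r_W)) {
    dr_cat <- dr
  } else {
    gr$proj_r_W <- gr$proj_r_W + crossprod(ca$r_cat, dr)
    gr$proj_r_b <- gr$proj_r_b + colSums(dr)
    dr_cat <- tcrossprod(dr, params$proj_r_W)
  }
  dr_s <- dr_cat[, seq_len(cfg$d_conv), drop = FALSE]
  dr_d <- dr_cat[, cfg$d_conv + seq_len(cfg$d_h), drop = FALSE]
  if (!is.null(ca$rd_drop))
    dr_d <- dr_d * ca$rd_drop / (1 - cfg$dropout)
  if (length(ca$override_rows)) dr_d[ca$override_rows, ] <- 0
  # history channel
  if (!is.null(ca$ha)) {
    dHavg <- hist_attn_bwd(dr_d, ca$ha, ca$Havg, params$ha_v, gr)
    dE_f <- gru_seq_bwd(dHavg / 2, ca$gf, ca$E, batch$offsets, batch$ks,
                        gpars(params, "gf"), "gf", gr, cfg$d_conv)
    dE_b <- gru_seq_bwd(dHavg / 2, ca$gb, ca$E, batch$offsets, batch$ks,
                        gpars(params, "gb"), "gb", gr, cfg$d_conv)
    enc_field_bwd(dE_f + dE_b, ca$rrep,
                  fpars(params, field_key(cfg, "reply")),
                  field_key(cfg, "reply"), params$emb, gr)
  }
  enc_field_bwd(dr_s, ca$rcred, fpars(params, field_key(cfg, "cred")),
                field_key(cfg, "cred"), params$emb, gr)
  # patient projection and fields
  gr$proj_p_W <- gr$proj_p_W + crossprod(ca$e_cat, de)
  gr$proj_p_b <- gr$proj_p_b + colSums(de)
  de_cat <- tcrossprod(de, params$proj_p_W)
  dc <- cfg$d_conv
  for (i in seq_along(c("title", "content", "tags", "profile"))) {
    f <- c("title", "content", "tags", "profile")[i]
    enc_field_bwd(de_cat[, (i - 1L) * dc + seq_len(dc), drop = FALSE],
                  ca$fcache[[f]], fpars(params, field_key(cfg, f)),
                  field_key(cfg, f), params$emb, gr)
  }
  gr$emb[1L, ] <- 0  # pad row excluded from updates
  gr
}

# L2 penalty gradient on weight matrices (biases, scalars and the
# embedding table are exempt)
add_l2 <- function(gr, params, lambda) {
  if (lambda <= 0) return(invisible(NULL))
  for (nm in names(params)) {
    if (nm == "emb" || grepl("_(b|bc|vb)$", nm) || grepl("_b$", nm)) next
    gr[[nm]] <- gr[[nm]] + 2 * lambda * params[[nm]]
  }
  invisible(NULL)
}

adam_state <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)

adam_step <- function(params, gr, st, cfg) {
  st$t <- st$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  corr1 <- 1 - b1^st$t; corr2 <- 1 - b2^st$t
  lr <- cfg$learning_rate
  for (nm in names(params)) {
    g <- gr[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / corr1) / (sqrt(st$v[[nm]] / corr2) + cfg$adam_eps)
  }
  params$emb[1L, ] <- 0
  list(params = params, state = st)
}

bce_loss <- function(score, labels) {
  eps <- 1e-12
  -mean(labels * log(score + eps) + (1 - labels) * log(1 - score + eps))
}
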