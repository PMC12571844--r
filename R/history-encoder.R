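#' @title Physician temporal channel
#' @description The reply-history encoder: selection of the recent 15-day
#'   reply window, per-reply field encoding, a bidirectional GRU whose
#'   aligned forward and backward states are averaged per step, scaled
#'   tanh-score attention over the steps, and fusion with the credential
#'   vector into the physician representation `r = [r_s, r_d]`.
#' @name history_encoder
NULL

#' Select the recent reply window
#'
#' Keeps replies with day index in the left-open, right-closed interval
#' `(now - window_days, now]`, in chronological order, truncated to the
#' most recent `max_history`. An empty result is allowed and routes the
#' physician to the cold-start path.
#'
#' @param history list of `list(day, tokens)` sorted ascending by day.
#' @param now the interaction's day index.
#' @param window_days window width in days (default 15).
#' @param max_history cap on the number of replies kept (default 32).
#' @return The selected sublist, possibly empty.
#' @export
select_recent <- function(history, now, window_days = 15L,
                          max_history = 32L) {
  if (length(history) == 0L) return(list())
  days <- vapply(history, `[[`, integer(1L), "day")
  keep <- which(days > now - window_days & days <= now)
  if (length(keep) > max_history)
    keep <- keep[(length(keep) - max_history + 1L):length(keep)]
  history[keep]
}

#' Encode a reply sequence
#'
#' Each reply's token sequence goes through the field-encoding pipeline
#' with the reply channel's parameters; row `i` of the result is the
#' vector of reply `i` in the order given.
#'
#' @param replies non-empty list of `list(day, tokens)`.
#' @param model an `ohc_model`.
#' @return A `k` x `d_conv` matrix `E`.
#' @export
encode_replies <- function(replies, model) {
  if (length(replies) == 0L) stop("cannot encode an empty reply sequence")
  cfg <- model$config; vocab <- model$vocab
  pf <- fpars(model$params, field_key(cfg, "reply"))
  t(vapply(replies, function(r) {
    ids <- pad_ids(vocab_ids(vocab, r$tokens), cfg$max_reply_len,
                   vocab$pad_id, vocab$unk_id)
    encode_field(ids, model$params$emb, pf)$pooled
  }, numeric(cfg$d_conv)))
}

#' Create GRU parameters
#'
#' Gate matrices act on the concatenation `[h_{t-1}, x_t]`; following the
#' update equations there are no bias terms.
#'
#' @param d_in input width.
#' @param d_h hidden width.
#' @param seed RNG seed.
#' @return A list of class `gru_params` with `Wz`, `Wr`, `W`
#'   (each `(d_h + d_in)` x `d_h`) and `d_h`.
#' @export
gru_params <- function(d_in = 64L, d_h = 64L, seed = 1L) {
  ps <- with_seed(seed, list(Wz = glorot(d_h + d_in, d_h),
                             Wr = glorot(d_h + d_in, d_h),
                             W = glorot(d_h + d_in, d_h),
                             d_h = d_h))
  structure(ps, class = "gru_params")
}

#' One GRU update step
#'
#' `z_t = sigmoid(Wz . [h, x])`, `r_t = sigmoid(Wr . [h, x])`,
#' `htilde = tanh(W . [r_t * h, x])`,
#' `h_t = (1 - z_t) * h + z_t * htilde` (elementwise products). With
#' `h_0 = 0` every later state is a convex combination of tanh outputs,
#' hence bounded in (-1, 1).
#'
#' @param h_prev previous hidden state (length `d_h`).
#' @param x input vector.
#' @param params a [gru_params()].
#' @return The next hidden state, length `d_h`.
#' @export
gru_step <- function(h_prev, x, params) {
  d_h <- params$d_h
  if (length(h_prev) != d_h) stop("h_prev has wrong width")
  if (length(h_prev) + length(x) != nrow(params$Wz))
    stop("input width does not match the gate matrices")
  cat_hx <- c(h_prev, x)
  z <- sigmoid(as.vector(cat_hx %*% params$Wz))
  r <- sigmoid(as.vector(cat_hx %*% params$Wr))
  htil <- tanh(as.vector(c(r * h_prev, x) %*% params$W))
  (1 - z) * h_prev + z * htil
}

#' Bidirectional GRU over a reply-vector sequence
#'
#' Runs a forward pass over `E` and a backward pass over the reversed
#' sequence (both from zero initial states) and returns, per step, the
#' arithmetic mean of the aligned directional states
#' `h_t = (Df(t) + Db(t)) / 2`. With `concat = TRUE` the two states are
#' concatenated instead.
#'
#' @param E `k` x `d_in` matrix of reply vectors (k >= 1).
#' @param params_fwd,params_bwd directional [gru_params()].
#' @param concat concatenate instead of averaging the directions.
#' @return A `k` x `d_h` (or `k` x `2 d_h`) matrix of per-step states.
#' @export
bigru <- function(E, params_fwd, params_bwd, concat = FALSE) {
  if (!is.matrix(E) || nrow(E) < 1L) stop("E must have at least one row")
  k <- nrow(E); d_h <- params_fwd$d_h
  Hf <- matrix(0, k, d_h); Hb <- matrix(0, k, d_h)
  h <- numeric(d_h)
  for (t in seq_len(k)) Hf[t, ] <- h <- gru_step(h, E[t, ], params_fwd)
  h <- numeric(d_h)
  for (t in rev(seq_len(k))) Hb[t, ] <- h <- gru_step(h, E[t, ], params_bwd)
  if (concat) cbind(Hf, Hb) else (Hf + Hb) / 2
}

#' Attention over history steps
#'
#' The same tanh-score softmax form as the field encoder, with the score
#' scaled by `1 / sqrt(d_h)` to keep it width-invariant:
#' `alpha_i = tanh((v . h_i) / sqrt(d_h) + vb)`. Returns the pooled
#' temporal vector `r_d = sum_i a_i h_i`.
#'
#' @param H `k` x `d_h` matrix of averaged states (k >= 1).
#' @param v attention weight vector (length `d_h`).
#' @param vb attention bias scalar.
#' @return A list with `weights` and `r_d`.
#' @export
attend_history <- function(H, v, vb = 0) {
  if (!is.matrix(H) || nrow(H) < 1L)
    stop("empty history: cold physicians must go through augmentation")
  alpha <- tanh(as.vector(H %*% v) / sqrt(ncol(H)) + vb)
  ex <- exp(alpha - max(alpha))
  a <- ex / sum(ex)
  list(weights = a, r_d = as.vector(crossprod(H, a)))
}

#' Encode a physician
#'
#' Combines the credential vector `r_s` with the temporal vector `r_d`
#' from the recent reply window into `r = [r_s, r_d]` (projected to
#' `d_match` when the widths differ; identity otherwise). When the recent
#' window is empty the physician is cold: with an `augmenter` the
#' surrogate vector from the credential knowledge base replaces `r_d`,
#' otherwise an explicit cold-start error is raised.
#'
#' @param physician a `physician_profile`.
#' @param now the interaction's day index.
#' @param model an `ohc_model`.
#' @param augmenter optional [build_cold_augmenter()] result.
#' @return A list with `r` (length `d_match`), `r_s`, `r_d` and `k`, the
#'   number of replies in the window.
#' @export
encode_physician <- function(physician, now, model, augmenter = NULL) {
  cfg <- model$config
  r_s <- encode_credentials(physician, model)$r_s
  recent <- select_recent(physician$reply_history, now,
                          cfg$window_days, cfg$max_history)
  if (length(recent) == 0L) {
    if (is.null(augmenter))
      stop("cold-start: physician ", physician$physician_id,
           " has no recent replies and no augmentation is configured")
    r_d <- augment_cold_physician(physician, augmenter,
                                  check_threshold = FALSE)
  } else {
    E <- encode_replies(recent, model)
    H <- bigru(E, gpars_as_gru(model$params, "gf", cfg),
               gpars_as_gru(model$params, "gb", cfg),
               concat = isTRUE(cfg$bigru_concat))
    r_d <- attend_history(H, model$params$ha_v, model$params$ha_vb)$r_d
  }
  r_cat <- c(r_s, r_d)
  r <- if (is.null(model$params$proj_r_W)) r_cat
    else as.vector(crossprod(model$params$proj_r_W, r_cat)) +
      model$params$proj_r_b
  list(r = r, r_s = r_s, r_d = r_d, k = length(recent))
}

gpars_as_gru <- function(params, dir, cfg) {
  structure(c(gpars(params, dir), list(d_h = cfg$d_h)),
            class = "gru_params")
}
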