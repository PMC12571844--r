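#' @title Patient-channel text encoder
#' @description The field-level encoding pipeline shared by every textual
#'   input: embedding lookup, width-3 windowed convolution with ReLU
#'   (half-window `M = 1`, zero vectors past the boundaries, "same"
#'   padding), and tanh-scored softmax attention pooling. The four patient
#'   fields (title, content, profile, tags) are encoded this way and fused
#'   into a 128-dimensional patient representation; physician credentials
#'   go through the identical pipeline to give the static expertise vector
#'   `r_s`.
#' @name text_encoder
NULL

#' Create an embedding table
#'
#' Rows are indexed by token id + 1; the padding row (id 0) is all zeros
#' and stays zero through training.
#'
#' @param n_tokens vocabulary size (including reserved ids).
#' @param d_emb embedding width.
#' @param seed RNG seed for the uniform initialization.
#' @param scale half-width of the uniform initial range.
#' @return An `n_tokens` x `d_emb` numeric matrix.
#' @export
embedding_table <- function(n_tokens, d_emb = 64L, seed = 1L, scale = 0.1) {
  tab <- with_seed(seed,
    matrix(stats::runif(n_tokens * d_emb, -scale, scale), n_tokens, d_emb))
  tab[1L, ] <- 0
  tab
}

#' Create convolution + attention parameters for one field
#'
#' @param d_emb embedding width the window consumes.
#' @param d_conv number of convolution features.
#' @param seed RNG seed (Glorot-uniform initialization).
#' @param M half-window; the token window has width `2M + 1` (fixed 1).
#' @return A list of class `conv_attn_params` with `Wc`
#'   (`3 d_emb` x `d_conv`), `bc`, attention vector `v`, bias `vb`, and `M`.
#' @export
conv_attn_params <- function(d_emb = 64L, d_conv = 64L, seed = 1L, M = 1L) {
  if (M != 1L) stop("the window half-width is fixed at M = 1")
  ps <- with_seed(seed, list(
    Wc = glorot(3L * d_emb, d_conv),
    bc = numeric(d_conv),
    v = as.vector(glorot(d_conv, 1L)),
    vb = 0, M = 1L))
  structure(ps, class = "conv_attn_params")
}

#' Embedding lookup
#'
#' Maps a token-id sequence to its embedding rows; the pad id yields an
#' all-zero row.
#'
#' @param ids integer id vector (0-based; 0 = pad).
#' @param table embedding matrix from [embedding_table()].
#' @return A `length(ids)` x `d_emb` matrix.
#' @export
embed_tokens <- function(ids, table) {
  ids <- as.integer(ids)
  if (any(ids < 0L) || any(ids >= nrow(table)))
    stop("token id out of range of the embedding table")
  table[ids + 1L, , drop = FALSE]
}

#' Windowed convolution with ReLU
#'
#' Each output position is
#' `c_i = relu(Wc . concat(W[i-1], W[i], W[i+1]) + bc)` with zero vectors
#' past the sequence boundaries ("same" padding), so the output length
#' equals the input length.
#'
#' @param W `n` x `d_emb` matrix of embedded tokens.
#' @param params a [conv_attn_params()].
#' @return An `n` x `d_conv` feature matrix.
#' @export
conv_window <- function(W, params) {
  if (!is.matrix(W) || nrow(W) < 1L) stop("need at least one position")
  if (3L * ncol(W) != nrow(params$Wc))
    stop("embedding width does not match the convolution weights")
  n <- nrow(W); z <- matrix(0, 1L, ncol(W))
  prev <- rbind(z, W[-n, , drop = FALSE])
  nxt <- rbind(W[-1L, , drop = FALSE], z)
  S <- add_rowvec(cbind(prev, W, nxt) %*% params$Wc, params$bc)
  S[S < 0] <- 0
  S
}

#' Attention pooling over a feature sequence
#'
#' Scores `alpha_i = tanh(v . c_i + vb)`, normalizes them by softmax over
#' the unmasked positions and returns the weighted sum
#' `pooled = sum_i a_i c_i`. The weights are non-negative and sum to one,
#' so the pooled vector lies in the convex hull of the features.
#'
#' @param C `n` x `d_conv` feature matrix.
#' @param params a [conv_attn_params()] (only `v`, `vb` are used).
#' @param mask optional logical vector; `FALSE` positions are excluded from
#'   the softmax. At least one position must remain.
#' @return A list with `weights` (length `n`, zeros at masked positions)
#'   and `pooled` (length `d_conv`).
#' @export
attention_pool <- function(C, params, mask = NULL) {
  n <- nrow(C)
  if (n < 1L) stop("cannot pool an empty sequence")
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (!any(mask)) stop("all positions are masked")
  alpha <- tanh(as.vector(C %*% params$v) + params$vb)
  a <- numeric(n)
  ex <- exp(alpha[mask] - max(alpha[mask]))
  a[mask] <- ex / sum(ex)
  list(weights = a, pooled = as.vector(crossprod(C, a)))
}

#' Encode one token field
#'
#' Composition embedding -> windowed convolution -> attention pooling.
#' Padding positions (id 0) are masked out of the softmax; their zero
#' embeddings still serve as the boundary context of the convolution.
#'
#' @param ids integer token-id sequence (at least one non-pad id).
#' @param table embedding matrix.
#' @param params a [conv_attn_params()].
#' @return A list of class `field_encoding` with `features` (the
#'   convolution output), `weights` and `pooled`.
#' @export
encode_field <- function(ids, table, params) {
  ids <- as.integer(ids)
  if (length(ids) == 0L) stop("cannot encode an empty field")
  C <- conv_window(embed_tokens(ids, table), params)
  ap <- attention_pool(C, params, mask = ids > 0L)
  structure(list(features = C, weights = ap$weights, pooled = ap$pooled),
            class = "field_encoding")
}

#' Encode a patient query
#'
#' Encodes the four patient fields (title, content, semantic tags,
#' profile; the structured fields via their `field=value` serialization)
#' with the model's per-field parameters and projects the concatenation
#' `[e_w, e_t, e_z, e_r]` to the matching width.
#'
#' @param query a `patient_query`.
#' @param model a trained or initialized `ohc_model`.
#' @return A list with `fields` (named `field_encoding`s) and `e`, the
#'   `d_match`-dimensional patient representation.
#' @export
encode_patient <- function(query, model) {
  cfg <- model$config; vocab <- model$vocab; params <- model$params
  toks <- query_field_tokens(query)
  lens <- c(title = cfg$max_title_len, content = cfg$max_content_len,
            tags = cfg$max_tag_len, profile = cfg$max_profile_len)
  fields <- list()
  pooled <- list()
  for (f in names(lens)) {
    ids <- pad_ids(vocab_ids(vocab, toks[[f]]), lens[[f]],
                   vocab$pad_id, vocab$unk_id)
    fe <- encode_field(ids, params$emb,
                       fpars(params, field_key(cfg, f)))
    fields[[f]] <- fe
    pooled[[f]] <- fe$pooled
  }
  e_cat <- c(pooled$title, pooled$content, pooled$tags, pooled$profile)
  e <- as.vector(crossprod(params$proj_p_W, e_cat)) + params$proj_p_b
  list(fields = fields, e = e)
}

#' Encode physician credentials
#'
#' The static expertise vector `r_s`: the credential fields are serialized
#' to `field=value` tokens and passed through the field-encoding pipeline
#' with the credential channel's parameters.
#'
#' @param physician a `physician_profile`.
#' @param model an `ohc_model`.
#' @return A list with the `field_encoding` and `r_s` (length `d_conv`).
#' @export
encode_credentials <- function(physician, model) {
  cfg <- model$config; vocab <- model$vocab
  ids <- pad_ids(vocab_ids(vocab, credential_tokens(physician)),
                 cfg$max_cred_len, vocab$pad_id, vocab$unk_id)
  fe <- encode_field(ids, model$params$emb,
                     fpars(model$params, field_key(cfg, "cred")))
  list(encoding = fe, r_s = fe$pooled)
}
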