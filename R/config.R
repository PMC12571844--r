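#' Default model and pipeline configuration
#'
#' Returns the full set of tunable knobs used across corpus handling, the
#' encoders, training and evaluation. Values can be overridden by name; a
#' YAML file with the same keys can be loaded with [load_config()].
#'
#' The scoring head combines the fully connected stack over the
#' concatenated pair vector with the bilinear inner product `e . r` of the
#' two representations (`inner_product_term = TRUE`); the bilinear term is
#' what lets the match interaction be learned within the short training
#' budget, while the stack captures side-specific effects.
#'
#' Key defaults: embedding width `d_emb = 64`, convolution features
#' `d_conv = 64`, GRU hidden width `d_h = 64`, matching width
#' `d_match = 128` (so the fused pair vector is 256-wide), half-window
#' `M = 1` (token window of width 3), recent-history window of 15 days
#' truncated to the latest 32 replies, cold threshold of 5 replies, and the
#' training recipe: batch size 256, learning rate 0.01, at most 4 epochs
#' with early stopping on validation AUC (patience 1), dropout 0.5 on
#' pooled field vectors and hidden scoring layers, binary cross-entropy
#' loss under Adam.
#'
#' `l2_lambda` is the effective L2 coefficient applied to weight matrices
#' (not biases or embeddings). The default is 3e-4; the nominal coefficient
#' of 3 can be requested literally via `l2_literal = TRUE`, but at learning
#' rate 0.01 it collapses all weights toward zero within an epoch.
#'
#' @param ... named overrides of any default.
#' @return A named list of class `ohc_config`.
#' @export
ohc_config <- function(...) {
  cfg <- list(
    # encoder geometry
    d_emb = 64L, d_conv = 64L, d_h = 64L, d_match = 128L, M = 1L,
    shared_field_params = FALSE,
    inner_product_term = TRUE,
    # length policy (tokens)
    max_title_len = 16L, max_content_len = 128L,
    max_tag_len = 8L, max_profile_len = 16L, max_reply_len = 40L,
    max_cred_len = 8L,
    # history channel
    window_days = 15L, max_history = 32L, bigru_concat = FALSE,
    # cold start
    cold_threshold = 5L, sparse_threshold = 8L,
    # vocabulary
    min_count = 1L,
    # outlier filter on reply token counts (analogue of the character filter)
    reply_min_tokens = 1L, reply_max_tokens = 2000L,
    # training
    batch_size = 256L, learning_rate = 0.01, epochs = 4L, dropout = 0.5,
    l2_lambda = 3e-4, l2_literal = FALSE, patience = 1L,
    adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8,
    init_scale = 0.1,
    # scoring head: 256 -> 128 -> 64 -> 32 -> 1
    fc_depth = 4L,
    # evaluation
    k = 10L, n_negatives = 49L, threshold = 0.5,
    # dataset handling
    split_ratios = c(0.6, 0.2, 0.2)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = "ohc_config")
}

#' Load a configuration from a YAML file
#'
#' Unknown keys are rejected so typos in config files fail loudly.
#'
#' @param path path to a flat YAML file whose keys match [ohc_config()].
#' @return An `ohc_config` list with the file's overrides applied.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) ov <- list()
  do.call(ohc_config, ov)
}

#' @export
print.ohc_config <- function(x, ...) {
  cat("<ohc_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

# effective L2 coefficient under the chosen convention
l2_coef <- function(cfg) if (isTRUE(cfg$l2_literal)) 3 else cfg$l2_lambda
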