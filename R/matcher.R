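#' @title Pair scoring, cold-start augmentation and training
#' @description The matching layer: the patient and physician
#'   representations are concatenated into a 256-dimensional joint vector
#'   and passed through a fully connected stack (depth 4 by default:
#'   256 -> 128 -> 64 -> 32 -> 1) whose logistic output is the adoption
#'   probability. Training minimizes binary cross-entropy with Adam at the
#'   standard recipe (batch 256, learning rate 0.01, at most 4 epochs with
#'   early stopping on validation AUC, dropout 0.5).
#' @name matcher
NULL

#' Initialize an untrained model
#'
#' @param vocab an `ohc_vocab`.
#' @param config an [ohc_config()].
#' @param seed RNG seed for parameter initialization.
#' @param variant optional ablation specification: a list with
#'   `patient_fields` (subset of title/content/tags/profile) and
#'   `physician_sources` (subset of credentials/history).
#' @return A list of class `ohc_model`.
#' @export
init_model <- function(vocab, config = ohc_config(), seed = 1L,
                       variant = NULL) {
  check_variant(variant)
  structure(list(params = init_params(vocab, config, seed),
                 vocab = vocab, config = config, variant = variant,
                 log = NULL, best_epoch = NA_integer_,
                 seed = as.integer(seed)),
            class = "ohc_model")
}

check_variant <- function(variant) {
  if (is.null(variant)) return(invisible(NULL))
  pf <- variant$patient_fields %||% character()
  ps <- variant$physician_sources %||% character()
  ok_pf <- c("title", "content", "tags", "profile")
  ok_ps <- c("credentials", "history")
  if (length(setdiff(pf, ok_pf)) || length(setdiff(ps, ok_ps)))
    stop("unknown field names in variant")
  if (length(pf) == 0L && length(ps) == 0L)
    stop("variant enables no input fields")
  invisible(NULL)
}

#' @export
print.ohc_model <- function(x, ...) {
  cat(sprintf("<ohc_model> vocab %d, d_match %d, fc depth %d\n",
              x$vocab$size, x$config$d_match, x$config$fc_depth))
  if (!is.null(x$log)) {
    cat(sprintf("  trained %d epoch(s); best epoch %d (val AUC %.4f)\n",
                nrow(x$log), x$best_epoch,
                x$log$val_auc[x$best_epoch]))
  }
  invisible(x)
}

#' Score one patient-physician pair
#'
#' Concatenates the two `d_match` representations and applies the fully
#' connected stack and logistic output:
#' `score = sigmoid(Psi_FC([e, r]))`, strictly inside (0, 1).
#'
#' @param patient patient representation (length `d_match`).
#' @param physician physician representation (length `d_match`).
#' @param model an `ohc_model` (its scoring-head weights are used).
#' @return The adoption probability.
#' @export
score_pair <- function(patient, physician, model) {
  cfg <- model$config
  if (length(patient) != cfg$d_match || length(physician) != cfg$d_match)
    stop("representation width must equal d_match = ", cfg$d_match)
  Z <- matrix(c(patient, physician), nrow = 1L)
  logit <- fc_fwd(Z, model$params, cfg, train = FALSE)$logit
  if (isTRUE(cfg$inner_product_term))
    logit <- logit + sum(patient * physician)
  as.vector(sigmoid(logit))
}

#' Rank candidate physicians for a query
#'
#' Scores every candidate against the query and returns them in
#' descending score order, ties broken by physician id ascending.
#'
#' @param query a `patient_query`.
#' @param candidates list of `physician_profile` records (>= 1).
#' @param model an `ohc_model`.
#' @param augmenter optional cold-start augmenter.
#' @return A data.frame with `rank`, `physician_id`, `score`.
#' @export
rank_candidates <- function(query, candidates, model, augmenter = NULL) {
  if (length(candidates) < 1L) stop("need at least one candidate")
  pids <- vapply(candidates, `[[`, character(1L), "physician_id")
  names(candidates) <- pids
  corpus <- list(queries = stats::setNames(list(query), query$query_id),
                 physicians = candidates)
  inter <- data.frame(query_id = query$query_id, physician_id = pids,
                      label = 0L, timestamp = query$timestamp,
                      stringsAsFactors = FALSE)
  scores <- predict_pairs(model, corpus, inter, augmenter = augmenter)
  ord <- order(-scores, pids, method = "radix")
  data.frame(rank = seq_along(ord), physician_id = pids[ord],
             score = scores[ord], stringsAsFactors = FALSE)
}

# surrogate r_d override rows for the cold physicians of a batch
# (NA rows mean "no override"); NULL when no augmenter or nothing is cold
make_rd_override <- function(corpus, inter, augmenter, cfg) {
  if (is.null(augmenter)) return(NULL)
  phys <- corpus$physicians[inter$physician_id]
  coldp <- vapply(phys, `[[`, integer(1L), "reply_count") <
    augmenter$cold_threshold
  if (!any(coldp)) return(NULL)
  rd_override <- matrix(NA_real_, nrow(inter), cfg$d_h)
  for (b in which(coldp))
    rd_override[b, ] <- augment_cold_physician(phys[[b]], augmenter,
                                               check_threshold = FALSE)
  rd_override
}

# r_d vectors for a set of physicians at a reference day, batched through
# the engine's history channel (zero rows for empty windows)
encode_rd_batch <- function(model, physicians, now) {
  cfg <- model$config; vocab <- model$vocab; params <- model$params
  B <- length(physicians)
  reps <- lapply(physicians, function(p)
    select_recent(p$reply_history, now, cfg$window_days, cfg$max_history))
  ks <- vapply(reps, length, integer(1L))
  if (sum(ks) == 0L) return(matrix(0, B, cfg$d_h))
  offsets <- c(0L, cumsum(ks))[seq_len(B)]
  all_replies <- unlist(reps, recursive = FALSE)
  rmat <- id_matrix(lapply(all_replies, `[[`, "tokens"), vocab,
                    cfg$max_reply_len)
  E <- enc_field_fwd(rmat, fpars(params, field_key(cfg, "reply")),
                     params$emb)$pooled
  gf <- gru_seq_fwd(E, offsets, ks, gpars(params, "gf"), cfg$d_h)
  gb <- gru_seq_fwd(E, offsets, ks, gpars(params, "gb"), cfg$d_h,
                    reverse = TRUE)
  owner <- rep.int(seq_len(B), ks)
  hist_attn_fwd((gf$Hseq + gb$Hseq) / 2, owner, B,
                params$ha_v, params$ha_vb)$pooled
}

#' Build the cold-start augmenter
#'
#' A credential-keyed knowledge base standing in for an external medical
#' knowledge graph: warm physicians (reply count at or above the cold
#' threshold, with a non-empty window at `now`) are encoded through the
#' model's history channel and their temporal vectors averaged per
#' `(specialty, title rank, hospital tier)` key, with specialty-level and
#' global fallbacks. An optional symptom lexicon (token -> expansion
#' tokens) supports sparse-query augmentation.
#'
#' @param model a trained `ohc_model`.
#' @param corpus the training corpus.
#' @param lexicon named list mapping a token to a character vector of
#'   expansion tokens (UMLS-style synonym stand-in).
#' @param now reference day for the recent window; defaults to the latest
#'   day observed in the corpus.
#' @return A list of class `cold_augmenter`.
#' @export
build_cold_augmenter <- function(model, corpus, lexicon = list(),
                                 now = NULL) {
  cfg <- model$config
  phys <- corpus$physicians
  if (is.null(now)) {
    days <- unlist(lapply(phys, function(p)
      vapply(p$reply_history, `[[`, integer(1L), "day")))
    now <- max(c(corpus$interactions$timestamp, days, 1L))
  }
  counts <- vapply(phys, `[[`, integer(1L), "reply_count")
  warm <- phys[counts >= cfg$cold_threshold]
  if (length(warm) == 0L)
    stop("empty knowledge base: no warm physicians to build surrogates from")
  rd <- encode_rd_batch(model, warm, now)
  nonempty <- rowSums(rd != 0) > 0
  if (!any(nonempty))
    stop("empty knowledge base: no warm physician has replies in the window")
  rd <- rd[nonempty, , drop = FALSE]
  warm <- warm[nonempty]
  key3 <- vapply(warm, function(p)
    paste(p$specialty_id, p$title_rank, p$hospital_tier, sep = "|"),
    character(1L))
  key1 <- vapply(warm, `[[`, character(1L), "specialty_id")
  mean_by <- function(key) {
    m <- rowsum(rd, key) / as.vector(table(key)[sort(unique(key))])
    m[sort(unique(key)), , drop = FALSE]
  }
  structure(list(kb_exact = mean_by(key3), kb_spec = mean_by(key1),
                 global = colMeans(rd), lexicon = lexicon,
                 cold_threshold = cfg$cold_threshold, now = now),
            class = "cold_augmenter")
}

#' Surrogate temporal vector for a cold physician
#'
#' Looks up the knowledge base on (specialty, title rank, hospital tier),
#' falling back to the specialty mean and then the global mean. The result
#' replaces `r_d` in [encode_physician()].
#'
#' @param physician a `physician_profile` with
#'   `reply_count < cold_threshold`.
#' @param augmenter a [build_cold_augmenter()] result.
#' @param check_threshold enforce the cold precondition (default TRUE).
#' @return A numeric surrogate vector (length `d_h`).
#' @export
augment_cold_physician <- function(physician, augmenter,
                                   check_threshold = TRUE) {
  if (check_threshold &&
      physician$reply_count >= augmenter$cold_threshold)
    stop("physician ", physician$physician_id, " is not cold (",
         physician$reply_count, " replies)")
  k3 <- paste(physician$specialty_id, physician$title_rank,
              physician$hospital_tier, sep = "|")
  if (k3 %in% rownames(augmenter$kb_exact))
    return(as.vector(augmenter$kb_exact[k3, ]))
  if (physician$specialty_id %in% rownames(augmenter$kb_spec))
    return(as.vector(augmenter$kb_spec[physician$specialty_id, ]))
  augmenter$global
}

#' Expand a sparse query's content via the symptom lexicon
#'
#' For queries whose content is shorter than the sparse threshold, the
#' lexicon expansions of the title and content tokens are appended to the
#' content (deduplicated, capped at the content length limit). Title,
#' profile and tags are unchanged; expansion never removes tokens.
#'
#' @param query a `patient_query`.
#' @param augmenter a `cold_augmenter` (its `lexicon` is used).
#' @param sparse_threshold content length below which expansion applies.
#' @param max_content_len cap on the expanded content length.
#' @return The (possibly expanded) query.
#' @export
augment_sparse_query <- function(query, augmenter, sparse_threshold = 8L,
                                 max_content_len = 128L) {
  content <- query$content_tokens
  if (length(content) >= sparse_threshold) return(query)
  lex <- augmenter$lexicon
  if (length(lex) == 0L) return(query)
  seen <- unique(c(query$title_tokens, content))
  expansions <- unique(unlist(lex[intersect(seen, names(lex))],
                              use.names = FALSE))
  expansions <- setdiff(expansions, content)
  room <- max_content_len - length(content)
  if (length(expansions) > room)
    expansions <- expansions[seq_len(max(0L, room))]
  query$content_tokens <- c(content, expansions)
  query
}

#' Predict adoption scores for labelled pairs
#'
#' Batched forward pass (no dropout). With an `augmenter`, physicians
#' below the cold threshold have their temporal vector replaced by the
#' credential surrogate; without one, an empty recent window contributes a
#' zero temporal vector.
#'
#' @param model an `ohc_model`.
#' @param corpus an `ohc_corpus` (or compatible list).
#' @param interactions data.frame with `query_id`, `physician_id`,
#'   `label`, `timestamp`.
#' @param augmenter optional `cold_augmenter`.
#' @param batch_size forward chunk size.
#' @return Numeric score vector aligned with `interactions` rows.
#' @export
predict_pairs <- function(model, corpus, interactions, augmenter = NULL,
                          batch_size = NULL) {
  cfg <- model$config
  bs <- batch_size %||% cfg$batch_size
  n <- nrow(interactions)
  scores <- numeric(n)
  ds <- prepare_dataset(corpus, interactions, model$vocab, cfg,
                        variant = model$variant)
  for (start in seq(1L, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    inter <- interactions[idx, , drop = FALSE]
    batch <- subset_batch(ds, idx)
    rd_override <- make_rd_override(corpus, inter, augmenter, cfg)
    scores[idx] <- model_fwd(model$params, batch, cfg, train = FALSE,
                             rd_override = rd_override)$score
  }
  scores
}

#' Train the matching model
#'
#' Mini-batch binary cross-entropy optimization with Adam at the default
#' recipe (batch 256, learning rate 0.01, at most 4 epochs, dropout 0.5,
#' L2 on weight matrices). After every epoch the validation accuracy and
#' AUC are logged; the parameters with the best validation AUC are
#' retained and training stops early once validation AUC fails to improve
#' for `patience` consecutive epochs. Fully reproducible from `seed`: the
#' master seed derives separate streams for initialization, shuffling and
#' dropout.
#'
#' @param corpus an `ohc_corpus`.
#' @param split an [split_dataset()] result.
#' @param config an [ohc_config()].
#' @param seed master seed.
#' @param variant optional ablation specification (see [init_model()]).
#' @param vocab optional pre-built vocabulary; by default it is built from
#'   the training split only.
#' @param augmenter optional `cold_augmenter`: when given, cold
#'   physicians' temporal vectors are replaced by their credential
#'   surrogates during training and validation, so the enriched inputs
#'   feed the model end to end.
#' @param verbose print per-epoch progress.
#' @return A trained `ohc_model` with a per-epoch `log` data.frame
#'   (`epoch`, `train_loss`, `val_acc`, `val_auc`) and `best_epoch`.
#' @export
train_matcher <- function(corpus, split, config = ohc_config(), seed = 1L,
                          variant = NULL, vocab = NULL, augmenter = NULL,
                          verbose = FALSE) {
  cfg <- config
  check_variant(variant)
  train <- split$train
  if (is.null(vocab)) {
    vocab <- build_vocab(corpus$queries[unique(train$query_id)],
                         corpus$physicians[unique(train$physician_id)],
                         min_count = cfg$min_count)
  }
  params <- init_params(vocab, cfg, derive_seed(seed, 1L))
  st <- adam_state(params)
  model <- structure(list(params = params, vocab = vocab, config = cfg,
                          variant = variant, log = NULL,
                          best_epoch = NA_integer_,
                          seed = as.integer(seed)),
                     class = "ohc_model")
  n <- nrow(train)
  ds_train <- prepare_dataset(corpus, train, vocab, cfg, variant = variant)
  log_rows <- list()
  best_auc <- -Inf; best_params <- params; best_epoch <- NA_integer_
  bad_epochs <- 0L
  with_seed(derive_seed(seed, 2L), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0L); sizes <- integer(0L)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        inter <- train[idx, , drop = FALSE]
        batch <- subset_batch(ds_train, idx)
        fwd <- model_fwd(params, batch, cfg, train = TRUE,
                         keep_cache = TRUE,
                         rd_override = make_rd_override(corpus, inter,
                                                        augmenter, cfg))
        loss <- bce_loss(fwd$score, batch$labels)
        if (!is.finite(loss))
          stop(sprintf(
            "non-finite training loss (epoch %d, batch at %d): %s; ",
            epoch, start, format(loss)),
            "inspect the learning rate and input scaling")
        losses <- c(losses, loss); sizes <- c(sizes, length(idx))
        gr <- model_bwd(params, batch, cfg, fwd)
        add_l2(gr, params, l2_coef(cfg))
        upd <- adam_step(params, gr, st, cfg)
        params <- upd$params; st <- upd$state
      }
      model$params <- params
      val <- predict_pairs(model, corpus, split$validation,
                           augmenter = augmenter)
      vacc <- mean((val >= cfg$threshold) == split$validation$label)
      vauc <- auc_scores(val, split$validation$label)
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = sum(losses * sizes) / sum(sizes),
        val_acc = vacc, val_auc = vauc)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val ACC %.4f, val AUC %.4f",
                        epoch, log_rows[[epoch]]$train_loss, vacc, vauc))
      if (is.finite(vauc) && vauc > best_auc) {
        best_auc <- vauc; best_params <- params; best_epoch <- epoch
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs > cfg$patience) break
      }
    }
  })
  model$params <- best_params
  model$log <- do.call(rbind, log_rows)
  model$best_epoch <- best_epoch
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint archive holds the full parameter set, vocabulary and
#' configuration; save followed by load round-trips bit-exactly.
#'
#' @param model an `ohc_model`.
#' @param path checkpoint file path.
#' @return `path` invisibly; `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ohc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ohc_model")) stop("not an ohcmatch checkpoint")
  model
}
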