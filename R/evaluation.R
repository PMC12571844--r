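#' @title Evaluation metrics and reporting
#' @description Classification metrics (accuracy at threshold 0.5, AUC by
#'   the rank statistic with half-credit for ties), macro-averaged top-K
#'   ranking metrics (Precision@K, Recall@K, NDCG@K with binary relevance
#'   and a log2 discount), and the popularity-bias audit (per-tier
#'   exposure rate and coverage contribution), with per-split (cold /
#'   warm / all) reporting and the input-ablation harness.
#' @name evaluation
NULL

#' Build a prediction table
#'
#' One row per scored pair with the true label, score and the predicted
#' label at the classification threshold.
#'
#' @param query_id,physician_id identifier vectors.
#' @param label true binary labels.
#' @param score predicted probabilities in (0, 1).
#' @param threshold classification threshold (default 0.5).
#' @return A data.frame of class `prediction_table`.
#' @export
prediction_table <- function(query_id, physician_id, label, score,
                             threshold = 0.5) {
  if (any(score <= 0 | score >= 1))
    stop("scores must lie strictly in (0, 1)")
  df <- data.frame(query_id = as.character(query_id),
                   physician_id = as.character(physician_id),
                   label = as.integer(label), score = as.numeric(score),
                   predicted = as.integer(score >= threshold),
                   stringsAsFactors = FALSE)
  class(df) <- c("prediction_table", "data.frame")
  df
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + FP + FN + TN)` at the table's threshold.
#'
#' @param table a [prediction_table()].
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(table) {
  if (nrow(table) == 0L) stop("empty prediction table")
  mean(table$predicted == table$label)
}

# rank-statistic AUC on raw vectors; NA when one class is absent
auc_scores <- function(score, label) {
  npos <- sum(label == 1L); nneg <- sum(label == 0L)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(score)  # average ranks give ties half credit
  (sum(r[label == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the ROC curve
#'
#' The rank-statistic estimator: the fraction of (positive, negative)
#' pairs ranked correctly, with ties counted half. Equals the probability
#' that a random positive scores above a random negative. A single-class
#' table is undefined and raises an error rather than returning 0.
#'
#' @param table a [prediction_table()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(table) {
  out <- auc_scores(table$score, table$label)
  if (is.na(out))
    stop("AUC is undefined: the table contains a single class")
  out
}

#' Build per-query recommendation lists
#'
#' For every test query with at least one adopted (positive) interaction,
#' the candidate set is its positive physicians plus `n_negatives` sampled
#' non-positive physicians; candidates are ranked by score (descending,
#' ties by physician id). Relevance is the binary adoption label.
#'
#' @param model an `ohc_model`.
#' @param corpus the corpus.
#' @param interactions evaluation interactions (typically the test split).
#' @param n_negatives sampled negatives per query (default 49).
#' @param seed RNG seed for negative sampling.
#' @param augmenter optional cold-start augmenter.
#' @return A data.frame of class `rec_table` with `query_id`, `rank`,
#'   `physician_id`, `score`, `relevant`.
#' @export
build_recommendations <- function(model, corpus, interactions,
                                  n_negatives = 49L, seed = 1L,
                                  augmenter = NULL) {
  pos <- interactions[interactions$label == 1L, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no positive interactions to recommend for")
  all_pids <- names(corpus$physicians)
  qids <- unique(pos$query_id)
  cand <- with_seed(seed, {
    do.call(rbind, lapply(qids, function(q) {
      qpos <- pos[pos$query_id == q, , drop = FALSE]
      pool <- setdiff(all_pids, qpos$physician_id)
      neg <- pool[sample.int(length(pool),
                             min(n_negatives, length(pool)))]
      data.frame(query_id = q,
                 physician_id = c(qpos$physician_id, neg),
                 label = c(rep(1L, nrow(qpos)), rep(0L, length(neg))),
                 timestamp = max(qpos$timestamp),
                 stringsAsFactors = FALSE)
    }))
  })
  cand$score <- predict_pairs(model, corpus, cand, augmenter = augmenter)
  ord <- order(cand$query_id, -cand$score, cand$physician_id,
               method = "radix")
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- stats::ave(seq_len(nrow(cand)), cand$query_id,
                          FUN = seq_along)
  out <- data.frame(query_id = cand$query_id, rank = cand$rank,
                    physician_id = cand$physician_id, score = cand$score,
                    relevant = cand$label, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rec_table", "data.frame")
  out
}

split_by_query <- function(recs) split(recs, recs$query_id)

#' Precision at K
#'
#' Per query, the fraction of the top `min(k, list length)` slots holding
#' relevant physicians; macro-averaged over queries.
#'
#' @param recs a `rec_table`.
#' @param k list depth (default 10).
#' @return Macro-averaged precision in `[0, 1]`.
#' @export
precision_at_k <- function(recs, k = 10L) {
  per <- vapply(split_by_query(recs), function(d) {
    kk <- min(k, nrow(d))
    sum(d$relevant[d$rank <= kk]) / kk
  }, numeric(1L))
  mean(per)
}

#' Recall at K
#'
#' Per query, the fraction of all relevant physicians captured in the top
#' `k`; macro-averaged. Queries without any relevant candidate are
#' excluded and counted in the `n_excluded` attribute.
#'
#' @inheritParams precision_at_k
#' @return Macro-averaged recall in `[0, 1]`.
#' @export
recall_at_k <- function(recs, k = 10L) {
  per <- vapply(split_by_query(recs), function(d) {
    nrel <- sum(d$relevant)
    if (nrel == 0L) return(NA_real_)
    sum(d$relevant[d$rank <= k]) / nrel
  }, numeric(1L))
  out <- mean(per, na.rm = TRUE)
  attr(out, "n_excluded") <- sum(is.na(per))
  out
}

#' Normalized discounted cumulative gain at K
#'
#' Binary relevance with the standard log2 discount:
#' `DCG = sum_{i<=k} rel_i / log2(i + 1)`, normalized by the ideal
#' ordering's DCG. Queries without relevant candidates are excluded.
#'
#' @inheritParams precision_at_k
#' @return Macro-averaged NDCG in `[0, 1]`.
#' @export
ndcg_at_k <- function(recs, k = 10L) {
  per <- vapply(split_by_query(recs), function(d) {
    nrel <- sum(d$relevant)
    if (nrel == 0L) return(NA_real_)
    top <- d[d$rank <= k, , drop = FALSE]
    dcg <- sum(top$relevant / log2(top$rank + 1))
    ideal <- seq_len(min(k, nrel))
    dcg / sum(1 / log2(ideal + 1))
  }, numeric(1L))
  out <- mean(per, na.rm = TRUE)
  attr(out, "n_excluded") <- sum(is.na(per))
  out
}

#' Per-tier exposure rate
#'
#' The share of top-K recommendation slots occupied by each popularity
#' tier's physicians; the three shares sum to one.
#'
#' @param recs a `rec_table`.
#' @param tiers an [assign_tiers()] result covering every recommended
#'   physician.
#' @param k list depth.
#' @return Named numeric vector (`head`, `middle`, `tail`).
#' @export
exposure_rate <- function(recs, tiers, k = 10L) {
  top <- recs[recs$rank <= k, , drop = FALSE]
  tt <- tiers[top$physician_id]
  if (anyNA(tt))
    stop("recommended physician without a tier assignment: ",
         top$physician_id[which(is.na(tt))[1L]])
  out <- c(head = 0, middle = 0, tail = 0)
  tab <- table(tt) / length(tt)
  out[names(tab)] <- as.vector(tab)
  out
}

#' Per-tier coverage contribution
#'
#' The share of distinct physicians appearing in any top-K list that
#' belong to each tier; shares sum to one.
#'
#' @inheritParams exposure_rate
#' @return Named numeric vector (`head`, `middle`, `tail`).
#' @export
coverage_contribution <- function(recs, tiers, k = 10L) {
  ids <- unique(recs$physician_id[recs$rank <= k])
  tt <- tiers[ids]
  if (anyNA(tt))
    stop("recommended physician without a tier assignment: ",
         ids[which(is.na(tt))[1L]])
  out <- c(head = 0, middle = 0, tail = 0)
  tab <- table(tt) / length(tt)
  out[names(tab)] <- as.vector(tab)
  out
}

# recall at k restricted to relevant physicians of one tier
tier_recall_at_k <- function(recs, tiers, tier, k = 10L) {
  per <- vapply(split_by_query(recs), function(d) {
    rel <- d[d$relevant == 1L & tiers[d$physician_id] == tier, ,
             drop = FALSE]
    if (nrow(rel) == 0L) return(NA_real_)
    sum(rel$rank <= k) / nrow(rel)
  }, numeric(1L))
  if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
}

#' Popularity-bias report
#'
#' Per tier: exposure rate, tier-restricted Recall@K and coverage
#' contribution over a recommendation table.
#'
#' @inheritParams exposure_rate
#' @return A data.frame with one row per tier.
#' @export
bias_report <- function(recs, tiers, k = 10L) {
  er <- exposure_rate(recs, tiers, k)
  cc <- coverage_contribution(recs, tiers, k)
  data.frame(tier = c("head", "middle", "tail"),
             exposure_rate = as.vector(er),
             recall_at_k = vapply(c("head", "middle", "tail"),
                                  function(t)
                                    tier_recall_at_k(recs, tiers, t, k),
                                  numeric(1L)),
             coverage_contribution = as.vector(cc),
             stringsAsFactors = FALSE)
}

#' Evaluate a model on a dataset split
#'
#' Computes ACC/AUC on the labelled pairs and the top-K metrics on
#' per-query candidate sets, reported for the cold subset (interactions
#' whose physician is below the cold threshold), the warm subset and the
#' whole split, plus the per-tier bias audit.
#'
#' @param model an `ohc_model`.
#' @param corpus the corpus.
#' @param interactions a split's interaction table (with `cold` column).
#' @param tiers optional [assign_tiers()] result; computed from the corpus
#'   when missing.
#' @param seed seed for negative sampling.
#' @param augmenter optional cold-start augmenter.
#' @param k list depth for the ranking metrics.
#' @return A list of class `metric_report` with `splits` (cold/warm/all
#'   ACC, AUC, P@K, R@K, NDCG@K), `tiers` (bias audit) and `k`.
#' @export
evaluate_model <- function(model, corpus, interactions, tiers = NULL,
                           seed = 1L, augmenter = NULL, k = NULL) {
  cfg <- model$config
  k <- k %||% cfg$k
  if (is.null(tiers)) tiers <- assign_tiers(corpus$physicians)
  if (is.null(interactions$cold)) {
    counts <- vapply(corpus$physicians, `[[`, integer(1L), "reply_count")
    interactions$cold <-
      counts[interactions$physician_id] < cfg$cold_threshold
  }
  score <- predict_pairs(model, corpus, interactions,
                         augmenter = augmenter)
  subsets <- list(cold = which(interactions$cold),
                  warm = which(!interactions$cold),
                  all = seq_len(nrow(interactions)))
  rows <- lapply(names(subsets), function(s) {
    idx <- subsets[[s]]
    if (length(idx) == 0L)
      return(data.frame(split = s, n = 0L, acc = NA_real_,
                        auc = NA_real_, precision_at_k = NA_real_,
                        recall_at_k = NA_real_, ndcg_at_k = NA_real_))
    sub <- interactions[idx, , drop = FALSE]
    sc <- score[idx]
    acc <- mean((sc >= cfg$threshold) == sub$label)
    a <- auc_scores(sc, sub$label)
    p <- r <- nd <- NA_real_
    if (any(sub$label == 1L)) {
      recs <- build_recommendations(model, corpus, sub,
                                    n_negatives = cfg$n_negatives,
                                    seed = derive_seed(seed, 3L),
                                    augmenter = augmenter)
      p <- precision_at_k(recs, k)
      r <- as.numeric(recall_at_k(recs, k))
      nd <- as.numeric(ndcg_at_k(recs, k))
    }
    data.frame(split = s, n = length(idx), acc = acc, auc = a,
               precision_at_k = p, recall_at_k = r, ndcg_at_k = nd)
  })
  recs_all <- build_recommendations(model, corpus, interactions,
                                    n_negatives = cfg$n_negatives,
                                    seed = derive_seed(seed, 3L),
                                    augmenter = augmenter)
  structure(list(splits = do.call(rbind, rows),
                 tiers = bias_report(recs_all, tiers, k), k = k),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$splits, row.names = FALSE, digits = 4)
  cat("per-tier bias audit:\n")
  print(x$tiers, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Standard ablation variants
#'
#' The patient-side groups (E1 content only, E2 tags only, E3 title only,
#' E4 title+content, E5 full context) and physician-side groups (F1
#' credentials only, F2 reply history only, F3 both). Disabled patient
#' fields are replaced by the learned null token; a disabled history
#' channel contributes a zero temporal vector.
#'
#' @return Named list of variant specifications.
#' @export
ablation_variants <- function() {
  full_p <- c("title", "content", "tags", "profile")
  full_s <- c("credentials", "history")
  list(
    E1 = list(patient_fields = "content", physician_sources = full_s),
    E2 = list(patient_fields = "tags", physician_sources = full_s),
    E3 = list(patient_fields = "title", physician_sources = full_s),
    E4 = list(patient_fields = c("title", "content"),
              physician_sources = full_s),
    E5 = list(patient_fields = full_p, physician_sources = full_s),
    F1 = list(patient_fields = full_p, physician_sources = "credentials"),
    F2 = list(patient_fields = full_p, physician_sources = "history"),
    F3 = list(patient_fields = full_p, physician_sources = full_s))
}

#' Run the input-ablation harness
#'
#' Trains one model per variant per seed with otherwise identical
#' configurations and reports per-variant mean and standard deviation of
#' test ACC and AUC.
#'
#' @param corpus an `ohc_corpus`.
#' @param split a dataset split.
#' @param variants named list of variant specifications (see
#'   [ablation_variants()]).
#' @param seeds integer vector of training seeds.
#' @param config an [ohc_config()].
#' @param verbose print progress.
#' @return A list with `runs` (per variant x seed test ACC/AUC) and
#'   `summary` (per variant mean and sd).
#' @export
run_ablation <- function(corpus, split, variants = ablation_variants(),
                         seeds = 1:5, config = ohc_config(),
                         verbose = FALSE) {
  if (length(variants) == 0L) stop("no variants given")
  for (v in variants) check_variant(v)
  runs <- list()
  for (vn in names(variants)) {
    for (s in seeds) {
      m <- train_matcher(corpus, split, config, seed = s,
                         variant = variants[[vn]])
      sc <- predict_pairs(m, corpus, split$test)
      runs[[length(runs) + 1L]] <- data.frame(
        variant = vn, seed = s,
        acc = mean((sc >= config$threshold) == split$test$label),
        auc = auc_scores(sc, split$test$label))
      if (verbose)
        message(sprintf("%s seed %d: AUC %.4f", vn, s,
                        runs[[length(runs)]]$auc))
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$variant), function(d)
    data.frame(variant = d$variant[1L], n = nrow(d),
               mean_acc = mean(d$acc), sd_acc = stats::sd(d$acc),
               mean_auc = mean(d$auc), sd_auc = stats::sd(d$auc))))
  agg <- agg[match(names(variants), agg$variant), , drop = FALSE]
  rownames(agg) <- NULL
  list(runs = runs, summary = agg)
}
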