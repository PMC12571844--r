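#' @title Synthetic online-health-community generator
#' @description Seeded generator of a full synthetic corpus (queries,
#'   physicians, adoption-labelled interactions) built around latent
#'   medical specialties. Queries and physicians each carry one latent
#'   specialty; their texts mix a specialty-specific vocabulary with shared
#'   noise under a controllable signal strength, physician activity follows
#'   a Zipf skew, and adoption labels are Bernoulli draws conditioned on
#'   specialty agreement. The latent assignment is returned separately so
#'   models can never read it by accident.
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' Defaults emulate the structure of a scraped health Q&A platform at desk
#' scale: short titles (mean 15 tokens), longer contents (mean 128 tokens),
#' an 8-major / 32-minor tag taxonomy, physician credential fields
#' (title rank, hospital tier, specialty), reply histories over a 120-day
#' horizon with Zipf(1.1)-skewed activity, and a roughly 50/50 mix of
#' specialty-matched and mismatched candidate pairs labelled with adoption
#' probabilities 0.85 (matched) versus 0.10 (mismatched).
#'
#' @param n_specialties number of latent specialties (<= `n_major`).
#' @param n_patients,n_physicians,n_interactions corpus sizes.
#' @param vocab_per_specialty distinct tokens per specialty vocabulary.
#' @param shared_noise_vocab distinct tokens in the shared noise vocabulary.
#' @param signal_strength probability `s` that a text token (or tag major)
#'   comes from the entity's specialty rather than noise.
#' @param match_prob_same,match_prob_diff adoption probabilities for
#'   specialty-matched / mismatched pairs (`same > diff` required).
#' @param matched_fraction fraction of candidate pairs that are matched.
#' @param popularity_skew Zipf exponent for physician activity.
#' @param mean_replies mean replies per physician over the horizon.
#' @param max_replies cap on a single physician's reply count.
#' @param horizon_days day-index horizon; interactions are stamped on
#'   days 16..horizon so a full 15-day window precedes each one.
#' @param title_len_mean,content_len_mean,reply_len_mean Poisson means of
#'   the token-sequence lengths (clipped to >= 1).
#' @param n_major,n_minor_per_major tag taxonomy shape (8 x 4 = 32 minors).
#' @param mean_tags Poisson mean of tags per query (clipped to >= 1).
#' @param authority_bonus optional additive adoption-probability bonus for
#'   Chief physicians (default 0 = off).
#' @param seed integer master seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_specialties = 4L, n_patients = 800L,
                             n_physicians = 200L, n_interactions = 4000L,
                             vocab_per_specialty = 50L,
                             shared_noise_vocab = 200L,
                             signal_strength = 0.7,
                             match_prob_same = 0.85,
                             match_prob_diff = 0.10,
                             matched_fraction = 0.5,
                             popularity_skew = 1.1,
                             mean_replies = 40L, max_replies = 400L,
                             horizon_days = 120L,
                             title_len_mean = 15, content_len_mean = 128,
                             reply_len_mean = 40,
                             n_major = 8L, n_minor_per_major = 4L,
                             mean_tags = 2,
                             authority_bonus = 0,
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(signal_strength, match_prob_same, match_prob_diff,
             matched_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (match_prob_same <= match_prob_diff)
    stop("match_prob_same must exceed match_prob_diff for a learnable corpus")
  if (n_specialties > n_major)
    stop("n_specialties cannot exceed the number of major tag categories")
  if (vocab_per_specialty < 1L || shared_noise_vocab < 1L)
    stop("vocabulary sizes must be positive")
  if (n_patients < 1L || n_physicians < 2L || n_interactions < 1L)
    stop("corpus sizes too small")
  if (horizon_days <= 16L) stop("horizon_days must exceed 16")
  structure(cfg, class = "generator_config")
}

# length draw: Poisson clipped to >= 1
rlen <- function(n, mean) pmax(1L, stats::rpois(n, mean))

# draw m tokens for an entity of specialty k: specialty vocabulary with
# probability s, shared noise otherwise
draw_tokens <- function(m, k, cfg) {
  from_spec <- stats::runif(m) < cfg$signal_strength
  toks <- character(m)
  ns <- sum(from_spec)
  if (ns) toks[from_spec] <- paste0(
    "s", k, "w", sample.int(cfg$vocab_per_specialty, ns, replace = TRUE))
  if (m - ns) toks[!from_spec] <- paste0(
    "nw", sample.int(cfg$shared_noise_vocab, m - ns, replace = TRUE))
  toks
}

# balanced latent specialty assignment (guarantees every specialty occurs)
draw_specialties <- function(n, K) sample(rep_len(seq_len(K), n))

#' Generate a synthetic corpus
#'
#' Everything is reproducible from `config$seed`; identical configurations
#' yield byte-identical corpora. In the degenerate limit
#' `signal_strength = 1`, `match_prob_same = 1`, `match_prob_diff = 0`, the
#' adoption label is a deterministic function of latent specialty equality.
#'
#' @param config a [generator_config()].
#' @return A list of class `ohc_generated` with elements `corpus` (an
#'   `ohc_corpus`), `latent` (named specialty vectors for queries and
#'   physicians) and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  with_seed(cfg$seed, {
    K <- cfg$n_specialties
    qspec <- draw_specialties(cfg$n_patients, K)
    pspec <- draw_specialties(cfg$n_physicians, K)
    qids <- sprintf("q%04d", seq_len(cfg$n_patients))
    pids <- sprintf("p%04d", seq_len(cfg$n_physicians))

    queries <- vector("list", cfg$n_patients)
    tlen <- rlen(cfg$n_patients, cfg$title_len_mean)
    clen <- rlen(cfg$n_patients, cfg$content_len_mean)
    ntag <- rlen(cfg$n_patients, cfg$mean_tags)
    for (i in seq_len(cfg$n_patients)) {
      k <- qspec[i]
      major <- ifelse(stats::runif(ntag[i]) < cfg$signal_strength, k,
                      sample.int(cfg$n_major, ntag[i], replace = TRUE))
      tags <- cbind(major,
                    sample.int(cfg$n_minor_per_major, ntag[i],
                               replace = TRUE))
      age <- if (stats::runif(1) < 0.1) NA_integer_ else
        as.integer(pmin(90, pmax(18, round(stats::rnorm(1, 45, 15)))))
      disease_spec <- if (stats::runif(1) < cfg$signal_strength) k else
        sample.int(K, 1L)
      queries[[i]] <- patient_query(
        qids[i],
        title_tokens = draw_tokens(tlen[i], k, cfg),
        content_tokens = draw_tokens(clen[i], k, cfg),
        profile = list(
          age = age,
          gender = sample(c("F", "M", "Unknown"), 1L,
                          prob = c(0.45, 0.45, 0.10)),
          region = paste0("r", sample.int(10L, 1L)),
          disease = paste0("d", disease_spec, ".",
                           sample.int(3L, 1L)),
          history_flags = sample(paste0("flag", 1:10),
                                 stats::rbinom(1L, 3L, 0.3))),
        tags = tags,
        timestamp = sample(16:cfg$horizon_days, 1L))
    }

    # Zipf activity: rank weights i^(-skew), permuted over physicians
    w <- seq_len(cfg$n_physicians)^(-cfg$popularity_skew)
    counts <- round(cfg$mean_replies * cfg$n_physicians * w / sum(w))
    counts <- pmin(cfg$max_replies, pmax(1L, counts))
    counts <- sample(counts)
    physicians <- vector("list", cfg$n_physicians)
    for (i in seq_len(cfg$n_physicians)) {
      k <- pspec[i]
      m <- counts[i]
      days <- sort(sample.int(cfg$horizon_days, m, replace = TRUE))
      lens <- rlen(m, cfg$reply_len_mean)
      hist <- lapply(seq_len(m), function(j)
        list(day = days[j], tokens = draw_tokens(lens[j], k, cfg)))
      physicians[[i]] <- physician_profile(
        pids[i],
        title_rank = sample(c("Chief", "AssociateChief", "Attending"), 1L,
                            prob = c(0.2, 0.3, 0.5)),
        hospital_tier = sample.int(3L, 1L, prob = c(0.3, 0.4, 0.3)),
        specialty_id = paste0("s", k),
        reply_history = hist)
    }

    inter <- sample_interactions(cfg, qids, pids, qspec, pspec, physicians)
    corpus <- ohc_corpus(queries, physicians, inter)
    latent <- list(query = stats::setNames(qspec, qids),
                   physician = stats::setNames(pspec, pids))
    structure(list(corpus = corpus, latent = latent, config = cfg),
              class = "ohc_generated")
  })
}

# candidate pairs: ~matched_fraction specialty-matched, unique (query,
# physician) pairs, Bernoulli adoption labels by specialty agreement
sample_interactions <- function(cfg, qids, pids, qspec, pspec, physicians) {
  by_spec <- split(seq_along(pids), pspec)
  n <- cfg$n_interactions
  qi <- integer(n); pi <- integer(n)
  seen <- new.env(hash = TRUE, size = 2L * n)
  filled <- 0L; attempts <- 0L
  while (filled < n) {
    attempts <- attempts + 1L
    if (attempts > 50L * n)
      stop("could not sample ", n, " unique interaction pairs; ",
           "corpus too small for n_interactions")
    q <- sample.int(length(qids), 1L)
    matched <- stats::runif(1) < cfg$matched_fraction
    pool <- if (matched) by_spec[[as.character(qspec[q])]]
      else setdiff(seq_along(pids), by_spec[[as.character(qspec[q])]])
    if (length(pool) == 0L) next
    p <- pool[sample.int(length(pool), 1L)]
    key <- paste0(q, "_", p)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    filled <- filled + 1L
    qi[filled] <- q; pi[filled] <- p
  }
  same <- qspec[qi] == pspec[pi]
  prob <- ifelse(same, cfg$match_prob_same, cfg$match_prob_diff)
  if (cfg$authority_bonus > 0) {
    chief <- vapply(physicians[pi], function(p) p$title_rank == "Chief",
                    logical(1L))
    prob <- pmin(1, prob + cfg$authority_bonus * chief)
  }
  interactions_table(qids[qi], pids[pi],
                     label = stats::rbinom(n, 1L, prob),
                     timestamp = sample(16:cfg$horizon_days, n,
                                        replace = TRUE))
}

#' Generate a corpus with a controlled cold-physician fraction
#'
#' Generates a corpus from `config`, then truncates the histories of
#' exactly `ceiling(fraction * n_physicians)` randomly chosen physicians to
#' 0-4 replies (below the cold threshold of 5), keeping the most recent
#' replies. Credential fields are untouched, so they remain informative of
#' the latent specialty.
#'
#' @param config a [generator_config()].
#' @param fraction fraction of physicians to make cold, in (0, 1).
#' @return An `ohc_generated` list with an extra `cold_ids` element.
#' @export
make_cold_corpus <- function(config, fraction = 0.3) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  gen <- generate_corpus(config)
  with_seed(derive_seed(config$seed, 7L), {
    n <- length(gen$corpus$physicians)
    n_cold <- as.integer(ceiling(fraction * n))
    cold_idx <- sample.int(n, n_cold)
    keep_n <- sample(0:4, n_cold, replace = TRUE)
    for (j in seq_len(n_cold)) {
      p <- gen$corpus$physicians[[cold_idx[j]]]
      m <- length(p$reply_history)
      hist <- if (keep_n[j] == 0L) list()
        else p$reply_history[seq.int(max(1L, m - keep_n[j] + 1L), m)]
      if (m <= keep_n[j]) hist <- p$reply_history
      gen$corpus$physicians[[cold_idx[j]]] <- physician_profile(
        p$physician_id, p$title_rank, p$hospital_tier, p$specialty_id, hist)
    }
    gen$cold_ids <- names(gen$corpus$physicians)[sort(cold_idx)]
    gen
  })
}
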