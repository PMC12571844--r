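#' @title Corpus data model and I/O
#' @description Constructors and validators for the three record kinds of an
#'   online-health-community corpus (patient queries, physician profiles,
#'   adoption-labelled interactions), a JSON-lines storage format, vocabulary
#'   construction, 6:2:2 dataset splitting and head/middle/tail popularity
#'   tier assignment.
#' @name corpus_io
NULL

#' Construct a patient query record
#'
#' A query holds the four patient-side input fields of the matching model:
#' the title token sequence (short, ~15 tokens), the content token sequence
#' (longer, ~128 tokens), structured profile fields, and semantic tag
#' identifiers drawn from a major/minor taxonomy. Missing categorical
#' profile values must be the literal category `"Unknown"`.
#'
#' @param query_id unique identifier string.
#' @param title_tokens character vector of title tokens (non-empty).
#' @param content_tokens character vector of content tokens.
#' @param profile named list with elements `age` (integer years or NA),
#'   `gender`, `region`, `disease` (categories, `"Unknown"` when missing)
#'   and `history_flags` (character vector, possibly empty).
#' @param tags integer matrix with columns `major`, `minor` (0 rows allowed).
#' @param timestamp integer day index.
#' @return A list of class `patient_query`.
#' @export
patient_query <- function(query_id, title_tokens, content_tokens,
                          profile = list(), tags = NULL, timestamp = 0L) {
  if (!is.character(query_id) || length(query_id) != 1L || !nzchar(query_id))
    stop("query_id must be a non-empty string")
  title_tokens <- as.character(title_tokens)
  if (length(title_tokens) == 0L)
    stop("query ", query_id, ": title_tokens must be non-empty")
  defaults <- list(age = NA_integer_, gender = "Unknown", region = "Unknown",
                   disease = "Unknown", history_flags = character())
  profile <- utils::modifyList(defaults, as.list(profile))
  profile$age <- if (is.null(profile$age) || length(profile$age) == 0L ||
                     is.na(profile$age)) NA_integer_
    else as.integer(profile$age)
  for (f in c("gender", "region", "disease")) {
    v <- profile[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !nzchar(v))
      profile[[f]] <- "Unknown"
    else profile[[f]] <- as.character(v)
  }
  profile$history_flags <- as.character(profile$history_flags)
  if (is.null(tags)) tags <- matrix(integer(), ncol = 2L)
  tags <- matrix(as.integer(tags), ncol = 2L,
                 dimnames = list(NULL, c("major", "minor")))
  if (nrow(tags) && (any(tags[, 1L] < 1L) || any(tags[, 2L] < 1L)))
    stop("query ", query_id, ": tag categories must be >= 1")
  structure(list(query_id = query_id,
                 title_tokens = title_tokens,
                 content_tokens = as.character(content_tokens),
                 profile = profile, tags = tags,
                 timestamp = as.integer(timestamp)),
            class = "patient_query")
}

#' Construct a physician profile record
#'
#' Holds static credentials (professional title rank, hospital tier,
#' specialty) and the time-stamped reply history that feeds the temporal
#' channel. The history is kept sorted by day index and `reply_count`
#' always equals its length.
#'
#' @param physician_id unique identifier string.
#' @param title_rank one of `"Chief"`, `"AssociateChief"`, `"Attending"`.
#' @param hospital_tier integer ordered tier (1 = top).
#' @param specialty_id category label (stand-in for an ICD-11 chapter).
#' @param reply_history list of `list(day = <int>, tokens = <chr>)`, any order.
#' @return A list of class `physician_profile`.
#' @export
physician_profile <- function(physician_id, title_rank = "Attending",
                              hospital_tier = 3L, specialty_id = "Unknown",
                              reply_history = list()) {
  if (!is.character(physician_id) || length(physician_id) != 1L ||
      !nzchar(physician_id))
    stop("physician_id must be a non-empty string")
  ranks <- c("Chief", "AssociateChief", "Attending")
  title_rank <- as.character(title_rank)
  if (!title_rank %in% ranks)
    stop("physician ", physician_id, ": title_rank must be one of ",
         paste(ranks, collapse = ", "))
  reply_history <- lapply(reply_history, function(r)
    list(day = as.integer(r$day), tokens = as.character(r$tokens)))
  if (length(reply_history)) {
    ord <- order(vapply(reply_history, `[[`, integer(1L), "day"))
    reply_history <- reply_history[ord]
  }
  structure(list(physician_id = physician_id,
                 title_rank = title_rank,
                 hospital_tier = as.integer(hospital_tier),
                 specialty_id = as.character(specialty_id),
                 reply_history = reply_history,
                 reply_count = length(reply_history)),
            class = "physician_profile")
}

#' Construct the interaction table
#'
#' One row per supervised (query, physician) pair with a binary adoption
#' label (1 = the physician's answer was endorsed) and a day-index
#' timestamp. Pairs must be unique.
#'
#' @param query_id,physician_id character vectors (recycled as data.frame).
#' @param label integer 0/1 vector.
#' @param timestamp integer day indices.
#' @return A data.frame of class `interaction_table`.
#' @export
interactions_table <- function(query_id, physician_id, label, timestamp) {
  label <- as.integer(label)
  if (any(!label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  df <- data.frame(query_id = as.character(query_id),
                   physician_id = as.character(physician_id),
                   label = label, timestamp = as.integer(timestamp),
                   stringsAsFactors = FALSE)
  key <- paste(df$query_id, df$physician_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate interaction pair: (", d$query_id, ", ",
         d$physician_id, ")")
  }
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Assemble and validate a corpus
#'
#' @param queries list of [patient_query()] records.
#' @param physicians list of [physician_profile()] records.
#' @param interactions an [interactions_table()].
#' @return A list of class `ohc_corpus` with named `queries` and
#'   `physicians` lists and the `interactions` table.
#' @export
ohc_corpus <- function(queries, physicians, interactions) {
  qids <- vapply(queries, `[[`, character(1L), "query_id")
  pids <- vapply(physicians, `[[`, character(1L), "physician_id")
  if (anyDuplicated(qids))
    stop("duplicate query_id: ", qids[duplicated(qids)][1L])
  if (anyDuplicated(pids))
    stop("duplicate physician_id: ", pids[duplicated(pids)][1L])
  names(queries) <- qids
  names(physicians) <- pids
  if (!inherits(interactions, "interaction_table"))
    interactions <- interactions_table(interactions$query_id,
                                       interactions$physician_id,
                                       interactions$label,
                                       interactions$timestamp)
  missq <- setdiff(interactions$query_id, qids)
  if (length(missq)) stop("interaction references unknown query_id: ",
                          missq[1L])
  missp <- setdiff(interactions$physician_id, pids)
  if (length(missp)) stop("interaction references unknown physician_id: ",
                          missp[1L])
  structure(list(queries = queries, physicians = physicians,
                 interactions = interactions),
            class = "ohc_corpus")
}

#' @export
print.ohc_corpus <- function(x, ...) {
  cat(sprintf(
    "<ohc_corpus> %d queries, %d physicians, %d interactions (%.1f%% positive)\n",
    length(x$queries), length(x$physicians), nrow(x$interactions),
    100 * mean(x$interactions$label)))
  invisible(x)
}

record_to_json <- function(rec) {
  if (inherits(rec, "patient_query")) {
    obj <- list(record_type = "query", query_id = rec$query_id,
                title_tokens = rec$title_tokens,
                content_tokens = rec$content_tokens,
                profile = list(age = rec$profile$age,
                               gender = rec$profile$gender,
                               region = rec$profile$region,
                               disease = rec$profile$disease,
                               history_flags = I(rec$profile$history_flags)),
                tags = lapply(seq_len(nrow(rec$tags)),
                              function(i) unname(rec$tags[i, ])),
                timestamp = rec$timestamp)
  } else if (inherits(rec, "physician_profile")) {
    obj <- list(record_type = "physician", physician_id = rec$physician_id,
                title_rank = rec$title_rank,
                hospital_tier = rec$hospital_tier,
                specialty_id = rec$specialty_id,
                reply_history = lapply(rec$reply_history, function(r)
                  list(day = r$day, tokens = I(r$tokens))))
  } else stop("unknown record class")
  jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null",
                   digits = NA)
}

#' Write a corpus to a JSON-lines file
#'
#' One UTF-8 JSON object per line with a `record_type` discriminator in
#' `{"query","physician","interaction"}`. Round-trips through
#' [read_corpus()].
#'
#' @param corpus an `ohc_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "ohc_corpus"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (q in corpus$queries) writeLines(record_to_json(q), con)
  for (p in corpus$physicians) writeLines(record_to_json(p), con)
  it <- corpus$interactions
  for (i in seq_len(nrow(it))) {
    writeLines(jsonlite::toJSON(
      list(record_type = "interaction", query_id = it$query_id[i],
           physician_id = it$physician_id[i], label = it$label[i],
           timestamp = it$timestamp[i]),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a corpus from a JSON-lines file
#'
#' Parses and validates every line; a malformed line aborts with its line
#' number, duplicate identifiers abort with the offending id. Unknown
#' fields in a record are ignored.
#'
#' @param path path to a `.jsonl` corpus written by [write_corpus()].
#' @return An `ohc_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  queries <- list(); physicians <- list()
  iq <- ip <- 0L
  irec <- vector("list", length(lines)); ni <- 0L
  for (ln in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = TRUE),
                    error = function(e)
                      stop("parse error at line ", ln, ": ",
                           conditionMessage(e), call. = FALSE))
    rt <- obj$record_type
    if (is.null(rt))
      stop("line ", ln, ": missing record_type discriminator")
    if (rt == "query") {
      tags <- if (length(obj$tags)) {
        tg <- obj$tags
        if (is.list(tg)) tg <- do.call(rbind, tg)
        matrix(as.integer(tg), ncol = 2L)
      } else NULL
      age <- obj$profile$age
      queries[[iq <- iq + 1L]] <- patient_query(
        obj$query_id, obj$title_tokens, obj$content_tokens %||% character(),
        profile = list(age = if (is.null(age)) NA_integer_ else age,
                       gender = obj$profile$gender,
                       region = obj$profile$region,
                       disease = obj$profile$disease,
                       history_flags = obj$profile$history_flags %||%
                         character()),
        tags = tags, timestamp = obj$timestamp %||% 0L)
    } else if (rt == "physician") {
      rh <- obj$reply_history
      hist <- if (is.null(rh) || length(rh) == 0L) list()
        else if (is.data.frame(rh))
          lapply(seq_len(nrow(rh)), function(i)
            list(day = rh$day[i], tokens = rh$tokens[[i]]))
        else rh
      physicians[[ip <- ip + 1L]] <- physician_profile(
        obj$physician_id, obj$title_rank %||% "Attending",
        obj$hospital_tier %||% 3L, obj$specialty_id %||% "Unknown",
        reply_history = hist)
    } else if (rt == "interaction") {
      irec[[ni <- ni + 1L]] <- list(obj$query_id, obj$physician_id,
                                    obj$label, obj$timestamp %||% 0L)
    } else stop("line ", ln, ": unknown record_type '", rt, "'")
  }
  if (ni == 0L) stop("corpus contains no interaction records")
  irec <- irec[seq_len(ni)]
  inter <- interactions_table(
    vapply(irec, `[[`, character(1L), 1L),
    vapply(irec, `[[`, character(1L), 2L),
    vapply(irec, function(r) as.integer(r[[3L]]), integer(1L)),
    vapply(irec, function(r) as.integer(r[[4L]]), integer(1L)))
  ohc_corpus(queries, physicians, inter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a token vocabulary from a corpus
#'
#' Counts tokens over every stream the encoders consume: query titles,
#' contents, serialized profile and tag tokens, serialized physician
#' credentials and reply texts. Tokens with frequency at least `min_count`
#' receive ids starting at 2, ordered by frequency (descending) then
#' lexicographically, so construction is deterministic. Id 0 is the padding
#' token, id 1 the unknown token; a learned `"<null>"` token (used to blank
#' out ablated input fields) is always appended.
#'
#' @param queries list of `patient_query` records.
#' @param physicians list of `physician_profile` records.
#' @param min_count minimum corpus frequency for inclusion (>= 1).
#' @return A list of class `ohc_vocab` with `token_to_id`, `id_to_token`,
#'   `pad_id = 0`, `unk_id = 1`, `null_id` and `size`.
#' @export
build_vocab <- function(queries, physicians, min_count = 1L) {
  if (min_count < 1L) stop("min_count must be >= 1")
  if (length(queries) == 0L && length(physicians) == 0L)
    stop("cannot build a vocabulary from an empty corpus")
  streams <- c(
    unlist(lapply(queries, function(q) c(q$title_tokens, q$content_tokens,
                                         profile_tokens(q),
                                         tag_tokens(q))),
           use.names = FALSE),
    unlist(lapply(physicians, function(p)
      c(credential_tokens(p),
        unlist(lapply(p$reply_history, `[[`, "tokens"), use.names = FALSE))),
      use.names = FALSE))
  if (length(streams) == 0L) stop("corpus contains no tokens")
  tab <- table(streams)
  keep <- tab[tab >= min_count]
  toks <- names(keep)[order(-as.integer(keep), names(keep), method = "radix")]
  toks <- setdiff(toks, c("<pad>", "<unk>", "<null>"))
  id_to_token <- c("<pad>", "<unk>", toks, "<null>")
  token_to_id <- stats::setNames(seq_along(id_to_token) - 1L, id_to_token)
  structure(list(token_to_id = token_to_id, id_to_token = id_to_token,
                 pad_id = 0L, unk_id = 1L,
                 null_id = unname(token_to_id[["<null>"]]),
                 size = length(id_to_token)),
            class = "ohc_vocab")
}

#' Look up token ids
#'
#' Unseen tokens map to the unknown id.
#'
#' @param vocab an `ohc_vocab`.
#' @param tokens character vector.
#' @return Integer id vector of the same length.
#' @export
vocab_ids <- function(vocab, tokens) {
  ids <- vocab$token_to_id[tokens]
  ids[is.na(ids)] <- vocab$unk_id
  as.integer(ids)
}

#' @export
print.ohc_vocab <- function(x, ...) {
  cat(sprintf("<ohc_vocab> %d tokens (pad=0, unk=1, null=%d)\n",
              x$size, x$null_id))
  invisible(x)
}

#' Split interactions into train/validation/test
#'
#' Seeded shuffle followed by partition at the rounded 6:2:2 targets (or any
#' ratios summing to one). Every interaction lands in exactly one part. A
#' logical `cold` column marks interactions whose physician has fewer than
#' `cold_threshold` historical replies.
#'
#' @param interactions an `interaction_table`.
#' @param physicians named list of `physician_profile` records (for the cold
#'   mask); may be `NULL` to skip it.
#' @param ratios numeric length-3, summing to 1 (tolerance 1e-9).
#' @param seed integer RNG seed.
#' @param cold_threshold replies below which a physician counts as cold.
#' @return A list of class `ohc_split` with elements `train`, `validation`,
#'   `test` (interaction tables with a `cold` column) and the `seed`.
#' @export
split_dataset <- function(interactions, physicians = NULL,
                          ratios = c(0.6, 0.2, 0.2), seed = 1L,
                          cold_threshold = 5L) {
  n <- nrow(interactions)
  if (n < 5L) stop("need at least 5 interactions to split")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be three numbers summing to 1")
  it <- as.data.frame(interactions)
  if (!is.null(physicians)) {
    counts <- vapply(physicians, `[[`, integer(1L), "reply_count")
    names(counts) <- vapply(physicians, `[[`, character(1L), "physician_id")
    it$cold <- unname(counts[it$physician_id] < cold_threshold)
  } else it$cold <- FALSE
  perm <- with_seed(seed, sample.int(n))
  n_train <- round(ratios[1L] * n)
  n_val <- round(ratios[2L] * n)
  if (n_train + n_val >= n) n_val <- max(0L, n - n_train - 1L)
  idx <- list(train = perm[seq_len(n_train)],
              validation = perm[n_train + seq_len(n_val)],
              test = perm[(n_train + n_val + 1L):n])
  out <- lapply(idx, function(i) {
    d <- it[i, , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  structure(c(out, list(seed = as.integer(seed),
                        cold_threshold = as.integer(cold_threshold))),
            class = "ohc_split")
}

#' Assign physicians to head/middle/tail popularity tiers
#'
#' Physicians are ordered by reply count (descending) with ties broken by
#' id (ascending); the top 10% form the head tier, the next 40% the middle
#' tier and the remaining 50% the tail. Tier sizes use largest-remainder
#' rounding so they always sum to the number of physicians.
#'
#' @param physicians named list of `physician_profile` records (>= 10).
#' @return A named character vector physician_id -> tier of class
#'   `tier_assignment`.
#' @export
assign_tiers <- function(physicians) {
  n <- length(physicians)
  if (n < 10L) stop("tier assignment needs at least 10 physicians")
  ids <- vapply(physicians, `[[`, character(1L), "physician_id")
  counts <- vapply(physicians, `[[`, integer(1L), "reply_count")
  ord <- order(-counts, ids, method = "radix")
  sizes <- largest_remainder(n, c(head = 0.1, middle = 0.4, tail = 0.5))
  tier <- rep(c("head", "middle", "tail"), times = sizes)
  structure(stats::setNames(tier, ids[ord]), class = "tier_assignment")
}

# largest-remainder apportionment of n into shares p (sums to n exactly);
# remainder ties broken in the order of p
largest_remainder <- function(n, p) {
  exact <- n * p
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(-(exact - base), seq_along(p))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' Drop outlier replies from physician histories
#'
#' Token-count analogue of the character-length outlier filter applied to
#' raw reply texts: replies shorter than `min_tokens` or longer than
#' `max_tokens` are removed and `reply_count` updated.
#'
#' @param physicians named list of `physician_profile` records.
#' @param min_tokens,max_tokens inclusive token-count bounds.
#' @return The filtered physician list.
#' @export
filter_reply_outliers <- function(physicians, min_tokens = 1L,
                                  max_tokens = 2000L) {
  lapply(physicians, function(p) {
    keep <- vapply(p$reply_history, function(r) {
      k <- length(r$tokens); k >= min_tokens && k <= max_tokens
    }, logical(1L))
    physician_profile(p$physician_id, p$title_rank, p$hospital_tier,
                      p$specialty_id, p$reply_history[keep])
  })
}

# run code under a local, restorable RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a sub-seed from a master seed for an independent random stream;
# kept below 2^31 by construction
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483629L
}
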