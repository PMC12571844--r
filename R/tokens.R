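#' @title Field serialization and length policy
#' @description Structured fields (profile, tags, credentials) enter the
#'   encoders as deterministic `field=value` token sequences in a fixed
#'   field order; free-text fields are padded or truncated to configured
#'   lengths with right padding.
#' @name tokens
NULL

# decade bucketing keeps the age vocabulary small and unseen ages meaningful
age_token <- function(age) {
  if (is.null(age) || length(age) == 0L || is.na(age)) return("age=Unknown")
  paste0("age=", (as.integer(age) %/% 10L) * 10L, "s")
}

#' Serialize a query's profile to tokens
#'
#' Fixed order: age (decade-bucketed), gender, region, disease, then sorted
#' history flags. Missing categories appear as `field=Unknown`.
#'
#' @param query a `patient_query`.
#' @return Character token vector.
#' @export
profile_tokens <- function(query) {
  p <- query$profile
  c(age_token(p$age),
    paste0("gender=", p$gender),
    paste0("region=", p$region),
    paste0("disease=", p$disease),
    if (length(p$history_flags))
      paste0("hx=", sort(p$history_flags)))
}

#' Serialize a query's semantic tags to tokens
#'
#' Each (major, minor) tag yields a `major=` and a `minor=` token; tags are
#' emitted in (major, minor) sorted order for determinism.
#'
#' @param query a `patient_query`.
#' @return Character token vector (empty if the query has no tags).
#' @export
tag_tokens <- function(query) {
  tg <- query$tags
  if (!nrow(tg)) return(character())
  ord <- order(tg[, 1L], tg[, 2L])
  tg <- tg[ord, , drop = FALSE]
  as.vector(rbind(paste0("major=", tg[, 1L]),
                  paste0("minor=", tg[, 1L], ".", tg[, 2L])))
}

#' Serialize physician credentials to tokens
#'
#' Fixed order: professional title rank, hospital tier, specialty.
#'
#' @param physician a `physician_profile`.
#' @return Character token vector.
#' @export
credential_tokens <- function(physician) {
  c(paste0("title=", physician$title_rank),
    paste0("tier=", physician$hospital_tier),
    paste0("spec=", physician$specialty_id))
}

#' Apply the length policy to a token id sequence
#'
#' Truncates to `len` and right-pads with the pad id. An empty input is
#' replaced by a single unknown token so every field stays encodable.
#'
#' @param ids integer id vector.
#' @param len target length.
#' @param pad_id,unk_id reserved ids (defaults 0 and 1).
#' @return Integer vector of length `len`.
#' @export
pad_ids <- function(ids, len, pad_id = 0L, unk_id = 1L) {
  ids <- as.integer(ids)
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0L) ids <- unk_id
  if (length(ids) >= len) return(ids[seq_len(len)])
  c(ids, rep(pad_id, len - length(ids)))
}

# Stack a list of token vectors into a B x L id matrix under the length
# policy. Used by the batched engine; one vocabulary lookup for the whole
# batch.
id_matrix <- function(token_list, vocab, len) {
  B <- length(token_list)
  lens <- lengths(token_list)
  ids <- vocab_ids(vocab, unlist(token_list, use.names = FALSE))
  m <- matrix(vocab$pad_id, nrow = B, ncol = len)
  keep <- pmin(lens, len)
  row_idx <- rep.int(seq_len(B), keep)
  col_idx <- sequence(keep)
  src <- rep.int(c(0L, cumsum(lens))[seq_len(B)], keep) + col_idx
  m[cbind(row_idx, col_idx)] <- ids[src]
  if (any(lens == 0L)) m[lens == 0L, 1L] <- vocab$unk_id
  m
}

# The four patient-side fields of a query as token vectors, honouring an
# ablation specification (disabled fields become the learned null token).
query_field_tokens <- function(query, fields = c("title", "content",
                                                 "tags", "profile")) {
  list(
    title = if ("title" %in% fields) query$title_tokens else "<null>",
    content = if ("content" %in% fields) query$content_tokens else "<null>",
    tags = if ("tags" %in% fields) tag_tokens(query) else "<null>",
    profile = if ("profile" %in% fields) profile_tokens(query) else "<null>")
}
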