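normalize_text <- function(text) {
  x <- stringr::str_remove_all(text, "https?://\\S+")
  x <- stringr::str_to_lower(x)
  x <- stringr::str_squish(x)
  x
}

#' Collapse duplicate texts to their earliest post
#'
#' Micro-blog streams collected by keyword are highly redundant: most posts
#' are verbatim copies of a much smaller set of unique texts. This collapses
#' posts whose normalized text (lowercased, URLs stripped, whitespace
#' squeezed) is identical, keeping as canonical the earliest post by day and
#' then by position in the stream.
#'
#' @param stream A [pulse_stream].
#' @return A list with `unique` (the deduplicated [pulse_stream]) and
#'   `dup_map`, a tibble with columns `post_id` and `canonical_id` mapping
#'   each removed copy to the post it duplicates. Counts are conserved:
#'   `nrow(unique$posts) + nrow(dup_map)` equals the input post count.
#' @export
#' @examples
#' d <- dedup_texts(small_fixture()$stream)
#' nrow(d$dup_map)
dedup_texts <- function(stream) {
  if (nrow(stream$posts) == 0) abort("dedup_texts: empty stream")
  posts <- stream$posts |>
    mutate(.norm = normalize_text(.data$text), .pos = dplyr::row_number()) |>
    arrange(.data$.norm, .data$day, .data$.pos)
  canon <- posts |>
    group_by(.data$.norm) |>
    mutate(canonical_id = dplyr::first(.data$post_id)) |>
    ungroup()
  dup_map <- canon |>
    filter(.data$post_id != .data$canonical_id) |>
    arrange(.data$.pos) |>
    select("post_id", "canonical_id")
  keep_ids <- canon$post_id[canon$post_id == canon$canonical_id]
  unique_stream <- stream_keep_posts(stream, stream$posts$post_id %in% keep_ids)
  list(unique = unique_stream, dup_map = dup_map)
}

#' Partition a stream into original posts and retweets
#'
#' Retweets carry no new content; they are analysed separately, purely as
#' user interaction (audience). A post is a retweet iff `retweet_of` is set.
#' Retweets pointing at posts outside the stream are kept and flagged
#' `dangling` (a message reports how many), never dropped.
#'
#' @param stream A [pulse_stream].
#' @return A list with `originals` and `retweets`, both [pulse_stream]s over
#'   the same user table and window. The retweet stream's posts gain a
#'   logical `dangling` column.
#' @export
split_retweets <- function(stream) {
  is_rt <- !is.na(stream$posts$retweet_of)
  originals <- stream_keep_posts(stream, !is_rt)
  retweets <- stream_keep_posts(stream, is_rt)
  dangling <- !retweets$posts$retweet_of %in% stream$posts$post_id
  retweets$posts$dangling <- dangling
  if (any(dangling)) {
    inform(paste0(sum(dangling), " retweet(s) point outside the stream (kept, flagged)"))
  }
  list(originals = originals, retweets = retweets)
}

#' Keep posts matching a keyword list
#'
#' Mirrors keyword-based stream collection: a post is kept when its token
#' sequence contains any single-word keyword, or any multiword keyword as a
#' contiguous run of tokens (e.g. the bigram "skin cancer").
#'
#' @param stream A [pulse_stream].
#' @param keywords Character vector of lowercase keywords; entries may
#'   contain spaces for multiword matches.
#' @return The filtered [pulse_stream].
#' @export
keyword_filter <- function(stream, keywords) {
  if (length(keywords) == 0) abort("keyword_filter: keywords must be non-empty")
  keywords <- stringr::str_to_lower(keywords)
  single <- keywords[!stringr::str_detect(keywords, " ")]
  multi <- stringr::str_split(keywords[stringr::str_detect(keywords, " ")], " ")
  hit <- map_lgl(seq_len(nrow(stream$posts)), function(i) {
    toks <- tokenize(stream$posts$text[i])
    if (any(toks %in% single)) return(TRUE)
    for (kw in multi) {
      k <- length(kw)
      if (length(toks) >= k) {
        for (j in seq_len(length(toks) - k + 1)) {
          if (all(toks[j:(j + k - 1)] == kw)) return(TRUE)
        }
      }
    }
    FALSE
  })
  stream_keep_posts(stream, hit)
}

#' Default collection keywords
#'
#' The cancer-surveillance keyword set used throughout the examples:
#' conditions, treatments and clinical observations.
#'
#' @return Character vector of lowercase keywords.
#' @export
default_keywords <- function() {
  c(
    "cancer", "tumor", "carcinoma", "leukemia", "lymphoma", "metastasis",
    "sarcoma", "skin cancer", "melanoma",
    "chemotherapy", "homeopathy",
    "uv", "cholesterol", "ldl", "mri"
  )
}
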