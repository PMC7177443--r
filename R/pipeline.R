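#' Run the full surveillance analysis over a stream
#'
#' The reference end-to-end pipeline: split retweets from originals, build
#' user facts on the raw originals (metrics need every authored post),
#' filter out low-quality users, collapse duplicate texts, detect event and
#' topic term groups on the unique originals, and aggregate the report
#' tables.
#'
#' @param stream A [pulse_stream].
#' @param domain_lm Domain language model; defaults to the packaged
#'   synthetic lexicon.
#' @param profile_model Optional [train_profile_classifier()] model for the
#'   profile dimension.
#' @param quality [quality_thresholds()].
#' @param thresholds [event_thresholds()].
#' @param seed Integer seed for term clustering.
#' @param min_total Minimum total occurrences for a term to be scored.
#' @param unigram_whitelist Unigrams treated as standalone terms.
#' @return A list:
#' \describe{
#'   \item{user_facts}{[build_user_facts()] tibble with quality bands.}
#'   \item{removed_fraction}{Fraction of posts rejected by user filtering.}
#'   \item{dup_map}{Duplicate-to-canonical post map.}
#'   \item{unique_fraction}{Fraction of original posts with unique text.}
#'   \item{terms}{Scored and classified term statistics.}
#'   \item{groups}{Event/topic term groups.}
#'   \item{assignments}{Group-to-post assignments.}
#'   \item{coverage}{Event/topic/overlap coverage fractions.}
#'   \item{modularity}{Modularity of the event and topic partitions.}
#'   \item{reports}{[group_report()] rows for every group.}
#'   \item{audience}{[audience_profile_histogram()] rows.}
#'   \item{screen}{[controversial_screen()] flags.}
#'   \item{originals, retweets}{The filtered, deduplicated originals stream
#'     and the filtered retweet stream.}
#' }
#' @export
#' @examples
#' fx <- small_fixture()
#' res <- surveil_stream(fx$stream, seed = 1L)
#' res$coverage
surveil_stream <- function(stream,
                           domain_lm = default_domain_lexicon(),
                           profile_model = NULL,
                           quality = quality_thresholds(),
                           thresholds = event_thresholds(),
                           seed = 1L,
                           min_total = 5L,
                           unigram_whitelist = character()) {
  facts <- build_user_facts(stream, domain_lm, profile_model, th = quality)
  kept <- filter_stream(stream, facts)
  removed_fraction <- attr(kept, "removed_fraction")

  parts <- split_retweets(kept)
  dd <- dedup_texts(parts$originals)
  originals <- dd$unique

  det <- detect_term_groups(originals, th = thresholds, seed = seed,
                            min_total = min_total,
                            unigram_whitelist = unigram_whitelist)
  reports <- NULL
  audience <- NULL
  screen <- NULL
  if (nrow(det$assignments) > 0) {
    reports <- group_report(det$groups, det$assignments, originals,
                            parts$retweets, facts)
    audience <- audience_profile_histogram(det$groups, det$assignments,
                                           originals, parts$retweets, facts)
    screen <- controversial_screen(reports)
  }

  list(
    user_facts = facts,
    removed_fraction = removed_fraction,
    dup_map = dd$dup_map,
    unique_fraction = nrow(originals$posts) /
      (nrow(originals$posts) + nrow(dd$dup_map)),
    terms = det$terms,
    groups = det$groups,
    assignments = det$assignments,
    coverage = det$coverage,
    modularity = det$modularity,
    reports = reports,
    audience = audience,
    screen = screen,
    originals = originals,
    retweets = parts$retweets
  )
}
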