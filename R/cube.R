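#' User-quality thresholds
#'
#' Bands for the user-quality dimension. A user is *filtered* when prolific
#' and lexically repetitive (bot/spammer signature: many posts, Yule's I
#' below 30) or prolific and off-domain (coherence below 0.5e-4). Users
#' within a multiplicative margin of either boundary are marked *inspect*
#' for manual review; everyone else is *good*.
#'
#' @param bot_max_yule Yule's I below which a prolific account is considered
#'   automated (default 30).
#' @param bot_min_posts Minimum post count for the bot rule (default 100).
#' @param offdomain_max_coherence Coherence below which a prolific account
#'   is considered off-domain (default 0.5e-4).
#' @param offdomain_min_posts Minimum post count for the off-domain rule.
#' @param inspect_margin Multiplicative band half-width around each boundary
#'   (default 0.2 = +/-20%).
#' @return A list of class `quality_thresholds`.
#' @export
quality_thresholds <- function(bot_max_yule = 30, bot_min_posts = 100L,
                               offdomain_max_coherence = 0.5e-4,
                               offdomain_min_posts = 100L,
                               inspect_margin = 0.2) {
  stopifnot(bot_max_yule > 0, bot_min_posts > 0,
            offdomain_max_coherence > 0, offdomain_min_posts > 0,
            inspect_margin >= 0)
  structure(list(bot_max_yule = bot_max_yule,
                 bot_min_posts = as.integer(bot_min_posts),
                 offdomain_max_coherence = offdomain_max_coherence,
                 offdomain_min_posts = as.integer(offdomain_min_posts),
                 inspect_margin = inspect_margin),
            class = "quality_thresholds")
}

#' Assign quality bands to user facts
#'
#' @param facts Tibble with columns `n_posts_in_stream`, `yules_i`,
#'   `coherence` (one row per user; see [build_user_facts()]).
#' @param th A [quality_thresholds()] object.
#' @return Character vector (`"good"`, `"inspect"`, `"filtered"`; `NA` for
#'   users with undefined metrics) aligned with `facts` rows.
#' @export
#' @examples
#' f <- tibble::tibble(n_posts_in_stream = c(963, 2556, 2),
#'                     yules_i = c(29.8, 94.3, 200),
#'                     coherence = c(0.32e-4, 0.21e-4, 3e-4))
#' classify_user_quality(f)
classify_user_quality <- function(facts, th = quality_thresholds()) {
  n <- facts$n_posts_in_stream
  y <- facts$yules_i
  coh <- facts$coherence
  bot <- n >= th$bot_min_posts & y < th$bot_max_yule
  dom <- n >= th$offdomain_min_posts & coh < th$offdomain_max_coherence
  filtered <- bot | dom
  m <- th$inspect_margin
  near_bot <- n >= th$bot_min_posts * (1 - m) & y < th$bot_max_yule * (1 + m)
  near_dom <- n >= th$offdomain_min_posts * (1 - m) &
    coh < th$offdomain_max_coherence * (1 + m)
  band <- ifelse(filtered, "filtered",
                 ifelse(near_bot | near_dom, "inspect", "good"))
  band[is.na(y) | is.na(coh) | is.na(n)] <- NA_character_
  band
}

#' Build the user-fact table
#'
#' One row per account: post count in the stream, pooled-vocabulary Yule's I
#' and domain coherence over the user's *original* posts (retweets carry no
#' authored text), predicted profile, and quality band. Users with no
#' original post get `NA` metrics and a `metrics_defined = FALSE` flag.
#'
#' @param stream A [pulse_stream].
#' @param domain_lm Domain language model (see [read_domain_lexicon()]).
#' @param profile_model Optional [train_profile_classifier()] model; when
#'   `NULL` every profile is `NA`.
#' @param th [quality_thresholds()] for band assignment.
#' @param yule_cap Finite cap replacing the infinite Yule's I of all-distinct
#'   vocabularies in the table (default 10000).
#' @return Tibble: `user_id`, `screen_name`, `n_posts_in_stream`, `yules_i`,
#'   `coherence`, `verified`, `followers`, `profile`, `quality_band`,
#'   `metrics_defined`.
#' @export
build_user_facts <- function(stream, domain_lm, profile_model = NULL,
                             th = quality_thresholds(), yule_cap = 1e4) {
  parts <- split_retweets(stream)
  originals <- parts$originals$posts
  toks <- tokenize_all(originals$text)
  flat <- unlist(toks, use.names = FALSE)
  flat_user <- rep.int(originals$user_id, lengths(toks))
  pooled <- split(flat, flat_user)
  metrics <- tibble(
    user_id = names(pooled),
    yules_i = unname(map_dbl(pooled, function(tk) {
      if (length(tk) == 0) return(NA_real_)
      yules_i(tk, cap = yule_cap)
    })),
    coherence = unname(map_dbl(pooled, function(tk) {
      if (length(tk) == 0) return(NA_real_)
      domain_coherence(build_language_model(tk), domain_lm)
    }))
  )
  n_posts <- count(originals, .data$user_id, name = "n_posts_in_stream")

  facts <- stream$users |>
    left_join(n_posts, by = "user_id") |>
    left_join(metrics, by = "user_id") |>
    mutate(
      n_posts_in_stream = tidyr::replace_na(.data$n_posts_in_stream, 0L),
      metrics_defined = !is.na(.data$yules_i)
    )
  if (!is.null(profile_model)) {
    pred <- predict_profile(profile_model, facts$description)
    facts$profile <- pred$label
  } else {
    facts$profile <- NA_character_
  }
  facts$quality_band <- classify_user_quality(facts, th)
  facts |>
    select("user_id", "screen_name", "n_posts_in_stream", "yules_i",
           "coherence", "verified", "followers", "profile", "quality_band",
           "metrics_defined")
}

#' Remove posts of filtered users
#'
#' Drops every post (originals and retweets) authored by a user in the
#' `filtered` quality band and reports which fraction of the stream that
#' rejects.
#'
#' @param stream A [pulse_stream].
#' @param facts A [build_user_facts()] tibble with `quality_band`.
#' @return The filtered [pulse_stream], with attribute `removed_fraction`.
#' @export
filter_stream <- function(stream, facts) {
  bad_users <- facts$user_id[!is.na(facts$quality_band) &
                               facts$quality_band == "filtered"]
  keep <- !stream$posts$user_id %in% bad_users
  removed <- 1 - mean(keep)
  if (all(!keep)) warn("all users filtered: stream is empty")
  out <- stream_keep_posts(stream, keep)
  attr(out, "removed_fraction") <- removed
  out
}

#' Build the post-fact table
#'
#' @param stream A [pulse_stream].
#' @return Tibble: `post_id`, `user_id`, `day`, `lang`, `is_reply`,
#'   `is_first_person`, `reply_count`, `retweet_count`, `like_count`.
#' @export
build_post_facts <- function(stream) {
  posts <- stream$posts
  toks <- tokenize_all(posts$text)
  posts |>
    mutate(
      is_reply = !is.na(.data$in_reply_to),
      is_first_person = purrr::map2_lgl(toks, .data$lang, is_first_person)
    ) |>
    select("post_id", "user_id", "day", "lang", "is_reply",
           "is_first_person", "reply_count", "retweet_count", "like_count")
}

#' Per-group report table
#'
#' One row per term group with the reporting columns of the surveillance
#' tables: tweet count, average author Yule's I (`avg_yule`), percentage of
#' verified authors (`pct_verified`), mean author activity in the stream
#' (`on_dom`), distinct authors and retweeting users, and the percentage of
#' group posts that are replies or first-person. Author-level metrics
#' average over *distinct* authors, not posts.
#'
#' @param groups Tibble `group_id`, `kind`, `term` (see
#'   [detect_term_groups()]).
#' @param assignments Tibble `group_id`, `post_id` from [assign_posts()].
#' @param originals Originals [pulse_stream] the assignments refer to.
#' @param retweets Retweets [pulse_stream] (for the audience column).
#' @param facts [build_user_facts()] tibble.
#' @return Tibble: `group_id`, `kind`, `label` (most frequent member term),
#'   `n_terms`, `n_tweets`, `avg_yule`, `pct_verified`, `on_dom`,
#'   `n_users_tweeting`, `n_users_retweeting`, `pct_replies`,
#'   `pct_first_person`.
#' @export
group_report <- function(groups, assignments, originals, retweets, facts) {
  if (nrow(assignments) == 0) abort("group_report: no posts assigned")
  pf <- build_post_facts(originals)
  ga <- assignments |>
    inner_join(pf, by = "post_id")
  if (nrow(ga) == 0) abort("group_report: assignments match no original posts")

  author_side <- ga |>
    distinct(.data$group_id, .data$user_id) |>
    inner_join(facts, by = "user_id") |>
    group_by(.data$group_id) |>
    summarise(
      avg_yule = mean(.data$yules_i, na.rm = TRUE),
      pct_verified = 100 * mean(.data$verified),
      on_dom = mean(.data$n_posts_in_stream),
      n_users_tweeting = dplyr::n(),
      .groups = "drop"
    )
  post_side <- ga |>
    group_by(.data$group_id) |>
    summarise(
      n_tweets = dplyr::n_distinct(.data$post_id),
      pct_replies = 100 * mean(.data$is_reply),
      pct_first_person = 100 * mean(.data$is_first_person),
      .groups = "drop"
    )
  rt <- retweets$posts |>
    select(rt_user = "user_id", post_id = "retweet_of") |>
    inner_join(assignments, by = "post_id") |>
    group_by(.data$group_id) |>
    summarise(n_users_retweeting = dplyr::n_distinct(.data$rt_user),
              .groups = "drop")
  labels <- groups |>
    group_by(.data$group_id) |>
    summarise(kind = dplyr::first(.data$kind),
              n_terms = dplyr::n(),
              label = dplyr::first(sort(.data$term)),
              .groups = "drop")

  post_side |>
    inner_join(author_side, by = "group_id") |>
    left_join(rt, by = "group_id") |>
    mutate(n_users_retweeting = tidyr::replace_na(.data$n_users_retweeting, 0L)) |>
    inner_join(labels, by = "group_id") |>
    select("group_id", "kind", "label", "n_terms", "n_tweets", "avg_yule",
           "pct_verified", "on_dom", "n_users_tweeting",
           "n_users_retweeting", "pct_replies", "pct_first_person") |>
    arrange(desc(.data$n_tweets))
}

#' Author/audience profile histogram for term groups
#'
#' Authors are the distinct posters of a group's original posts; the
#' audience is the distinct users retweeting those posts. A user may appear
#' in both roles. Counts are broken down by predicted profile.
#'
#' @inheritParams group_report
#' @return Tibble: `group_id`, `profile`, `n_authors`, `n_audience`.
#' @export
audience_profile_histogram <- function(groups, assignments, originals,
                                       retweets, facts) {
  prof <- facts |> select("user_id", "profile")
  authors <- assignments |>
    inner_join(originals$posts |> select("post_id", "user_id"), by = "post_id") |>
    distinct(.data$group_id, .data$user_id) |>
    inner_join(prof, by = "user_id") |>
    count(.data$group_id, .data$profile, name = "n_authors")
  audience <- retweets$posts |>
    select(rt_user = "user_id", post_id = "retweet_of") |>
    inner_join(assignments, by = "post_id") |>
    distinct(.data$group_id, rt_user = .data$rt_user) |>
    inner_join(prof, by = c(rt_user = "user_id")) |>
    count(.data$group_id, .data$profile, name = "n_audience")
  full_join(authors, audience, by = c("group_id", "profile")) |>
    mutate(n_authors = tidyr::replace_na(.data$n_authors, 0L),
           n_audience = tidyr::replace_na(.data$n_audience, 0L)) |>
    arrange(.data$group_id, .data$profile)
}

#' Screen report rows for monitoring candidates
#'
#' Flags groups whose parameters match known risk signatures:
#' `spam_like` — very low author diversity with hyper-active authors
#' (avg Yule's I < 30 and mean on-stream activity > 100);
#' `active_discussion` — reply share at or above 40%;
#' `unverified_viral` — retweeted audience with not a single verified
#' author. All thresholds configurable.
#'
#' @param reports A [group_report()] tibble.
#' @param spam_max_yule,spam_min_ondom,discussion_min_replies Thresholds.
#' @return The rows of `reports` with at least one flag, with logical
#'   columns `spam_like`, `active_discussion`, `unverified_viral` added.
#' @export
controversial_screen <- function(reports, spam_max_yule = 30,
                                 spam_min_ondom = 100,
                                 discussion_min_replies = 40) {
  out <- reports |>
    mutate(
      spam_like = .data$avg_yule < spam_max_yule & .data$on_dom > spam_min_ondom,
      active_discussion = .data$pct_replies >= discussion_min_replies,
      unverified_viral = .data$pct_verified == 0 & .data$n_users_retweeting > 0
    )
  out |> filter(.data$spam_like | .data$active_discussion | .data$unverified_viral)
}
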