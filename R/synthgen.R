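#' Configuration for the synthetic-stream generator
#'
#' Describes a ground-truthed surveillance stream: a day-resolution window,
#' users of several archetypes, planted short bursts (events), sustained
#' multi-term themes (topics), rare noise bigrams, retweet/reply wiring,
#' first-person markers in two languages, and verbatim text duplication.
#' The default configuration is the package's reference study condition:
#' a 90-day window, 50 users, 10 planted events, 20 topics and 100 noise
#' bigrams, with 60% of posts being copies.
#'
#' Term layouts and volumes are laid out deterministically here; all
#' randomness is drawn inside [generate_stream()] under `seed`.
#'
#' @param seed Integer seed (mandatory; all generation randomness derives
#'   from it).
#' @param n_days Window length in days.
#' @param start_day First day of the window.
#' @param users Named integer vector: users per archetype among
#'   `lay`, `organization`, `journalist`, `bot`, `spammer`, `offdomain`,
#'   `concerned`, `pseudo`.
#' @param n_events,n_topics,n_noise Number of planted event groups (2
#'   bigrams each), topic groups ([topic_terms_each] bigrams each) and rare
#'   noise bigrams.
#' @param event_volumes,event_widths Recycled across events: total posts in
#'   the burst and its width in days. Every event post contains all of its
#'   group's bigrams, so each event term's daily peak is at least
#'   `min(event_volumes) * min-burst-day-share`.
#' @param topic_totals Recycled across topics: posts per topic group. Each
#'   topic post carries two terms sampled from the group (one term when the
#'   group has a single term).
#' @param topic_terms_each Bigrams per topic group (default 3).
#' @param topic_cross_prob Probability that a topic post borrows one term
#'   from a different topic group (weak inter-group ties).
#' @param noise_totals Recycled across noise bigrams: total occurrences.
#' @param bot_posts,spammer_posts,offdomain_posts Posts per user of those
#'   archetypes.
#' @param baseline_posts Chatter posts per engaged (non-automated,
#'   in-domain) user.
#' @param retweet_rate Retweets as a fraction of original posts.
#' @param reply_prob Probability that an engaged post replies to an earlier
#'   post.
#' @param first_person_prob Named vector of per-archetype probabilities of a
#'   first-person marker (archetypes not named get 0).
#' @param duplicate_rate Fraction of the final post stream that is a
#'   verbatim copy of another post (default 0.6: keyword streams are
#'   dominated by copies).
#' @param lang_mix Named probabilities for user languages `en`/`es`.
#' @param background_vocab_size Size of the out-of-domain background
#'   vocabulary.
#' @param domain_mix Fraction of filler tokens drawn from the medical
#'   lexicon (vs background) for in-domain users.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_days = 90L,
                         start_day = as.Date("2019-06-01"),
                         users = c(lay = 30L, organization = 4L,
                                   journalist = 4L, bot = 3L, spammer = 2L,
                                   offdomain = 4L, concerned = 2L,
                                   pseudo = 1L),
                         n_events = 10L,
                         n_topics = 20L,
                         n_noise = 100L,
                         event_volumes = c(80L, 100L, 120L, 140L),
                         event_widths = c(1L, 2L, 3L),
                         topic_totals = c(120L, 150L, 180L, 210L),
                         topic_terms_each = 3L,
                         topic_cross_prob = 0.05,
                         noise_totals = 3:10,
                         bot_posts = 150L,
                         spammer_posts = 120L,
                         offdomain_posts = 120L,
                         baseline_posts = 3L,
                         retweet_rate = 0.4,
                         reply_prob = 0.1,
                         first_person_prob = c(lay = 0.2, concerned = 0.5,
                                               pseudo = 0.1),
                         duplicate_rate = 0.6,
                         lang_mix = c(en = 0.7, es = 0.3),
                         background_vocab_size = 1500L,
                         domain_mix = 0.35) {
  if (missing(seed)) abort("synth_config: seed is mandatory")
  stopifnot(n_days >= 2, all(users >= 0),
            duplicate_rate >= 0, duplicate_rate < 1,
            retweet_rate >= 0, reply_prob >= 0, reply_prob <= 1,
            topic_cross_prob >= 0, topic_cross_prob <= 1,
            topic_terms_each >= 1,
            domain_mix >= 0, domain_mix <= 1)
  known <- c("lay", "organization", "journalist", "bot", "spammer",
             "offdomain", "concerned", "pseudo")
  bad <- setdiff(names(users), known)
  if (length(bad) > 0) {
    abort(paste0("unknown archetype(s): ", paste(bad, collapse = ", ")))
  }

  events <- NULL
  if (n_events > 0) {
    peak_days <- round(seq(8, n_days - 8, length.out = n_events))
    events <- tibble(
      group_id = sprintf("ev%02d", seq_len(n_events)),
      terms = map(seq_len(n_events), function(i) {
        c(sprintf("ev%02da ev%02db", i, i), sprintf("ev%02dc ev%02dd", i, i))
      }),
      peak_day = peak_days,
      width = rep_len(as.integer(event_widths), n_events),
      volume = rep_len(as.integer(event_volumes), n_events)
    )
    stopifnot(all(events$width <= 10))
  }
  topics <- NULL
  if (n_topics > 0) {
    topics <- tibble(
      group_id = sprintf("tp%02d", seq_len(n_topics)),
      terms = map(seq_len(n_topics), function(i) {
        sprintf("tp%02dx%d tp%02dy%d", i, seq_len(topic_terms_each), i,
                seq_len(topic_terms_each))
      }),
      total = rep_len(as.integer(topic_totals), n_topics)
    )
  }
  noise <- NULL
  if (n_noise > 0) {
    noise <- tibble(
      term = sprintf("nz%03da nz%03db", seq_len(n_noise), seq_len(n_noise)),
      total = rep_len(as.integer(noise_totals), n_noise)
    )
  }

  structure(
    list(seed = as.integer(seed), n_days = as.integer(n_days),
         start_day = as.Date(start_day), users = users,
         events = events, topics = topics, noise = noise,
         topic_cross_prob = topic_cross_prob,
         bot_posts = as.integer(bot_posts),
         spammer_posts = as.integer(spammer_posts),
         offdomain_posts = as.integer(offdomain_posts),
         baseline_posts = as.integer(baseline_posts),
         retweet_rate = retweet_rate, reply_prob = reply_prob,
         first_person_prob = first_person_prob,
         duplicate_rate = duplicate_rate, lang_mix = lang_mix,
         background_vocab_size = as.integer(background_vocab_size),
         domain_mix = domain_mix),
    class = "synth_config"
  )
}

#' @method print synth_config
#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> seed ", x$seed, ": ", x$n_days, " days, ",
      sum(x$users), " users (",
      paste(names(x$users), x$users, sep = "=", collapse = ", "), "), ",
      if (is.null(x$events)) 0 else nrow(x$events), " events, ",
      if (is.null(x$topics)) 0 else nrow(x$topics), " topics, ",
      if (is.null(x$noise)) 0 else nrow(x$noise), " noise terms\n", sep = "")
  invisible(x)
}

archetype_profile_map <- c(
  lay = "others", organization = "h.services", journalist = "journalist",
  bot = "p.services", spammer = "pseudo", offdomain = "others",
  concerned = "concerned", pseudo = "pseudo"
)

# archetypes whose posts carry in-domain content and engage with terms
engaged_archetypes <- c("lay", "organization", "journalist", "concerned",
                        "pseudo")

# sample() that never falls into the length-1 integer trap
sample_vec <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

make_filler <- function(n, domain_vocab, background_vocab, domain_mix) {
  from_domain <- runif(n) < domain_mix
  out <- character(n)
  if (any(from_domain)) {
    out[from_domain] <- sample_vec(domain_vocab, sum(from_domain))
  }
  if (any(!from_domain)) {
    out[!from_domain] <- sample_vec(background_vocab, sum(!from_domain))
  }
  out
}

# each text: 2 filler words / planted terms / 2 filler words; a "|"
# placeholder between planted terms becomes one filler word, so planted
# bigrams never touch each other (no spurious bridging bigrams)
compose_texts <- function(term_strings, domain_vocab, background_vocab,
                          domain_mix) {
  n <- length(term_strings)
  f <- matrix(make_filler(4 * n, domain_vocab, background_vocab, domain_mix),
              nrow = n)
  pre <- paste(f[, 1], f[, 2])
  mid <- paste(f[, 3], f[, 4])
  out <- ifelse(nzchar(term_strings),
                paste(pre, term_strings, mid),
                paste(pre, mid))
  stringr::str_replace_all(out, stringr::fixed("|"), function(m) {
    make_filler(length(m), domain_vocab, background_vocab, domain_mix)
  })
}

# n texts of `len` words drawn with replacement from vocab
random_texts <- function(n, len, vocab) {
  m <- matrix(sample_vec(vocab, n * len), nrow = n)
  do.call(paste, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate a ground-truthed synthetic stream
#'
#' Emits a [pulse_stream] emulating a keyword-collected surveillance stream:
#' events appear as near-Gaussian day bursts truncated to their width (every
#' event post carries all of the event's bigrams), topics as uniform daily
#' rates over co-occurring term sets, bots as prolific accounts with a tiny
#' vocabulary (Yule's I well under 30), spammers as accounts repeating a
#' handful of promotional texts, off-domain users as prolific accounts
#' drawing only from a background vocabulary (coherence 0 against the
#' medical lexicon). Account descriptions are sampled from the per-profile
#' seed vocabulary; retweets and replies are wired to existing post ids;
#' duplicate posts are verbatim copies on the same or a later day. Fully
#' reproducible under `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list: `stream` (a [pulse_stream]) and `truth`, itself a list of
#'   tibbles `terms` (`term`, `class`, `group_id`), `users` (`user_id`,
#'   `archetype`, `profile`, `intended_band`) and `posts` (`post_id`,
#'   `kind`, `group_id`, `first_person`, `duplicate_of`).
#' @export
#' @examples
#' fx <- small_fixture()
#' fx$stream
#' head(fx$truth$terms)
generate_stream <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_days <- config$n_days
  days <- config$start_day + 0:(n_days - 1)
  lex <- default_domain_lexicon()
  domain_vocab <- names(lex)
  background_vocab <- sprintf("bg%04d", seq_len(config$background_vocab_size))
  seed_lex <- profile_seed_lexicon()

  ## ---- users ----
  counts <- config$users[config$users > 0]
  if (length(counts) == 0) abort("config implies zero users")
  archetype <- rep(names(counts), counts)
  n_users <- length(archetype)
  users <- tibble(
    user_id = sprintf("u%03d", seq_len(n_users)),
    archetype = archetype,
    screen_name = paste0(archetype, "_", seq_len(n_users)),
    profile = unname(archetype_profile_map[archetype]),
    lang = sample_vec(names(config$lang_mix), n_users,
                      prob = config$lang_mix),
    verified = runif(n_users) <
      ifelse(archetype %in% c("organization", "journalist"), 0.6, 0.02),
    followers = as.integer(round(exp(rnorm(n_users, 5, 1.5))))
  )
  users$description <- map_chr(users$profile, function(p) {
    words <- seed_lex[[p]]
    paste(sample(words, min(4, length(words))), collapse = " ")
  })
  users$intended_band <- ifelse(
    users$archetype %in% c("bot", "spammer", "offdomain"), "filtered", "good"
  )
  engaged <- users$user_id[users$archetype %in% engaged_archetypes]
  if (length(engaged) == 0 &&
      !(is.null(config$events) && is.null(config$topics) &&
          is.null(config$noise))) {
    abort("config plants terms but has no engaged users to author them")
  }

  ## ---- planned original posts (planted terms + chatter) ----
  plans <- list()
  if (!is.null(config$events)) {
    plans$event <- bind_rows(pmap(config$events, function(group_id, terms,
                                                          peak_day, width,
                                                          volume) {
      offsets <- seq_len(width) - 1L - (width - 1L) %/% 2L
      burst_days <- pmin(pmax(peak_day + offsets, 1L), n_days)
      w <- stats::dnorm(offsets, 0, max(width / 2, 0.6))
      tibble(
        kind = "event", group_id = group_id,
        day_idx = sample_vec(burst_days, volume, prob = w),
        term_string = paste(terms, collapse = " | "),
        user_id = sample_vec(engaged, volume)
      )
    }))
  }
  if (!is.null(config$topics)) {
    all_topic_terms <- unlist(config$topics$terms)
    plans$topic <- bind_rows(pmap(config$topics, function(group_id, terms,
                                                          total) {
      k <- min(2L, length(terms))
      own <- map_chr(seq_len(total), function(i) {
        paste(sample(terms, k), collapse = " | ")
      })
      cross <- runif(total) < config$topic_cross_prob
      if (any(cross) && length(all_topic_terms) > length(terms)) {
        foreign <- setdiff(all_topic_terms, terms)
        own[cross] <- paste(sample_vec(terms, sum(cross)),
                            sample_vec(foreign, sum(cross)), sep = " | ")
      }
      tibble(
        kind = "topic", group_id = group_id,
        day_idx = sample.int(n_days, total, replace = TRUE),
        term_string = own,
        user_id = sample_vec(engaged, total)
      )
    }))
  }
  if (!is.null(config$noise)) {
    plans$noise <- bind_rows(pmap(config$noise, function(term, total) {
      tibble(
        kind = "noise", group_id = NA_character_,
        day_idx = sample.int(n_days, total, replace = TRUE),
        term_string = term,
        user_id = sample_vec(engaged, total)
      )
    }))
  }
  if (config$baseline_posts > 0 && length(engaged) > 0) {
    n_base <- config$baseline_posts * length(engaged)
    plans$base <- tibble(
      kind = "base", group_id = NA_character_,
      day_idx = sample.int(n_days, n_base, replace = TRUE),
      term_string = "",
      user_id = rep(engaged, each = config$baseline_posts)
    )
  }
  planned <- bind_rows(plans)
  if (nrow(planned) > 0) {
    planned$text <- compose_texts(planned$term_string, domain_vocab,
                                  background_vocab, config$domain_mix)
    planned$term_string <- NULL
  }

  ## ---- automated / off-domain users ----
  extra <- list()
  for (i in which(users$archetype == "bot")) {
    vocab_b <- sample(domain_vocab, 8)
    n <- config$bot_posts
    extra[[length(extra) + 1]] <- tibble(
      kind = "bot", group_id = NA_character_,
      day_idx = sample.int(n_days, n, replace = TRUE),
      user_id = users$user_id[i],
      text = random_texts(n, 6, vocab_b)
    )
  }
  for (i in which(users$archetype == "spammer")) {
    promo <- map_chr(1:3, function(j) {
      paste(c(sample(seed_lex$pseudo, 3), sample(domain_vocab, 2)),
            collapse = " ")
    })
    extra[[length(extra) + 1]] <- tibble(
      kind = "spammer", group_id = NA_character_,
      day_idx = sample.int(n_days, config$spammer_posts, replace = TRUE),
      user_id = users$user_id[i],
      text = sample_vec(promo, config$spammer_posts)
    )
  }
  for (i in which(users$archetype == "offdomain")) {
    extra[[length(extra) + 1]] <- tibble(
      kind = "offdomain", group_id = NA_character_,
      day_idx = sample.int(n_days, config$offdomain_posts, replace = TRUE),
      user_id = users$user_id[i],
      text = random_texts(config$offdomain_posts, 6, background_vocab)
    )
  }
  extra <- bind_rows(extra)

  originals <- bind_rows(planned, extra)
  if (nrow(originals) == 0) abort("config implies zero posts")

  ## ---- language and first-person markers ----
  originals <- originals |>
    left_join(users |> select("user_id", lang = "lang", "archetype"),
              by = "user_id")
  fp_prob <- config$first_person_prob[originals$archetype]
  fp_prob[is.na(fp_prob)] <- 0
  fp <- runif(nrow(originals)) < fp_prob
  marker <- ifelse(originals$lang == "es", "estoy", "i'm")
  originals$text[fp] <- paste(marker[fp], originals$text[fp])
  originals$first_person <- fp

  ## ---- verbatim duplicates ----
  n_orig <- nrow(originals)
  originals$orig_key <- seq_len(n_orig)
  originals$dup_key <- NA_integer_
  if (config$duplicate_rate > 0) {
    n_dup <- round(n_orig * config$duplicate_rate /
                     (1 - config$duplicate_rate))
    src <- sample.int(n_orig, n_dup, replace = TRUE)
    copiers <- if (length(engaged) > 0) engaged else users$user_id
    dups <- originals[src, ] |>
      mutate(
        kind = "duplicate",
        user_id = sample_vec(copiers, n_dup),
        day_idx = pmin(.data$day_idx + sample(0:7, n_dup, replace = TRUE),
                       n_days),
        orig_key = NA_integer_,
        dup_key = src
      )
    originals <- bind_rows(originals, dups)
  }

  ## ---- ids, days, replies ----
  originals <- originals |>
    arrange(.data$day_idx) |>
    mutate(
      post_id = sprintf("p%06d", dplyr::row_number()),
      day = days[.data$day_idx],
      retweet_of = NA_character_,
      in_reply_to = NA_character_
    )
  originals$duplicate_of <-
    originals$post_id[match(originals$dup_key, originals$orig_key,
                            incomparables = NA)]

  do_reply <- originals$archetype %in% engaged_archetypes &
    runif(nrow(originals)) < config$reply_prob
  do_reply[1] <- FALSE
  idx <- which(do_reply)
  if (length(idx) > 0) {
    originals$in_reply_to[idx] <- vapply(idx, function(i) {
      originals$post_id[sample.int(i - 1L, 1L)]
    }, character(1))
  }

  ## ---- retweets ----
  rts <- NULL
  n_rt <- round(config$retweet_rate * n_orig)
  if (n_rt > 0) {
    weight <- ifelse(originals$kind %in% c("event", "topic"), 3, 1)
    tgt <- sample.int(nrow(originals), n_rt, replace = TRUE, prob = weight)
    rt_users <- users$user_id[!users$archetype %in% c("bot", "spammer")]
    sn <- setNames(users$screen_name, users$user_id)
    rt_day_idx <- pmin(originals$day_idx[tgt] +
                         sample(0:5, n_rt, replace = TRUE), n_days)
    rts <- tibble(
      kind = "retweet", group_id = originals$group_id[tgt],
      user_id = sample_vec(rt_users, n_rt),
      text = paste0("rt @", sn[originals$user_id[tgt]], ": ",
                    originals$text[tgt]),
      lang = originals$lang[tgt],
      first_person = FALSE,
      post_id = sprintf("r%06d", seq_len(n_rt)),
      day = days[rt_day_idx],
      retweet_of = originals$post_id[tgt],
      in_reply_to = NA_character_,
      duplicate_of = NA_character_
    )
  }

  post_cols <- c("post_id", "text", "day", "lang", "user_id", "retweet_of",
                 "in_reply_to", "kind", "group_id", "first_person",
                 "duplicate_of")
  all_posts <- bind_rows(originals[post_cols],
                         if (!is.null(rts)) rts[post_cols])

  ## ---- engagement counts ----
  rt_counts <- table(all_posts$retweet_of)
  reply_counts <- table(all_posts$in_reply_to)
  all_posts <- all_posts |>
    mutate(
      retweet_count = tidyr::replace_na(
        as.integer(rt_counts[.data$post_id]), 0L),
      reply_count = tidyr::replace_na(
        as.integer(reply_counts[.data$post_id]), 0L),
      like_count = rpois(dplyr::n(), 2)
    )

  stream <- pulse_stream(
    all_posts |> select("post_id", "text", "day", "lang", "user_id",
                        "retweet_of", "in_reply_to", "reply_count",
                        "retweet_count", "like_count"),
    users |> select("user_id", "screen_name", "description", "verified",
                    "followers"),
    window = c(days[1], days[n_days])
  )

  truth_terms <- bind_rows(
    if (!is.null(config$events)) {
      config$events |>
        select("group_id", "terms") |>
        tidyr::unnest_longer("terms", values_to = "term") |>
        mutate(class = "event")
    },
    if (!is.null(config$topics)) {
      config$topics |>
        select("group_id", "terms") |>
        tidyr::unnest_longer("terms", values_to = "term") |>
        mutate(class = "topic")
    },
    if (!is.null(config$noise)) {
      config$noise |>
        transmute(term = .data$term, class = "noise",
                  group_id = NA_character_)
    }
  ) |> select("term", "class", "group_id")

  truth <- list(
    terms = truth_terms,
    users = users |> select("user_id", "archetype", "profile",
                            "intended_band"),
    posts = all_posts |> select("post_id", "kind", "group_id",
                                "first_person", "duplicate_of")
  )
  list(stream = stream, truth = truth)
}

#' Small deterministic fixture stream
#'
#' A ~200-post, 60-day, 10-user bilingual stream with one planted
#' single-day event (peak 35, guaranteed past the default selection
#' thresholds), two single-bigram topics of 20 posts each, one bot with
#' exactly 100 repetitive posts (filtered at default quality thresholds)
#' and one off-domain user. No text duplication. Used in unit tests and
#' documentation examples.
#'
#' @return As [generate_stream()]: a list with `stream` and `truth`.
#' @export
small_fixture <- function() {
  cfg <- synth_config(
    seed = 20200328L,
    n_days = 60L,
    users = c(lay = 6L, organization = 1L, journalist = 1L, bot = 1L,
              offdomain = 1L),
    n_events = 1L, n_topics = 2L, n_noise = 0L,
    event_volumes = 35L, event_widths = 1L,
    topic_totals = 20L, topic_terms_each = 1L, topic_cross_prob = 0,
    bot_posts = 100L, offdomain_posts = 8L, baseline_posts = 1L,
    retweet_rate = 0.04, reply_prob = 0.15,
    duplicate_rate = 0,
    lang_mix = c(en = 0.6, es = 0.4)
  )
  generate_stream(cfg)
}
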