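test_that("classify_user_quality reproduces the reference band assignments", {
  facts <- tibble::tibble(
    n_posts_in_stream = c(963, 2556, 2, 1010, 3306),
    yules_i = c(29.8, 94.3, 200, 11.2, 42.3),
    coherence = c(0.32e-4, 0.21e-4, 3e-4, 0.31e-4, 0.88e-4)
  )
  bands <- classify_user_quality(facts)
  # prolific + repetitive -> bot rule; prolific + off-domain -> domain rule
  expect_equal(bands[1], "filtered")
  expect_equal(bands[2], "filtered")
  expect_equal(bands[3], "good")
  expect_equal(bands[4], "filtered")
  expect_equal(bands[5], "good")
})

test_that("the inspect band catches users near either boundary", {
  facts <- tibble::tibble(
    n_posts_in_stream = c(90, 150, 150),
    yules_i = c(25, 33, 200),
    coherence = c(3e-4, 3e-4, 0.55e-4)
  )
  bands <- classify_user_quality(facts)
  expect_equal(bands, c("inspect", "inspect", "inspect"))
  # undefined metrics stay unbanded
  na_facts <- tibble::tibble(n_posts_in_stream = 0L, yules_i = NA_real_,
                             coherence = NA_real_)
  expect_true(is.na(classify_user_quality(na_facts)))
})

test_that("build_user_facts pools original posts per user", {
  posts <- make_posts(
    post_id = paste0("p", 1:4),
    text = c("aa aa bb", "cc dd", "irrelevant", "copy"),
    day = rep("2019-06-01", 4),
    user_id = c("u1", "u2", "u3", "u3"),
    retweet_of = c(NA, NA, NA, "p1")
  )
  users <- make_users(c("u1", "u2", "u3", "u4"))
  s <- pulse_stream(posts, users)
  lex <- c(aa = 0.5, cc = 0.5)
  facts <- build_user_facts(s, lex)
  expect_equal(nrow(facts), 4)
  f1 <- facts[facts$user_id == "u1", ]
  expect_equal(f1$yules_i, 4 / 3) # tokens aa aa bb
  expect_equal(f1$coherence, (2 / 3) * 0.5)
  expect_equal(f1$n_posts_in_stream, 1L)
  # u4 never posted; u3's only original counts, the retweet does not
  expect_false(facts$metrics_defined[facts$user_id == "u4"])
  expect_equal(facts$n_posts_in_stream[facts$user_id == "u3"], 1L)
})

test_that("a user with only retweets gets flagged, not scored", {
  posts <- make_posts(
    post_id = c("p1", "p2"),
    text = c("original text", "original text"),
    day = rep("2019-06-01", 2),
    user_id = c("u1", "u2"),
    retweet_of = c(NA, "p1")
  )
  s <- pulse_stream(posts, make_users(c("u1", "u2")))
  facts <- build_user_facts(s, c(original = 1))
  f2 <- facts[facts$user_id == "u2", ]
  expect_false(f2$metrics_defined)
  expect_true(is.na(f2$yules_i))
  expect_equal(f2$n_posts_in_stream, 0L)
})

test_that("filter_stream removes filtered users' posts and reports the fraction", {
  posts <- make_posts(
    post_id = paste0("p", 1:100),
    text = paste("text", 1:100),
    day = rep("2019-06-01", 100),
    user_id = c(rep("bad", 15), rep("ok", 85))
  )
  s <- pulse_stream(posts, make_users(c("bad", "ok")))
  facts <- tibble::tibble(user_id = c("bad", "ok"),
                          quality_band = c("filtered", "good"))
  kept <- filter_stream(s, facts)
  expect_equal(nrow(kept$posts), 85)
  expect_equal(attr(kept, "removed_fraction"), 0.15)
  expect_equal(attr(kept, "removed_fraction") + 85 / 100, 1)

  none <- filter_stream(s, dplyr::mutate(facts, quality_band = "good"))
  expect_equal(none$posts, s$posts)
  expect_equal(attr(none, "removed_fraction"), 0)

  expect_warning(
    all_gone <- filter_stream(s, dplyr::mutate(facts,
                                               quality_band = "filtered")),
    "empty"
  )
  expect_equal(nrow(all_gone$posts), 0)
})

hand_report_fixture <- function() {
  # group term "alpha beta"; authors uA (tokens aa aa bb -> Yule 4/3 across
  # stream) and uB; uB has 8 stream posts, uA has 4 -> on_dom 6
  posts <- make_posts(
    post_id = paste0("p", 1:12),
    text = c(
      "alpha beta one", # p1 uA group
      "alpha beta two", # p2 uA group, reply
      "alpha beta three", # p3 uB group, first person marker below
      paste("chatter", 4:12) # fillers to set stream totals
    ),
    day = rep("2019-06-01", 12),
    lang = "en",
    user_id = c("uA", "uA", "uB", "uA", "uA", rep("uB", 7)),
    in_reply_to = c(NA, "p1", rep(NA, 10))
  )
  posts$text[3] <- "i'm alpha beta three"
  users <- make_users(c("uA", "uB"), verified = c(TRUE, FALSE))
  originals <- pulse_stream(posts, users)
  rt_posts <- make_posts(
    post_id = c("r1", "r2"),
    text = c("rt", "rt"),
    day = rep("2019-06-02", 2),
    user_id = c("uB", "uB"),
    retweet_of = c("p1", "p3")
  )
  retweets <- pulse_stream(rt_posts, users,
                           window = as.Date(c("2019-06-01", "2019-06-02")))
  groups <- tibble::tibble(group_id = "g1", kind = "event",
                           term = "alpha beta")
  assignments <- tibble::tibble(group_id = "g1", kind = "event",
                                post_id = c("p1", "p2", "p3"))
  facts <- tibble::tibble(
    user_id = c("uA", "uB"), yules_i = c(4 / 3, 8 / 3),
    verified = c(TRUE, FALSE), n_posts_in_stream = c(4L, 8L)
  )
  list(groups = groups, assignments = assignments, originals = originals,
       retweets = retweets, facts = facts)
}

test_that("group_report matches hand computation on a fixed fixture", {
  fx <- hand_report_fixture()
  rep1 <- group_report(fx$groups, fx$assignments, fx$originals, fx$retweets,
                       fx$facts)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$n_tweets, 3L)
  expect_equal(rep1$avg_yule, 2.0) # mean(4/3, 8/3) over distinct authors
  expect_equal(rep1$pct_verified, 50)
  expect_equal(rep1$on_dom, 6) # mean(4, 8)
  expect_equal(rep1$n_users_tweeting, 2L)
  expect_equal(rep1$n_users_retweeting, 1L)
  expect_equal(rep1$pct_replies, 100 / 3, tolerance = 1e-9)
  expect_equal(rep1$pct_first_person, 100 / 3, tolerance = 1e-9)
})

test_that("group_report agrees with a flat-scan oracle on the fixture stream", {
  fx <- small_fixture()
  parts <- split_retweets(fx$stream)
  facts <- build_user_facts(fx$stream, default_domain_lexicon())
  det <- detect_term_groups(parts$originals, seed = 1L)
  reports <- group_report(det$groups, det$assignments, parts$originals,
                          parts$retweets, facts)
  for (gid in reports$group_id) {
    ids <- det$assignments$post_id[det$assignments$group_id == gid]
    o <- oracle_group_report(ids, parts$originals, parts$retweets, facts)
    row <- reports[reports$group_id == gid, ]
    expect_equal(row$n_tweets, o$n_tweets)
    expect_equal(row$avg_yule, o$avg_yule)
    expect_equal(row$pct_verified, o$pct_verified)
    expect_equal(row$on_dom, o$on_dom)
    expect_equal(row$n_users_tweeting, o$n_users_tweeting)
    expect_equal(row$n_users_retweeting, o$n_users_retweeting)
    expect_equal(row$pct_replies, o$pct_replies)
    expect_equal(row$pct_first_person, o$pct_first_person)
  }
})

test_that("audience histogram counts authors and retweeters by profile", {
  fx <- hand_report_fixture()
  facts <- dplyr::mutate(fx$facts,
                         profile = c("journalist", "concerned"))
  hist <- audience_profile_histogram(fx$groups, fx$assignments, fx$originals,
                                     fx$retweets, facts)
  expect_equal(hist$n_authors[hist$profile == "journalist"], 1L)
  # uB both authors a group post and retweets one: counted in both roles
  expect_equal(hist$n_authors[hist$profile == "concerned"], 1L)
  expect_equal(hist$n_audience[hist$profile == "concerned"], 1L)
  expect_equal(hist$n_audience[hist$profile == "journalist"], 0L)

  no_rt <- audience_profile_histogram(
    fx$groups, fx$assignments, fx$originals,
    empty_retweets(fx$originals$users, fx$retweets$window), facts
  )
  expect_true(all(no_rt$n_audience == 0))
})

test_that("controversial_screen flags the monitoring signatures", {
  reports <- tibble::tibble(
    group_id = c("g1", "g2", "g3"),
    avg_yule = c(24, 85, 97),
    on_dom = c(282, 2, 5),
    pct_verified = c(0, 5, 0),
    n_users_retweeting = c(185L, 5915L, 0L),
    pct_replies = c(0, 43, 3)
  )
  flagged <- controversial_screen(reports)
  g1 <- flagged[flagged$group_id == "g1", ]
  expect_true(g1$spam_like && g1$unverified_viral && !g1$active_discussion)
  g2 <- flagged[flagged$group_id == "g2", ]
  expect_true(g2$active_discussion && !g2$spam_like && !g2$unverified_viral)
  expect_false("g3" %in% flagged$group_id)
})

test_that("every complete dimension partition conserves post counts", {
  fx <- small_fixture()
  facts <- build_user_facts(fx$stream, default_domain_lexicon())
  pf <- build_post_facts(fx$stream)
  pf <- dplyr::left_join(pf,
                         facts[, c("user_id", "quality_band")],
                         by = "user_id")
  n <- nrow(fx$stream$posts)
  for (dim in c("quality_band", "lang", "day", "is_reply",
                "is_first_person")) {
    cells <- table(pf[[dim]], useNA = "ifany")
    expect_equal(sum(cells), n)
  }
})
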