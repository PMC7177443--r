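test_that("write/read round-trips a stream field for field", {
  posts <- make_posts(
    post_id = c("p1", "p2", "p3"),
    text = c("melanoma news http://x.io/a", "tengo leucemia", "rt of p1"),
    day = c("2019-06-01", "2019-06-03", "2019-06-04"),
    lang = c("en", "es", "en"),
    user_id = c("u1", "u2", "u1"),
    retweet_of = c(NA, NA, "p1"),
    in_reply_to = c(NA, "p1", NA),
    reply_count = c(2L, 0L, 0L),
    retweet_count = c(1L, 0L, 0L),
    like_count = c(5L, 1L, 0L)
  )
  users <- make_users(c("u1", "u2"), c("alice", "bob"),
                      c("oncologist", "survivor runner"),
                      verified = c(TRUE, FALSE), followers = c(10L, 3L))
  s <- pulse_stream(posts, users)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_stream(s, path)
  s2 <- read_stream(path)
  expect_equal(s2$posts, s$posts)
  expect_equal(dplyr::arrange(s2$users, user_id), s$users)
  expect_equal(s2$window, s$window)
})

test_that("read_stream counts posts and deduplicates users", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id_str":"p1","full_text":"a","created_at":"2019-06-01","lang":"en","user":{"id_str":"u1","screen_name":"x","description":"","verified":false,"followers_count":1}}',
    '{"id_str":"p2","full_text":"b","created_at":"2019-06-02","lang":"en","user":{"id_str":"u2","screen_name":"y","description":"old","verified":false,"followers_count":2}}',
    '{"id_str":"p3","full_text":"c","created_at":"2019-06-03","lang":"en","user":{"id_str":"u2","screen_name":"y","description":"new","verified":true,"followers_count":9}}'
  ), path)
  s <- read_stream(path)
  expect_equal(nrow(s$posts), 3)
  expect_equal(nrow(s$users), 2)
  # last full record wins
  u2 <- s$users[s$users$user_id == "u2", ]
  expect_equal(u2$description, "new")
  expect_true(u2$verified)
  expect_equal(s$window, as.Date(c("2019-06-01", "2019-06-03")))
})

test_that("read_stream rejects malformed input with line numbers", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"text": "x"}', path)
  expect_error(read_stream(path), "line 1")

  writeLines(c(
    '{"id_str":"p1","full_text":"a","created_at":"2019-06-01","lang":"en","user":{"id_str":"u1","screen_name":"x","description":"","verified":false,"followers_count":1}}',
    "{not json"
  ), path)
  expect_error(read_stream(path), "line 2")

  # reference to a user never embedded in full
  writeLines(
    '{"id_str":"p1","full_text":"a","created_at":"2019-06-01","lang":"en","user_id_str":"ghost"}',
    path
  )
  expect_error(read_stream(path), "ghost")
})

test_that("empty stream file yields empty stream with undefined window", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), path)
  expect_warning(s <- read_stream(path), "undefined")
  expect_equal(nrow(s$posts), 0)
  expect_equal(nrow(s$users), 0)
  expect_true(all(is.na(s$window)))
})

test_that("dedup_texts keeps the earliest post per normalized text", {
  posts <- make_posts(
    post_id = c("p1", "p2", "p3"),
    text = c("AAA bbb", "AAA bbb", "ccc"),
    day = c("2019-06-01", "2019-06-02", "2019-06-02")
  )
  s <- pulse_stream(posts, make_users("u1"))
  d <- dedup_texts(s)
  expect_equal(nrow(d$unique$posts), 2)
  expect_equal(d$dup_map$post_id, "p2")
  expect_equal(d$dup_map$canonical_id, "p1")
})

test_that("dedup_texts normalizes case, whitespace and URLs", {
  posts <- make_posts(
    post_id = c("p1", "p2"),
    text = c("Hi  X", "hi x http://t.co/zzz"),
    day = c("2019-06-01", "2019-06-01")
  )
  s <- pulse_stream(posts, make_users("u1"))
  d <- dedup_texts(s)
  expect_equal(nrow(d$unique$posts), 1)
  expect_equal(nrow(d$dup_map), 1)
})

test_that("dedup_texts conserves counts and is identity on distinct texts", {
  fx <- small_fixture()
  d <- dedup_texts(fx$stream)
  expect_equal(nrow(d$unique$posts) + nrow(d$dup_map), nrow(fx$stream$posts))

  posts <- make_posts(c("p1", "p2"), c("abc", "xyz"),
                      c("2019-06-01", "2019-06-02"))
  s <- pulse_stream(posts, make_users("u1"))
  d2 <- dedup_texts(s)
  expect_equal(nrow(d2$dup_map), 0)
  expect_equal(d2$unique$posts, s$posts)
})

test_that("split_retweets partitions the stream exactly", {
  posts <- make_posts(
    post_id = paste0("p", 1:5),
    text = letters[1:5],
    day = rep("2019-06-01", 5),
    retweet_of = c(NA, "p1", NA, "p1", NA)
  )
  s <- pulse_stream(posts, make_users("u1"))
  parts <- split_retweets(s)
  expect_equal(nrow(parts$originals$posts), 3)
  expect_equal(nrow(parts$retweets$posts), 2)
  expect_setequal(c(parts$originals$posts$post_id, parts$retweets$posts$post_id),
                  posts$post_id)

  no_rt <- split_retweets(parts$originals)
  expect_equal(nrow(no_rt$retweets$posts), 0)
})

test_that("retweets of posts outside the stream are kept and flagged", {
  posts <- make_posts(
    post_id = c("p1", "p2"),
    text = c("a", "b"),
    day = rep("2019-06-01", 2),
    retweet_of = c(NA, "missing")
  )
  s <- pulse_stream(posts, make_users("u1"))
  expect_message(parts <- split_retweets(s), "outside the stream")
  expect_equal(nrow(parts$retweets$posts), 1)
  expect_true(parts$retweets$posts$dangling)
})

test_that("keyword_filter matches unigrams and contiguous multiword keywords", {
  posts <- make_posts(
    post_id = paste0("p", 1:3),
    text = c("new melanoma drug", "stock market news", "skin cancer ad"),
    day = rep("2019-06-01", 3)
  )
  s <- pulse_stream(posts, make_users("u1"))
  kept <- keyword_filter(s, default_keywords())
  expect_setequal(kept$posts$post_id, c("p1", "p3"))
  expect_error(keyword_filter(s, character()), "non-empty")
})

test_that("stream invariants are enforced at construction", {
  expect_error(
    pulse_stream(make_posts(c("p1", "p1"), c("a", "b"),
                            rep("2019-06-01", 2)),
                 make_users("u1")),
    "duplicate post_id"
  )
  expect_error(
    pulse_stream(make_posts("p1", "a", "2019-06-01", retweet_of = "p1"),
                 make_users("u1")),
    "themselves"
  )
  expect_error(
    pulse_stream(make_posts("p1", "a", "2019-06-01", user_id = "u9"),
                 make_users("u1")),
    "unknown user"
  )
})
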