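# compact constructors for hand-built fixture streams

make_posts <- function(post_id, text, day, lang = "en", user_id = "u1",
                       retweet_of = NA_character_,
                       in_reply_to = NA_character_, reply_count = 0L,
                       retweet_count = 0L, like_count = 0L) {
  tibble::tibble(
    post_id = post_id, text = text, day = as.Date(day), lang = lang,
    user_id = user_id, retweet_of = retweet_of, in_reply_to = in_reply_to,
    reply_count = as.integer(reply_count),
    retweet_count = as.integer(retweet_count),
    like_count = as.integer(like_count)
  )
}

make_users <- function(user_id, screen_name = user_id, description = "",
                       verified = FALSE, followers = 0L) {
  tibble::tibble(
    user_id = user_id, screen_name = screen_name, description = description,
    verified = verified, followers = as.integer(followers)
  )
}

empty_retweets <- function(users, window) {
  pulse_stream(
    make_posts(character(), character(), as.Date(character()),
               lang = character(), user_id = character()),
    users, window
  )
}
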