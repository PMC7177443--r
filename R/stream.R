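#' Post-stream container
#'
#' A `pulse_stream` bundles the two relations of a micro-blog stream — one
#' post per row and one account per row — together with the inclusive
#' day-resolution analysis window. All analytics in the package consume and
#' return tibbles, so the container is deliberately thin.
#'
#' @param posts A tibble with columns `post_id`, `text`, `day` (`Date`),
#'   `lang` (`"en"` or `"es"`), `user_id`, `retweet_of`, `in_reply_to`
#'   (character, `NA` when absent), `reply_count`, `retweet_count`,
#'   `like_count` (non-negative integers).
#' @param users A tibble with columns `user_id`, `screen_name`,
#'   `description`, `verified` (logical), `followers` (non-negative integer).
#' @param window Length-2 `Date` vector, inclusive `[start, end]`. Defaults
#'   to the range of `posts$day`; an empty stream gets an `NA` window.
#'
#' @return An object of class `pulse_stream`: a list with elements `posts`,
#'   `users` and `window`.
#' @export
#' @examples
#' s <- small_fixture()$stream
#' s
#' nrow(s$posts)
pulse_stream <- function(posts, users, window = NULL) {
  posts <- as_tibble(posts)
  users <- as_tibble(users)
  post_cols <- c(
    "post_id", "text", "day", "lang", "user_id", "retweet_of",
    "in_reply_to", "reply_count", "retweet_count", "like_count"
  )
  user_cols <- c("user_id", "screen_name", "description", "verified", "followers")
  missing_p <- setdiff(post_cols, names(posts))
  if (length(missing_p) > 0) {
    abort(paste0("posts is missing column(s): ", paste(missing_p, collapse = ", ")))
  }
  missing_u <- setdiff(user_cols, names(users))
  if (length(missing_u) > 0) {
    abort(paste0("users is missing column(s): ", paste(missing_u, collapse = ", ")))
  }
  posts <- posts[post_cols]
  users <- users[user_cols]

  if (anyDuplicated(posts$post_id)) {
    abort("duplicate post_id in stream")
  }
  if (anyDuplicated(users$user_id)) {
    abort("duplicate user_id in stream")
  }
  bad_self <- !is.na(posts$retweet_of) & posts$retweet_of == posts$post_id |
    !is.na(posts$in_reply_to) & posts$in_reply_to == posts$post_id
  if (any(bad_self)) {
    abort(paste0("post(s) linked to themselves: ",
                 paste(posts$post_id[bad_self], collapse = ", ")))
  }
  counts <- c(posts$reply_count, posts$retweet_count, posts$like_count, users$followers)
  if (any(counts < 0, na.rm = TRUE)) abort("engagement counts must be >= 0")
  unknown <- setdiff(posts$user_id, users$user_id)
  if (length(unknown) > 0) {
    abort(paste0("post(s) reference unknown user(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  bad_lang <- setdiff(unique(posts$lang), c("en", "es"))
  if (length(bad_lang) > 0) {
    abort(paste0("unsupported language tag(s): ", paste(bad_lang, collapse = ", ")))
  }

  if (is.null(window)) {
    window <- if (nrow(posts) > 0) range(posts$day) else as.Date(c(NA, NA))
  }
  window <- as.Date(window)
  if (nrow(posts) > 0 &&
      (any(posts$day < window[1]) || any(posts$day > window[2]))) {
    abort("post day outside the stream window")
  }

  structure(list(posts = posts, users = users, window = window),
            class = "pulse_stream")
}

#' @method print pulse_stream
#' @export
print.pulse_stream <- function(x, ...) {
  cat("<pulse_stream>\n")
  cat("  posts: ", nrow(x$posts), " (", sum(!is.na(x$posts$retweet_of)),
      " retweets)\n", sep = "")
  cat("  users: ", nrow(x$users), "\n", sep = "")
  if (all(is.na(x$window))) {
    cat("  window: <undefined: empty stream>\n")
  } else {
    cat("  window: ", format(x$window[1]), " .. ", format(x$window[2]),
        " (", as.integer(x$window[2] - x$window[1]) + 1L, " days)\n", sep = "")
  }
  invisible(x)
}

#' @method format pulse_stream
#' @export
format.pulse_stream <- function(x, ...) {
  paste0("<pulse_stream: ", nrow(x$posts), " posts, ", nrow(x$users), " users>")
}

empty_posts <- function() {
  tibble(
    post_id = character(), text = character(), day = as.Date(character()),
    lang = character(), user_id = character(), retweet_of = character(),
    in_reply_to = character(), reply_count = integer(),
    retweet_count = integer(), like_count = integer()
  )
}

empty_users <- function() {
  tibble(
    user_id = character(), screen_name = character(),
    description = character(), verified = logical(), followers = integer()
  )
}

#' Restrict a stream to a subset of posts
#'
#' Internal helper: keeps the given post rows, all users, and the original
#' window (so daily series remain comparable after filtering).
#' @noRd
stream_keep_posts <- function(stream, keep) {
  pulse_stream(stream$posts[keep, , drop = FALSE], stream$users, stream$window)
}

#' Read a JSON Lines post stream
#'
#' Parses one post per line in a compact dialect of the Twitter v1.1 export
#' format: `id_str`, `full_text`, `created_at` (ISO `YYYY-MM-DD` date),
#' `lang`, an embedded `user` object (`id_str`, `screen_name`, `description`,
#' `verified`, `followers_count`), optional `retweeted_status` (object with
#' `id_str`) , optional `in_reply_to_status_id_str`, and optional
#' `reply_count` / `retweet_count` / `favorite_count` (default 0). A post may
#' instead carry a bare `user_id_str` reference provided the full account
#' record is embedded somewhere else in the file.
#'
#' Accounts are deduplicated by `user_id`; when the same account appears more
#' than once the last full record wins. The analysis window defaults to the
#' `[min day, max day]` span of the file.
#'
#' @param path Path to a UTF-8 `.jsonl` file.
#' @param window Optional length-2 `Date` vector overriding the inferred
#'   window.
#' @return A [pulse_stream].
#' @export
read_stream <- function(path, window = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    warn("empty stream file: window is undefined")
    return(pulse_stream(empty_posts(), empty_users(), window))
  }

  posts <- vector("list", length(idx))
  users <- list()
  referenced <- character()

  for (k in seq_along(idx)) {
    i <- idx[k]
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        abort(paste0("malformed JSON at line ", i, ": ", conditionMessage(e)))
      }
    )
    req <- c("id_str", "full_text", "created_at", "lang")
    miss <- req[!req %in% names(rec)]
    if (length(miss) > 0) {
      abort(paste0("line ", i, ": missing required field(s): ",
                   paste(miss, collapse = ", ")))
    }
    u <- rec$user
    if (is.list(u) && !is.null(u$id_str)) {
      uid <- as.character(u$id_str)
      if (!is.null(u$screen_name)) {
        # full embedded record; last one wins
        users[[uid]] <- tibble(
          user_id = uid,
          screen_name = as.character(u$screen_name),
          description = as.character(u$description %||% ""),
          verified = isTRUE(u$verified),
          followers = as.integer(u$followers_count %||% 0L)
        )
      } else {
        referenced <- c(referenced, setNames(uid, i))
      }
    } else if (!is.null(rec$user_id_str)) {
      uid <- as.character(rec$user_id_str)
      referenced <- c(referenced, setNames(uid, i))
    } else {
      abort(paste0("line ", i, ": post has neither an embedded user nor user_id_str"))
    }
    posts[[k]] <- tibble(
      post_id = as.character(rec$id_str),
      text = as.character(rec$full_text),
      day = as.Date(rec$created_at),
      lang = as.character(rec$lang),
      user_id = uid,
      retweet_of = as.character(rec$retweeted_status$id_str %||% NA_character_),
      in_reply_to = as.character(rec$in_reply_to_status_id_str %||% NA_character_),
      reply_count = as.integer(rec$reply_count %||% 0L),
      retweet_count = as.integer(rec$retweet_count %||% 0L),
      like_count = as.integer(rec$favorite_count %||% 0L)
    )
  }
  users_tbl <- bind_rows(users)
  if (nrow(users_tbl) == 0) users_tbl <- empty_users()
  dangling_ref <- referenced[!referenced %in% users_tbl$user_id]
  if (length(dangling_ref) > 0) {
    abort(paste0("line ", names(dangling_ref)[1],
                 ": post references unknown user ", dangling_ref[1],
                 " with no embedded user object anywhere in the file"))
  }
  pulse_stream(bind_rows(posts), users_tbl, window)
}

#' Write a stream as JSON Lines
#'
#' Inverse of [read_stream()]: one post per line with the full author record
#' embedded, so `read_stream(write_stream(s))` reproduces `s` field for
#' field.
#'
#' @param stream A [pulse_stream].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  users <- stream$users
  rownames(users) <- NULL
  lookup <- split(users, seq_len(nrow(users)))
  names(lookup) <- users$user_id
  lines <- map_chr(seq_len(nrow(stream$posts)), function(i) {
    p <- stream$posts[i, ]
    u <- lookup[[p$user_id]]
    rec <- list(
      id_str = p$post_id,
      full_text = p$text,
      created_at = format(p$day),
      lang = p$lang,
      user = list(
        id_str = u$user_id,
        screen_name = u$screen_name,
        description = u$description,
        verified = u$verified,
        followers_count = u$followers
      ),
      reply_count = p$reply_count,
      retweet_count = p$retweet_count,
      favorite_count = p$like_count
    )
    if (!is.na(p$retweet_of)) rec$retweeted_status <- list(id_str = p$retweet_of)
    if (!is.na(p$in_reply_to)) rec$in_reply_to_status_id_str <- p$in_reply_to
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
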