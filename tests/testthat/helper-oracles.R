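# Independent oracles: deliberately naive recomputations, no package
# machinery beyond the public containers.

oracle_yule <- function(tokens) {
  counts <- as.integer(table(tokens))
  m1 <- length(counts)
  m2 <- sum(counts^2)
  if (m2 == m1) return(Inf)
  m1^2 / (m2 - m1)
}

oracle_kurtosis <- function(x) {
  mu <- sum(x) / length(x)
  m2 <- sum((x - mu)^2) / length(x)
  m4 <- sum((x - mu)^4) / length(x)
  if (m2 == 0) return(0)
  m4 / m2^2 - 3
}

# excess kurtosis of a 0/1 single-spike series of length n (Bernoulli
# closed form at p = 1/n)
bernoulli_spike_kurtosis <- function(n) {
  p <- 1 / n
  q <- 1 - p
  (1 - 6 * p * q) / (p * q)
}

oracle_inner_product <- function(u, d) {
  s <- 0
  for (w in names(u)) {
    if (w %in% names(d)) s <- s + u[[w]] * d[[w]]
  }
  s
}

# all set partitions of 1..n (Bell number growth: keep n <= 7)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1]] <- q
    }
    p[[length(p) + 1]] <- n
    out[[length(out) + 1]] <- p
  }
  out
}

# exhaustive maximum-modularity partition of a small graph
oracle_best_modularity <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 7)
  best <- -Inf
  for (p in all_partitions(n)) {
    memb <- integer(n)
    for (i in seq_along(p)) memb[p[[i]]] <- i
    q <- modularity_q(graph, memb)
    if (q > best) best <- q
  }
  best
}

macro_f1 <- function(truth, pred) {
  classes <- unique(truth)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

# flat-scan recomputation of one group's report row from raw tables
oracle_group_report <- function(group_post_ids, originals, retweets, facts) {
  posts <- originals$posts[originals$posts$post_id %in% group_post_ids, ]
  authors <- unique(posts$user_id)
  f <- facts[match(authors, facts$user_id), ]
  rt <- retweets$posts[retweets$posts$retweet_of %in% group_post_ids, ]
  fp <- logical(nrow(posts))
  for (i in seq_len(nrow(posts))) {
    fp[i] <- is_first_person(tokenize(posts$text[i]), posts$lang[i])
  }
  list(
    n_tweets = nrow(posts),
    avg_yule = mean(f$yules_i, na.rm = TRUE),
    pct_verified = 100 * mean(f$verified),
    on_dom = mean(f$n_posts_in_stream),
    n_users_tweeting = length(authors),
    n_users_retweeting = length(unique(rt$user_id)),
    pct_replies = 100 * mean(!is.na(posts$in_reply_to)),
    pct_first_person = 100 * mean(fp)
  )
}

# random token sequences for property tests
random_token_seq <- function(n_tokens, vocab_size) {
  paste0("w", sample.int(vocab_size, n_tokens, replace = TRUE))
}
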