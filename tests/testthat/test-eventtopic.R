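window5 <- as.Date(c("2019-06-01", "2019-06-05"))

test_that("daily_series counts occurrences per day with zeros included", {
  posts <- make_posts(
    post_id = paste0("p", 1:3),
    text = rep("skin cancer facts", 3),
    day = rep("2019-06-03", 3)
  )
  s <- pulse_stream(posts, make_users("u1"), window = window5)
  ds <- daily_series(s, "skin cancer")
  expect_equal(ds$count, c(0, 0, 3, 0, 0))

  expect_equal(daily_series(s, "absent term")$count, rep(0, 5))

  # two occurrences inside one post count twice
  s2 <- pulse_stream(
    make_posts("p1", "skin cancer and skin cancer", "2019-06-02"),
    make_users("u1"), window = window5
  )
  expect_equal(daily_series(s2, "skin cancer")$count, c(0, 2, 0, 0, 0))
})

test_that("series_kurtosis matches hand-derived moments", {
  expect_equal(series_kurtosis(c(0, 0, 10, 0, 0)), 0.25)
  expect_equal(series_kurtosis(c(5, 5, 5, 5)), 0)
  expect_error(series_kurtosis(7), "at least 2")
  set.seed(2)
  for (i in 1:50) {
    x <- rpois(sample(2:100, 1), sample(1:5, 1))
    expect_equal(series_kurtosis(x), oracle_kurtosis(x))
  }
})

test_that("single-spike series match the Bernoulli closed form", {
  for (n in c(10, 50, 100, 500)) {
    x <- rep(0, n)
    x[3] <- 20 # kurtosis is scale-invariant: any positive height
    expect_equal(series_kurtosis(x), bernoulli_spike_kurtosis(n),
                 tolerance = 1e-12)
  }
  x <- rep(0, 100); x[40] <- 20
  expect_equal(series_kurtosis(x), 95.0101, tolerance = 1e-4)
})

test_that("bigram_stats agrees with per-term daily_series recomputation", {
  fx <- small_fixture()
  originals <- split_retweets(fx$stream)$originals
  occ <- term_occurrences(originals)
  st <- bigram_stats(originals, occurrences = occ)
  expect_true(all(st$peak <= st$total))
  expect_true(all(st$span >= 1))
  for (t in sample(st$term, 10)) {
    ds <- daily_series(originals, t, occurrences = occ)
    row <- st[st$term == t, ]
    expect_equal(row$total, sum(ds$count))
    expect_equal(row$peak, max(ds$count))
    nz <- which(ds$count > 0)
    expect_equal(row$span, max(nz) - min(nz) + 1L)
    expect_equal(row$kurtosis, series_kurtosis(ds$count))
  }
})

test_that("event and topic selectors apply the threshold rules", {
  stats <- tibble::tibble(
    term = c("a b", "c d", "e f", "g h", "i j", "k l"),
    total = c(100, 50, 200, 100, 20, 5),
    peak = c(20, 10, 25, 3, 20, 5),
    span = c(1, 5, 30, 90, 1, 2),
    kurtosis = c(95, 0.25, 12, 0.5, 80, 88)
  )
  th <- event_thresholds()
  # selected iff kurtosis >= 10 & peak >= 20 & span <= 10
  expect_setequal(select_event_bigrams(stats, th), c("a b", "i j"))
  # topic iff total >= 20 and not event-shaped
  expect_setequal(select_topic_bigrams(stats, th), c("c d", "e f", "g h"))
  cls <- classify_terms(stats, th)
  expect_equal(cls$class,
               c("event", "topic", "topic", "topic", "event", "other"))
})

test_that("cooccurrence_graph counts co-posting and drops zero edges", {
  posts <- make_posts(
    post_id = paste0("p", 1:9),
    text = c(rep("alpha beta gamma delta", 7), "alpha beta", "other stuff"),
    day = rep("2019-06-01", 9)
  )
  s <- pulse_stream(posts, make_users("u1"), window = window5)
  g <- cooccurrence_graph(s, c("alpha beta", "gamma delta", "other stuff"))
  expect_equal(igraph::vcount(g), 3)
  w <- igraph::as_data_frame(g)
  expect_equal(nrow(w), 1) # only the pair that co-occurs
  expect_equal(w$weight, 7)

  g1 <- cooccurrence_graph(s, "alpha beta")
  expect_equal(igraph::vcount(g1), 1)
  expect_equal(igraph::ecount(g1), 0)
})

two_triangles <- function() {
  igraph::graph_from_edgelist(rbind(
    c("a", "b"), c("b", "c"), c("a", "c"),
    c("d", "e"), c("e", "f"), c("d", "f")
  ), directed = FALSE)
}

test_that("modularity_q matches the formula and igraph on known graphs", {
  g <- two_triangles()
  memb <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(modularity_q(g, memb), 0.5)

  edge <- igraph::graph_from_edgelist(rbind(c("x", "y")), directed = FALSE)
  expect_equal(modularity_q(edge, c(x = 1, y = 1)), 0)
  expect_equal(modularity_q(edge, c(x = 1, y = 2)), -0.5)

  expect_error(
    modularity_q(igraph::make_empty_graph(3, directed = FALSE), c(1, 2, 3)),
    "edgeless"
  )

  set.seed(9)
  for (i in 1:10) {
    gr <- igraph::sample_gnp(12, 0.35)
    if (igraph::ecount(gr) == 0) next
    igraph::E(gr)$weight <- sample(1:5, igraph::ecount(gr), replace = TRUE)
    memb <- sample(1:3, 12, replace = TRUE)
    expect_equal(modularity_q(gr, memb),
                 igraph::modularity(gr, memb, weights = igraph::E(gr)$weight))
  }
})

test_that("cluster_terms recovers the exhaustive-search optimum on small graphs", {
  g <- two_triangles()
  cl <- cluster_terms(g, seed = 1)
  expect_equal(length(unique(cl$group_id)), 2)
  expect_equal(attr(cl, "modularity"), oracle_best_modularity(g))
  # members of each triangle stay together
  grp_of <- setNames(cl$group_id, cl$term)
  expect_equal(length(unique(grp_of[c("a", "b", "c")])), 1)
  expect_equal(length(unique(grp_of[c("d", "e", "f")])), 1)

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  cl4 <- cluster_terms(k4, seed = 1)
  expect_equal(length(unique(cl4$group_id)), 1)

  iso <- igraph::make_empty_graph(3, directed = FALSE)
  iso <- igraph::set_vertex_attr(iso, "name", value = c("x", "y", "z"))
  cl0 <- cluster_terms(iso, seed = 1)
  expect_equal(length(unique(cl0$group_id)), 3)
})

test_that("cluster_terms is reproducible and never worse than singletons", {
  fx <- small_fixture()
  originals <- split_retweets(fx$stream)$originals
  st <- bigram_stats(originals)
  terms <- select_topic_bigrams(st)
  g <- cooccurrence_graph(originals, terms)
  if (igraph::ecount(g) > 0) {
    c1 <- cluster_terms(g, seed = 42)
    c2 <- cluster_terms(g, seed = 42)
    expect_identical(c1$group_id, c2$group_id)
    expect_identical(attr(c1, "modularity"), attr(c2, "modularity"))
    singleton_q <- modularity_q(g, seq_len(igraph::vcount(g)))
    expect_gte(attr(c1, "modularity"), singleton_q)
  }
  expect_error(cluster_terms(igraph::make_empty_graph(0)), "empty")
})

test_that("assign_posts maps posts to every owning group and reports coverage", {
  posts <- make_posts(
    post_id = paste0("p", 1:3),
    text = c("alpha beta also gamma delta", "alpha beta only", "nothing here at"),
    day = rep("2019-06-01", 3)
  )
  s <- pulse_stream(posts, make_users("u1"), window = window5)
  groups <- tibble::tibble(
    group_id = c("gA", "gB"), kind = c("event", "topic"),
    term = c("alpha beta", "gamma delta")
  )
  asg <- assign_posts(groups, s)
  expect_setequal(asg$assignments$group_id[asg$assignments$post_id == "p1"],
                  c("gA", "gB"))
  expect_false("p3" %in% asg$assignments$post_id)
  expect_equal(asg$coverage$event_fraction, 2 / 3)
  expect_equal(asg$coverage$topic_fraction, 1 / 3)
  expect_equal(asg$coverage$event_and_topic_fraction, 1 / 2)
})

test_that("planted coverage is recovered within two points", {
  g <- generate_stream(synth_config(seed = 303L, duplicate_rate = 0))
  originals <- split_retweets(g$stream)$originals
  det <- detect_term_groups(originals, seed = 1L)
  truth_event_posts <- g$truth$posts$post_id[g$truth$posts$kind == "event"]
  planted_fraction <- mean(originals$posts$post_id %in% truth_event_posts)
  expect_lt(abs(det$coverage$event_fraction - planted_fraction), 0.02)
})
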