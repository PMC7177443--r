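#' Per-post term occurrences
#'
#' Expands a stream into one row per term occurrence: each post contributes
#' every content bigram (and whitelisted unigram) it contains, with
#' multiplicity. This long table feeds [bigram_stats()],
#' [cooccurrence_graph()] and [assign_posts()].
#'
#' @param stream A [pulse_stream] (typically originals, after
#'   [dedup_texts()]).
#' @param unigram_whitelist Passed to [extract_bigrams()].
#' @return Tibble with columns `post_id`, `user_id`, `day`, `term`, `n`.
#' @export
term_occurrences <- function(stream, unigram_whitelist = character()) {
  posts <- stream$posts
  if (nrow(posts) == 0) {
    return(tibble(post_id = character(), user_id = character(),
                  day = as.Date(character()), term = character(), n = integer()))
  }
  toks <- tokenize_all(posts$text)
  lens <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  post_idx <- rep.int(seq_len(nrow(posts)), lens)
  sw <- ifelse(
    flat %in% stopword_lists$en & posts$lang[post_idx] == "en" |
      flat %in% stopword_lists$es & posts$lang[post_idx] == "es",
    TRUE, startsWith(flat, "@")
  )
  occ <- list()
  if (length(flat) >= 2) {
    i1 <- seq_len(length(flat) - 1)
    adjacent <- post_idx[i1] == post_idx[i1 + 1]
    ok <- adjacent & !sw[i1] & !sw[i1 + 1]
    if (any(ok)) {
      occ$bigrams <- tibble(
        row = post_idx[i1][ok],
        term = paste(flat[i1][ok], flat[i1 + 1][ok])
      )
    }
  }
  if (length(unigram_whitelist) > 0) {
    hit <- flat %in% unigram_whitelist
    if (any(hit)) {
      occ$unigrams <- tibble(row = post_idx[hit], term = flat[hit])
    }
  }
  occ <- bind_rows(occ)
  if (nrow(occ) == 0) {
    return(tibble(post_id = character(), user_id = character(),
                  day = as.Date(character()), term = character(), n = integer()))
  }
  occ |>
    count(.data$row, .data$term, name = "n") |>
    transmute(
      post_id = posts$post_id[.data$row],
      user_id = posts$user_id[.data$row],
      day = posts$day[.data$row],
      term = .data$term,
      n = as.integer(.data$n)
    ) |>
    arrange(.data$post_id, .data$term)
}

#' Daily occurrence series of a term
#'
#' @param stream A [pulse_stream].
#' @param term A term string (space-joined bigram or whitelisted unigram).
#' @param window Length-2 `Date` vector; defaults to the stream window.
#' @param occurrences Optional precomputed [term_occurrences()] table.
#' @return Tibble with one row per day in the window: `day`, `count`
#'   (zeros included).
#' @export
daily_series <- function(stream, term, window = stream$window,
                         occurrences = NULL) {
  if (any(is.na(window))) abort("daily_series needs a defined window")
  occ <- occurrences %||%
    term_occurrences(stream, unigram_whitelist = if (!grepl(" ", term)) term else character())
  days <- seq(window[1], window[2], by = "day")
  hits <- occ |>
    filter(.data$term == !!term) |>
    group_by(.data$day) |>
    summarise(count = sum(.data$n), .groups = "drop")
  tibble(day = days) |>
    left_join(hits, by = "day") |>
    mutate(count = tidyr::replace_na(.data$count, 0L))
}

#' Population excess kurtosis of a daily count series
#'
#' Computed over the full zero-padded window with population central
#' moments: `g2 = m4 / m2^2 - 3`. A constant (zero-variance) series returns
#' 0. High values flag spike-shaped series — the temporal signature of an
#' event; sustained topics sit near 0.
#'
#' @param counts Numeric vector of daily counts (a full window, zeros
#'   included), or the tibble returned by [daily_series()].
#' @return Numeric scalar.
#' @export
#' @examples
#' series_kurtosis(c(0, 0, 10, 0, 0)) # 0.25
series_kurtosis <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  n <- length(counts)
  if (n < 2) abort("series_kurtosis needs at least 2 days")
  mu <- mean(counts)
  d <- counts - mu
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  m4 <- mean(d^4)
  m4 / m2^2 - 3
}

#' Temporal statistics for every term in a stream
#'
#' For each term: total occurrences, peak daily count, span (days between
#' first and last occurrence, inclusive) and excess kurtosis of the
#' zero-padded daily series over the window. Terms below `min_total` are
#' dropped up front — rare bigrams carry no temporal signal and dominate the
#' raw term count otherwise.
#'
#' @param stream A [pulse_stream], or a precomputed [term_occurrences()]
#'   tibble via `occurrences`.
#' @param window Length-2 `Date` vector; defaults to the stream window.
#' @param min_total Minimum total occurrences for a term to be scored
#'   (default 5).
#' @param unigram_whitelist Passed to [term_occurrences()].
#' @param occurrences Optional precomputed occurrence table.
#' @return Tibble: `term`, `total`, `peak`, `span`, `kurtosis`.
#' @export
bigram_stats <- function(stream, window = stream$window, min_total = 5L,
                         unigram_whitelist = character(), occurrences = NULL) {
  if (any(is.na(window))) abort("bigram_stats needs a defined window")
  occ <- occurrences %||% term_occurrences(stream, unigram_whitelist)
  n_days <- as.integer(window[2] - window[1]) + 1L
  daily <- occ |>
    group_by(.data$term, .data$day) |>
    summarise(count = sum(.data$n), .groups = "drop")
  # zero-inclusive population moments without materializing full series:
  # the (n_days - k) zero days contribute (0 - mu)^p each.
  daily |>
    group_by(.data$term) |>
    summarise(
      total = sum(.data$count),
      peak = max(.data$count),
      span = as.integer(max(.data$day) - min(.data$day)) + 1L,
      k_days = dplyr::n(),
      s2 = sum(.data$count^2),
      s3 = sum(.data$count^3),
      s4 = sum(.data$count^4),
      .groups = "drop"
    ) |>
    filter(.data$total >= min_total) |>
    mutate(
      mu = .data$total / n_days,
      m2 = (.data$s2 - 2 * .data$mu * .data$total + n_days * .data$mu^2) / n_days,
      m4 = (.data$s4 - 4 * .data$mu * .data$s3 + 6 * .data$mu^2 * .data$s2 -
              4 * .data$mu^3 * .data$total + n_days * .data$mu^4) / n_days,
      kurtosis = ifelse(.data$m2 == 0, 0, .data$m4 / .data$m2^2 - 3)
    ) |>
    select("term", "total", "peak", "span", "kurtosis") |>
    arrange(desc(.data$total), .data$term)
}

#' Event/topic selection thresholds
#'
#' Defaults follow the reference configuration: an event term must form a
#' sharp, tall, short burst (kurtosis at least 10, daily peak at least 20,
#' span at most 10 days); a topic term must be frequent (total at least 20)
#' and *not* event-shaped.
#'
#' @param min_kurtosis,min_peak,max_span_days,topic_min_total Positive
#'   numerics.
#' @return A list of class `event_thresholds`.
#' @export
event_thresholds <- function(min_kurtosis = 10, min_peak = 20L,
                             max_span_days = 10L, topic_min_total = 20L) {
  stopifnot(min_kurtosis > 0, min_peak > 0, max_span_days > 0,
            topic_min_total > 0)
  structure(list(min_kurtosis = min_kurtosis, min_peak = as.integer(min_peak),
                 max_span_days = as.integer(max_span_days),
                 topic_min_total = as.integer(topic_min_total)),
            class = "event_thresholds")
}

#' Select event terms
#'
#' @param stats Tibble from [bigram_stats()].
#' @param th An [event_thresholds()] object.
#' @return Character vector of event terms.
#' @export
select_event_bigrams <- function(stats, th = event_thresholds()) {
  stats$term[stats$kurtosis >= th$min_kurtosis &
               stats$peak >= th$min_peak &
               stats$span <= th$max_span_days]
}

#' Select topic terms
#'
#' Frequent terms whose temporal shape is *not* a short burst. Topics may
#' still contain event posts (a burst inside a sustained theme), so the two
#' selections need not be disjoint at the post level.
#'
#' @inheritParams select_event_bigrams
#' @return Character vector of topic terms.
#' @export
select_topic_bigrams <- function(stats, th = event_thresholds()) {
  stats$term[stats$total >= th$topic_min_total &
               !(stats$kurtosis >= th$min_kurtosis &
                   stats$span <= th$max_span_days)]
}

#' Classify every scored term
#'
#' @inheritParams select_event_bigrams
#' @return The `stats` tibble with an added `class` column in
#'   `{"event", "topic", "other"}`.
#' @export
classify_terms <- function(stats, th = event_thresholds()) {
  ev <- stats$term %in% select_event_bigrams(stats, th)
  tp <- stats$term %in% select_topic_bigrams(stats, th)
  stats$class <- ifelse(ev, "event", ifelse(tp, "topic", "other"))
  stats
}

#' Term co-occurrence graph
#'
#' Nodes are the selected terms; the weight of edge (t1, t2) is the number
#' of posts containing both. Zero-weight edges and self-loops are absent.
#' Vertices are sorted by name so downstream clustering is order-stable.
#'
#' @param stream A [pulse_stream], or a precomputed occurrence table via
#'   `occurrences`.
#' @param terms Character vector of terms (the graph's node set).
#' @param occurrences Optional [term_occurrences()] tibble.
#' @return An [igraph::graph] with a `weight` edge attribute.
#' @export
cooccurrence_graph <- function(stream, terms, occurrences = NULL) {
  terms <- sort(unique(terms))
  occ <- occurrences %||%
    term_occurrences(stream, unigram_whitelist = terms[!grepl(" ", terms)])
  occ <- occ |> filter(.data$term %in% terms) |> distinct(.data$post_id, .data$term)
  g_empty <- igraph::make_empty_graph(n = length(terms), directed = FALSE)
  g_empty <- igraph::set_vertex_attr(g_empty, "name", value = terms)
  if (nrow(occ) == 0) return(g_empty)
  inc <- Matrix::sparseMatrix(
    i = match(occ$post_id, unique(occ$post_id)),
    j = match(occ$term, terms),
    x = 1,
    dims = c(length(unique(occ$post_id)), length(terms))
  )
  co <- Matrix::crossprod(inc)
  co <- Matrix::triu(co, k = 1)
  idx <- Matrix::which(co > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(g_empty)
  edges <- tibble(
    from = terms[idx[, 1]],
    to = terms[idx[, 2]],
    weight = co[idx]
  )
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = tibble(name = terms)
  )
  g
}

#' Modularity of a graph partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` with total edge mass `m`,
#' within-community mass `e_c` and community degree `d_c`, all
#' weight-aware.
#'
#' @param graph An undirected [igraph::graph]; a missing `weight` attribute
#'   means unit weights.
#' @param membership Community id per vertex, in vertex order (or named by
#'   vertex name).
#' @return Numeric scalar.
#' @export
modularity_q <- function(graph, membership) {
  if (igraph::ecount(graph) == 0) abort("modularity is undefined for an edgeless graph")
  vnames <- igraph::V(graph)$name
  if (!is.null(names(membership)) && !is.null(vnames)) {
    membership <- membership[vnames]
  }
  if (length(membership) != igraph::vcount(graph)) {
    abort("membership must cover every vertex")
  }
  w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  m <- sum(w)
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  same <- membership[ends[, 1]] == membership[ends[, 2]]
  deg <- igraph::strength(graph, weights = w)
  d_c <- tapply(deg, membership, sum)
  # communities with no internal edge contribute e_c = 0
  e_c <- setNames(rep(0, length(d_c)), names(d_c))
  if (any(same)) {
    e_present <- tapply(w[same], membership[ends[, 1]][same], sum)
    e_c[names(e_present)] <- e_present
  }
  sum(e_c / m - (d_c / (2 * m))^2)
}

#' Cluster terms into event/topic groups by modularity
#'
#' Greedy Louvain-style modularity maximization over the weighted
#' co-occurrence graph. Node order is fixed (sorted names) and the random
#' seed pins any tie-breaking, so results are reproducible. Isolated terms
#' become singleton groups.
#'
#' @param graph From [cooccurrence_graph()].
#' @param seed Integer seed.
#' @param kind Label stored on the result: `"event"` or `"topic"`.
#' @return Tibble of class `pulse_term_groups`: `group_id`, `kind`, `term`;
#'   attributes `modularity` (Q of the partition, `NA` for an edgeless
#'   graph) and `kind`.
#' @export
cluster_terms <- function(graph, seed = 1L, kind = "topic") {
  n <- igraph::vcount(graph)
  if (n == 0) abort("cluster_terms: empty graph")
  vnames <- igraph::V(graph)$name %||% as.character(seq_len(n))
  if (igraph::ecount(graph) == 0) {
    membership <- seq_len(n)
    q <- NA_real_
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(seed)
    cl <- igraph::cluster_louvain(graph, weights = igraph::E(graph)$weight)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    membership <- igraph::membership(cl)
    q <- modularity_q(graph, as.integer(membership))
  }
  out <- tibble(
    group_id = paste0(substr(kind, 1, 1), "g",
                      formatC(as.integer(membership), width = 3, flag = "0")),
    kind = kind,
    term = vnames
  ) |> arrange(.data$group_id, .data$term)
  structure(out, modularity = q, kind = kind,
            class = c("pulse_term_groups", class(out)))
}

#' Assign posts to term groups
#'
#' A post belongs to every group owning at least one term the post contains.
#' Coverage fractions are reported against the total post count of the
#' stream the occurrences were computed from.
#'
#' @param groups A [cluster_terms()] result, or a tibble with `group_id`,
#'   `kind`, `term` (event and topic groups may be row-bound).
#' @param stream The [pulse_stream] the groups were built from.
#' @param occurrences Optional precomputed [term_occurrences()] tibble.
#' @return A list: `assignments` (tibble `group_id`, `kind`, `post_id`) and
#'   `coverage` (tibble with `event_fraction`, `topic_fraction`,
#'   `event_and_topic_fraction` — the latter the fraction of event posts
#'   also assigned to a topic).
#' @export
assign_posts <- function(groups, stream, occurrences = NULL) {
  occ <- occurrences %||%
    term_occurrences(stream,
                     unigram_whitelist = unique(groups$term[!grepl(" ", groups$term)]))
  assignments <- occ |>
    distinct(.data$post_id, .data$term) |>
    inner_join(as_tibble(groups)[c("group_id", "kind", "term")],
               by = "term", relationship = "many-to-many") |>
    distinct(.data$group_id, .data$kind, .data$post_id) |>
    arrange(.data$group_id, .data$post_id)
  n_total <- nrow(stream$posts)
  ev_posts <- unique(assignments$post_id[assignments$kind == "event"])
  tp_posts <- unique(assignments$post_id[assignments$kind == "topic"])
  coverage <- tibble(
    event_fraction = length(ev_posts) / n_total,
    topic_fraction = length(tp_posts) / n_total,
    event_and_topic_fraction =
      if (length(ev_posts) == 0) 0 else mean(ev_posts %in% tp_posts)
  )
  list(assignments = assignments, coverage = coverage)
}

#' Full event/topic detection pipeline
#'
#' Scores all terms, selects event and topic terms, clusters each selection
#' on its own co-occurrence graph, and assigns posts to groups.
#'
#' @param stream A deduplicated originals [pulse_stream].
#' @param th [event_thresholds()].
#' @param seed Integer seed for clustering.
#' @param min_total Pre-filter for [bigram_stats()].
#' @param unigram_whitelist Unigrams treated as terms.
#' @return List: `terms` (scored + classified stats), `groups` (row-bound
#'   event and topic groups), `assignments`, `coverage`, `modularity`
#'   (named numeric for event/topic graphs).
#' @export
detect_term_groups <- function(stream, th = event_thresholds(), seed = 1L,
                               min_total = 5L, unigram_whitelist = character()) {
  occ <- term_occurrences(stream, unigram_whitelist)
  stats <- bigram_stats(stream, min_total = min_total, occurrences = occ) |>
    classify_terms(th)
  groups <- list()
  mods <- c(event = NA_real_, topic = NA_real_)
  for (kind in c("event", "topic")) {
    terms <- stats$term[stats$class == kind]
    if (length(terms) == 0) next
    g <- cooccurrence_graph(stream, terms, occurrences = occ)
    grp <- cluster_terms(g, seed = seed, kind = kind)
    mods[kind] <- attr(grp, "modularity")
    groups[[kind]] <- as_tibble(grp)
  }
  groups <- bind_rows(groups)
  asg <- assign_posts(groups, stream, occurrences = occ)
  list(terms = stats, groups = groups, assignments = asg$assignments,
       coverage = asg$coverage, modularity = mods)
}

#' @method print pulse_term_groups
#' @export
print.pulse_term_groups <- function(x, ...) {
  cat("<pulse_term_groups> ", length(unique(x$group_id)), " ",
      attr(x, "kind"), " group(s), ", nrow(x), " terms; Q = ",
      format(attr(x, "modularity"), digits = 4), "\n", sep = "")
  NextMethod()
}
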