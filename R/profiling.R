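#' Profile label vocabulary
#'
#' The closed set of user-profile labels assigned from account descriptions:
#' health professionals and services, retired professionals, students,
#' sports accounts, religious accounts, public services, disease-concerned
#' people, alternative-therapy accounts, journalists/publications, and a
#' residual class.
#'
#' @return Character vector of the 11 labels.
#' @export
profile_labels <- function() {
  c("professional", "ex-professional", "student", "sports", "religion",
    "p.services", "h.services", "concerned", "pseudo", "journalist",
    "others")
}

#' Seed vocabulary per profile
#'
#' Characteristic description words for each profile label, used to seed the
#' synthetic-stream generator and as a sanity anchor for the classifier
#' (e.g. "oncologist" for professionals, "reiki" for alternative-therapy
#' accounts, "survivor" for concerned users).
#'
#' @return Named list: label -> character vector of words.
#' @export
profile_seed_lexicon <- function() {
  list(
    professional = c("radiosurgery", "oncoplastic", "oncologist",
                     "haemato-oncology", "consultants", "surgeon",
                     "dermatologist", "md"),
    `ex-professional` = c("retired", "former", "senate", "viet", "colonel",
                          "veteran", "emeritus"),
    student = c("student", "thesis", "undergraduate", "engineering",
                "studying", "phd", "campus"),
    sports = c("runner", "marathon", "athlete", "skater", "rider",
               "cyclist", "triathlon"),
    religion = c("amin", "allah", "savior", "hindu", "jesus", "prayer",
                 "faith"),
    p.services = c("traffic", "24h", "breaking", "weather", "protection",
                   "emergency", "alerts"),
    h.services = c("urgencias", "screenings", "specialties", "uninsured",
                   "visitors", "clinic", "appointments"),
    concerned = c("survivor", "reminder_ribbon", "survivorship", "warrior",
                  "fighter", "remission"),
    pseudo = c("reiki", "meditation", "yoga", "ayurveda", "remedial",
               "holistic", "healing"),
    journalist = c("medline-indexed", "issn", "journal", "indexed",
                   "open-access", "editor", "correspondent"),
    others = c("zombies", "yin-yang", "weekends", "voracious", "virgo",
               "coffee", "music", "travel", "gamer", "foodie", "dreamer",
               "cats")
  )
}

#' Bag-of-words + bigram features of a description
#'
#' @param description Character scalar.
#' @return Named integer vector of unigram and adjacent-bigram counts
#'   (bigrams space-joined). Empty descriptions give an empty vector.
#' @export
#' @examples
#' description_features("retired colonel")
description_features <- function(description) {
  toks <- tokenize(description)
  feats <- toks
  if (length(toks) >= 2) {
    feats <- c(feats, paste(toks[-length(toks)], toks[-1]))
  }
  if (length(feats) == 0) return(setNames(integer(), character()))
  counts <- table(feats)
  setNames(as.integer(counts), names(counts))
}

feature_matrix <- function(descriptions, vocabulary = NULL, min_count = 1L,
                           max_features = Inf) {
  feats <- map(descriptions, description_features)
  if (is.null(vocabulary)) {
    all_counts <- table(unlist(map(feats, names)))
    all_counts <- all_counts[all_counts >= min_count]
    if (length(all_counts) > max_features) {
      # deterministic cap: most frequent first, ties alphabetical
      ord <- order(-as.integer(all_counts), names(all_counts))
      all_counts <- all_counts[ord[seq_len(max_features)]]
    }
    vocabulary <- sort(names(all_counts))
  }
  m <- matrix(0, nrow = length(descriptions), ncol = length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    f <- f[names(f) %in% vocabulary]
    if (length(f) > 0) m[i, names(f)] <- f
  }
  m
}

#' Train the user-profile classifier
#'
#' A single-hidden-layer feed-forward network (softmax output) over
#' unigram+bigram count features of the account descriptions. With
#' `method = "multinom"` the hidden layer is dropped and a skip-layer
#' multinomial-logistic model is fitted instead. Training is reproducible
#' under `seed`.
#'
#' @param data Tibble with columns `description` and `label` (labels from
#'   [profile_labels()]); a `user_id` column is carried along if present.
#' @param seed Integer seed (weight initialization).
#' @param hidden Hidden-layer size (default 16).
#' @param method `"nnet"` (default) or `"multinom"`.
#' @param min_count Minimum corpus frequency for a feature to enter the
#'   vocabulary (default 2 — hapax features only add noise).
#' @param max_features Vocabulary cap: the most frequent features are kept
#'   (default 300). Short account descriptions separate on a few hundred
#'   signal words, and the optimizer cost grows quadratically with the
#'   weight count.
#' @param decay L2 weight decay passed to [nnet::nnet()].
#' @param maxit Maximum optimizer iterations.
#' @return Object of class `pulse_profile_model`.
#' @export
train_profile_classifier <- function(data, seed = 1L, hidden = 16L,
                                     method = c("nnet", "multinom"),
                                     min_count = 2L, max_features = 300L,
                                     decay = 0.1, maxit = 100L) {
  method <- match.arg(method)
  data <- as_tibble(data)
  stopifnot(all(c("description", "label") %in% names(data)))
  bad <- setdiff(unique(data$label), profile_labels())
  if (length(bad) > 0) {
    abort(paste0("unknown profile label(s): ", paste(bad, collapse = ", ")))
  }
  tab <- table(data$label)
  if (length(tab) < 2) abort("training data must contain at least 2 classes")
  small <- names(tab)[tab < 5]
  if (length(small) > 0) {
    abort(paste0("class(es) with fewer than 5 examples: ",
                 paste(small, collapse = ", ")))
  }
  classes <- sort(names(tab))
  x <- feature_matrix(data$description, min_count = min_count,
                      max_features = max_features)
  if (ncol(x) == 0) abort("no features survive min_count; lower it or add data")
  y <- factor(data$label, levels = classes)
  set.seed(seed)
  size <- if (method == "nnet") hidden else 0L
  fit <- nnet::nnet(
    x, nnet::class.ind(y),
    size = size, skip = (size == 0), softmax = TRUE,
    decay = decay, maxit = maxit, trace = FALSE,
    MaxNWts = (ncol(x) + 1) * max(size, 1) +
      (max(size, 1) + 1 + ncol(x)) * length(classes) + 1000
  )
  train_pred <- classes[max.col(predict(fit, x))]
  model <- structure(
    list(fit = fit, vocabulary = colnames(x), classes = classes,
         seed = seed, method = method, hidden = size,
         n_train = nrow(data),
         train_labels = as.character(y), train_pred = train_pred),
    class = "pulse_profile_model"
  )
  model
}

#' @method print pulse_profile_model
#' @export
print.pulse_profile_model <- function(x, ...) {
  cat("<pulse_profile_model> ", x$method, " (hidden = ", x$hidden, "), ",
      length(x$classes), " classes, ", length(x$vocabulary),
      " features, trained on ", x$n_train, " descriptions (seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Predict user profiles from descriptions
#'
#' @param model A [train_profile_classifier()] model.
#' @param descriptions Character vector. Empty or feature-less descriptions
#'   are assigned `"others"` deterministically.
#' @return Tibble: `description`, `label`, `p_max`, plus one `p_<class>`
#'   probability column per class (each row sums to 1).
#' @export
#' @examples
#' \dontrun{
#' predict_profile(model, "oncologist consultants radiosurgery")
#' }
predict_profile <- function(model, descriptions) {
  x <- feature_matrix(descriptions, vocabulary = model$vocabulary)
  probs <- predict(model$fit, x)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  colnames(probs) <- model$classes
  # descriptions with no known features carry no signal: residual class
  blank <- rowSums(x) == 0
  if (any(blank)) {
    probs[blank, ] <- 0
    if ("others" %in% model$classes) {
      probs[blank, "others"] <- 1
    } else {
      probs[blank, ] <- 1 / length(model$classes)
    }
  }
  label <- model$classes[max.col(probs, ties.method = "first")]
  out <- tibble(
    description = descriptions,
    label = label,
    p_max = apply(probs, 1, max)
  )
  probs_tbl <- as_tibble(as.data.frame(probs))
  names(probs_tbl) <- paste0("p_", model$classes)
  bind_cols(out, probs_tbl)
}

#' @method predict pulse_profile_model
#' @export
predict.pulse_profile_model <- function(object, newdata, ...) {
  predict_profile(object, newdata)
}

#' Per-profile language models of descriptions
#'
#' Pools the descriptions of each labelled profile into a unigram model —
#' the lexical fingerprint of each profile.
#'
#' @param users Tibble with columns `description` and `label`.
#' @return Named list: label -> language model (named probability vector).
#' @export
profile_language_models <- function(users) {
  users <- as_tibble(users)
  stopifnot(all(c("description", "label") %in% names(users)))
  split(users$description, users$label) |>
    map(function(d) build_language_model(map(d, tokenize)))
}

#' Top description words per profile
#'
#' @param models Output of [profile_language_models()].
#' @param k Words per profile.
#' @return Tibble: `label`, `word`, `prob`, `rank`.
#' @export
profile_top_words <- function(models, k = 5L) {
  imap(models, function(lm, label) {
    lm <- sort(lm, decreasing = TRUE)
    n <- min(k, length(lm))
    if (n == 0) return(NULL)
    tibble(label = label, word = names(lm)[seq_len(n)],
           prob = unname(lm[seq_len(n)]), rank = seq_len(n))
  }) |> bind_rows()
}

#' Generate labelled synthetic account descriptions
#'
#' Samples descriptions for every profile label by mixing that profile's
#' seed vocabulary with background noise words — the stand-in for a manually
#' labelled training set. With `noise_frac` at or below 0.5 the signal words
#' dominate and a classifier should separate the profiles.
#'
#' @param n_per_class Descriptions per profile label.
#' @param noise_frac Fraction of words drawn from the noise vocabulary.
#' @param n_words Words per description.
#' @param seed Integer seed.
#' @return Tibble: `user_id`, `description`, `label`.
#' @export
generate_profile_descriptions <- function(n_per_class = 100L,
                                          noise_frac = 0.3,
                                          n_words = 6L, seed = 1L) {
  stopifnot(noise_frac >= 0, noise_frac <= 1, n_per_class >= 1)
  set.seed(seed)
  seed_lex <- profile_seed_lexicon()
  noise_vocab <- sprintf("nw%03d", 1:200)
  out <- imap(seed_lex, function(words, label) {
    desc <- vapply(seq_len(n_per_class), function(i) {
      n_noise <- stats::rbinom(1, n_words, noise_frac)
      picked <- c(sample(words, min(n_words - n_noise, length(words)),
                         replace = n_words - n_noise > length(words)),
                  sample(noise_vocab, n_noise, replace = TRUE))
      paste(sample(picked), collapse = " ")
    }, character(1))
    tibble(label = label, description = desc)
  })
  bind_rows(out) |>
    mutate(user_id = sprintf("lu%04d", dplyr::row_number())) |>
    select("user_id", "description", "label")
}
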