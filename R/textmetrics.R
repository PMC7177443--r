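#' Tokenize post text
#'
#' Lowercases, strips URLs, drops the `#` of hashtags (keeping the tag word),
#' keeps `@mentions` as single tokens, strips remaining punctuation (internal
#' apostrophes survive, so "i'm" stays one token) and splits on whitespace.
#'
#' @param text Character scalar (or vector; results are concatenated per
#'   element into a list when length > 1).
#' @return Character vector of tokens for a scalar input; a list of such
#'   vectors for a vector input.
#' @export
#' @examples
#' tokenize("Melanoma KILLS. http://t.co/x")
#' tokenize("#skincancer awareness @WHO")
tokenize <- function(text) {
  if (length(text) != 1) return(tokenize_all(text))
  tokenize_all(text)[[1]]
}

#' Tokenize many texts at once
#'
#' Vectorized form of [tokenize()] used on whole streams.
#'
#' @param texts Character vector.
#' @return List of token character vectors, one per input text.
#' @export
tokenize_all <- function(texts) {
  n <- length(texts)
  if (n == 0) return(list())
  x <- ifelse(is.na(texts), "", texts)
  x <- stringr::str_remove_all(x, "https?://\\S+")
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "’", "'")
  x <- stringr::str_remove_all(x, "#")
  # anything that is not a letter, digit, @ or apostrophe becomes a separator
  x <- stringr::str_replace_all(x, "[^\\p{L}\\p{N}@']+", " ")
  x <- stringr::str_squish(x)
  toks <- stringr::str_split(x, stringr::fixed(" "))
  flat <- unlist(toks, use.names = FALSE)
  flat <- stringr::str_remove_all(flat, "^'+|'+$")
  idx <- factor(rep.int(seq_len(n), lengths(toks)), levels = seq_len(n))
  keep <- nzchar(flat)
  out <- split(flat[keep], idx[keep])
  names(out) <- NULL
  out
}

#' Word frequency spectrum
#'
#' Tabulates how many word types occur exactly `i` times, the support of
#' Yule's diversity statistics: `M1` is the number of types, `N` the number
#' of tokens and `M2 = sum(i^2 * V_i)`.
#'
#' @param tokens Character vector of tokens.
#' @return A list of class `freq_spectrum` with elements `spectrum` (named
#'   integer vector, occurrence count -> number of types), `M1`, `M2`, `N`.
#' @export
#' @examples
#' frequency_spectrum(c("a", "a", "b"))
frequency_spectrum <- function(tokens) {
  if (length(tokens) == 0) {
    return(structure(list(spectrum = integer(), M1 = 0L, M2 = 0, N = 0L),
                     class = "freq_spectrum"))
  }
  counts <- table(tokens)
  spec <- table(as.integer(counts))
  i <- as.integer(names(spec))
  v <- as.integer(spec)
  structure(
    list(
      spectrum = setNames(v, i),
      M1 = sum(v),
      M2 = sum(as.numeric(i)^2 * v),
      N = sum(i * v)
    ),
    class = "freq_spectrum"
  )
}

#' @method print freq_spectrum
#' @export
print.freq_spectrum <- function(x, ...) {
  cat("<freq_spectrum> N =", x$N, " types =", x$M1, " M2 =", x$M2, "\n")
  invisible(x)
}

#' Yule's I vocabulary diversity
#'
#' The inverse of Yule's characteristic K: `I = M1^2 / (M2 - M1)` where `M1`
#' is the number of word types and `M2 = sum(i^2 * V_i)` over the frequency
#' spectrum. It is largely insensitive to text length; low values mean a
#' repetitive vocabulary (automated accounts typically score below 30),
#' engaged human accounts tend to land around 60-115.
#'
#' @param x A `freq_spectrum` (from [frequency_spectrum()]) or a character
#'   vector of tokens.
#' @param cap Value reported when every type occurs exactly once
#'   (`M2 == M1`, diversity unbounded). Default `Inf`; report tables use a
#'   finite cap (10000).
#' @return Non-negative numeric scalar.
#' @export
#' @examples
#' yules_i(c("a", "a", "b")) # 4/3
yules_i <- function(x, cap = Inf) {
  spec <- if (inherits(x, "freq_spectrum")) x else frequency_spectrum(x)
  if (spec$N == 0) abort("yules_i is undefined for an empty token sequence")
  if (spec$M2 == spec$M1) return(cap)
  spec$M1^2 / (spec$M2 - spec$M1)
}

#' Maximum-likelihood unigram language model
#'
#' Pools one or more token sequences and returns the empirical word
#' distribution.
#'
#' @param texts A character vector of tokens, or a list of such vectors.
#' @return Named numeric vector of probabilities summing to 1; empty input
#'   yields an empty model.
#' @export
build_language_model <- function(texts) {
  toks <- if (is.list(texts)) unlist(texts, use.names = FALSE) else texts
  if (length(toks) == 0) return(setNames(numeric(), character()))
  counts <- table(toks)
  setNames(as.numeric(counts) / sum(counts), names(counts))
}

#' Domain coherence of a user's vocabulary
#'
#' The inner product of the user's unigram distribution with a domain term
#' distribution: the probability that one word drawn from each coincides.
#' Zero iff the vocabularies are disjoint; typical values against a broad
#' medical lexicon are of order 1e-4, which is why quality thresholds on
#' this metric are quoted in those units.
#'
#' @param user_lm,domain_lm Named numeric probability vectors (see
#'   [build_language_model()] and [read_domain_lexicon()]).
#' @return Numeric scalar in `[0, 1]`.
#' @export
domain_coherence <- function(user_lm, domain_lm) {
  if (length(user_lm) == 0) {
    warn("empty user language model: coherence is 0")
    return(0)
  }
  shared <- intersect(names(user_lm), names(domain_lm))
  if (length(shared) == 0) return(0)
  sum(user_lm[shared] * domain_lm[shared])
}

first_person_lexicons <- list(
  en = c("i", "i'm", "i've", "me", "my", "mine"),
  es = c("yo", "me", "mi", "mis", "estoy", "tengo", "tuve")
)

#' First-person detection
#'
#' Flags token sequences containing a first-person marker; across a term
#' group this estimates the fraction of posters directly affected by the
#' condition rather than relaying news.
#'
#' @param tokens Character vector of tokens.
#' @param lang `"en"` or `"es"`.
#' @return Logical scalar.
#' @export
is_first_person <- function(tokens, lang) {
  lex <- first_person_lexicons[[lang]]
  if (is.null(lex)) abort(paste0("unsupported language: ", lang))
  any(tokens %in% lex)
}

stopword_lists <- list(
  en = c(
    "a", "an", "the", "and", "or", "of", "to", "in", "on", "for", "is",
    "are", "was", "were", "be", "been", "with", "at", "by", "from", "it",
    "its", "this", "that", "these", "those", "as", "has", "have", "had",
    "not", "but", "we", "you", "they", "he", "she", "i", "i'm", "i've",
    "im", "my", "me", "your",
    "their", "so", "if", "about", "into", "than", "then", "there", "here",
    "what", "when", "who", "how", "all", "can", "will", "just", "do",
    "does", "did", "up", "out", "no", "yes", "rt", "via", "amp"
  ),
  es = c(
    "el", "la", "los", "las", "un", "una", "unos", "unas", "y", "o", "u",
    "de", "del", "a", "al", "en", "por", "para", "con", "sin", "que", "se",
    "su", "sus", "es", "son", "fue", "era", "lo", "le", "les", "mi", "mis",
    "tu", "tus", "yo", "no", "si", "sí", "más", "mas", "pero", "estoy",
    "tengo", "tuve",
    "como", "cuando", "donde", "qué", "este", "esta", "esto", "ese",
    "esa", "eso", "ya", "hay", "ha", "he", "muy", "también", "rt"
  )
)

#' Built-in stopword list
#'
#' @param lang `"en"` or `"es"`.
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function(lang = "en") {
  sw <- stopword_lists[[lang]]
  if (is.null(sw)) abort(paste0("unsupported language: ", lang))
  sw
}

#' Extract content bigrams from a token sequence
#'
#' All adjacent token pairs, skipping pairs where either token is a stopword
#' or an `@mention`. Terms are returned as space-joined strings. Selected
#' unigrams (e.g. disease names whose semantics need no second word) can be
#' whitelisted and are emitted as degenerate one-word terms.
#'
#' @param tokens Character vector of tokens.
#' @param lang Language tag used to pick the stopword list.
#' @param stopwords Stopword vector; defaults to [default_stopwords()].
#' @param unigram_whitelist Character vector of single words additionally
#'   emitted as terms wherever they occur.
#' @return Character vector (multiset) of terms.
#' @export
#' @examples
#' extract_bigrams(c("skin", "cancer", "kills"))
extract_bigrams <- function(tokens, lang = "en",
                            stopwords = default_stopwords(lang),
                            unigram_whitelist = character()) {
  out <- character()
  if (length(tokens) >= 2) {
    w1 <- tokens[-length(tokens)]
    w2 <- tokens[-1]
    ok <- !(w1 %in% stopwords) & !(w2 %in% stopwords) &
      !startsWith(w1, "@") & !startsWith(w2, "@")
    out <- paste(w1[ok], w2[ok])
  }
  if (length(unigram_whitelist) > 0) {
    out <- c(out, tokens[tokens %in% unigram_whitelist])
  }
  out
}
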