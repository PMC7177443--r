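#' Read a domain lexicon as a term distribution
#'
#' The domain lexicon is a two-column TSV (`term<TAB>weight`) standing in for
#' any large medical-terminology resource. Weights are normalized to a
#' probability distribution over unigrams; multiword terms are split and each
#' constituent word receives the full term weight (so a user mentioning
#' either word of "skin cancer" gains coherence).
#'
#' @param path Path to the TSV file. Lines starting with `#` are skipped.
#' @return Named numeric vector of unigram probabilities (a language model
#'   usable with [domain_coherence()]).
#' @seealso The packaged stand-in:
#'   `system.file("extdata", "synthetic_medical_lexicon.tsv", package = "pulsecube")`.
#' @export
read_domain_lexicon <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("term", "weight"),
                           colClasses = c("character", "numeric"),
                           quote = "", fileEncoding = "UTF-8")
  if (nrow(raw) == 0) abort("empty domain lexicon")
  if (any(raw$weight < 0)) abort("lexicon weights must be non-negative")
  words <- stringr::str_split(stringr::str_to_lower(raw$term), "\\s+")
  tbl <- tibble(
    word = unlist(words),
    weight = rep(raw$weight, lengths(words))
  ) |>
    group_by(.data$word) |>
    summarise(weight = sum(.data$weight), .groups = "drop")
  setNames(tbl$weight / sum(tbl$weight), tbl$word)
}

#' Default packaged medical lexicon
#'
#' Loads the small synthetic medical-term lexicon shipped with the package.
#' It is a constructed stand-in covering common oncology vocabulary in
#' English and Spanish, adequate for examples and synthetic streams; real
#' deployments should point [read_domain_lexicon()] at a full terminology
#' export.
#'
#' @return Named numeric probability vector.
#' @export
default_domain_lexicon <- function() {
  read_domain_lexicon(
    system.file("extdata", "synthetic_medical_lexicon.tsv", package = "pulsecube")
  )
}
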