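#' Scatter plot of user-quality metrics
#'
#' Activity (posts in stream, log scale) against vocabulary diversity,
#' coloured by quality band — the visual used to audit bot/spam filtering.
#' Point size encodes domain coherence.
#'
#' @param facts A [build_user_facts()] tibble.
#' @return A ggplot object.
#' @export
plot_user_quality <- function(facts) {
  df <- facts |> filter(.data$metrics_defined)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$n_posts_in_stream, y = .data$yules_i,
    colour = .data$quality_band, size = .data$coherence
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(
      good = "#2e7d32", inspect = "#212121", filtered = "#c62828"
    )) +
    ggplot2::labs(
      x = "posts in stream", y = "Yule's I (vocabulary diversity)",
      colour = "quality band", size = "domain coherence",
      title = "User quality metrics"
    ) +
    ggplot2::theme_minimal()
}

#' Daily occurrence series of selected terms
#'
#' @param stream A [pulse_stream].
#' @param terms Character vector of terms to plot.
#' @param occurrences Optional precomputed [term_occurrences()] table.
#' @return A ggplot object (one facet per term).
#' @export
plot_term_series <- function(stream, terms, occurrences = NULL) {
  df <- bind_rows(map(terms, function(t) {
    daily_series(stream, t, occurrences = occurrences) |>
      mutate(term = t)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "#1565c0") +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "daily occurrences",
                  title = "Term temporal distributions") +
    ggplot2::theme_minimal()
}

#' Author vs audience profile histogram
#'
#' Side-by-side bars of authors (posters) and audience (retweeters) per
#' profile for one or more term groups.
#'
#' @param histogram An [audience_profile_histogram()] tibble.
#' @return A ggplot object (one facet per group).
#' @export
plot_audience_profiles <- function(histogram) {
  df <- histogram |>
    tidyr::pivot_longer(c("n_authors", "n_audience"),
                        names_to = "role", values_to = "n") |>
    mutate(role = ifelse(.data$role == "n_authors", "authors", "audience"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$profile, y = .data$n,
                                   fill = .data$role)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group_id), scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(authors = "#1565c0",
                                          audience = "#c62828")) +
    ggplot2::labs(x = NULL, y = "users", fill = NULL,
                  title = "Authors and audience by profile") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
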