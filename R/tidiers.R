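#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-class training diagnostics of a profile model
#'
#' @param x A [train_profile_classifier()] model.
#' @param ... Unused.
#' @return Tibble with one row per class: `class`, `n`, `precision`,
#'   `recall`, `f1` on the training data.
#' @export
tidy.pulse_profile_model <- function(x, ...) {
  map(x$classes, function(cl) {
    tp <- sum(x$train_pred == cl & x$train_labels == cl)
    fp <- sum(x$train_pred == cl & x$train_labels != cl)
    fn <- sum(x$train_pred != cl & x$train_labels == cl)
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
      NA_real_
    } else {
      2 * prec * rec / (prec + rec)
    }
    tibble(class = cl, n = sum(x$train_labels == cl),
           precision = prec, recall = rec, f1 = f1)
  }) |> bind_rows()
}

#' One-row summary of a profile model
#'
#' @param x A [train_profile_classifier()] model.
#' @param ... Unused.
#' @return Tibble: `method`, `hidden`, `n_train`, `n_features`, `n_classes`,
#'   `train_accuracy`, `seed`.
#' @export
glance.pulse_profile_model <- function(x, ...) {
  tibble(
    method = x$method, hidden = x$hidden, n_train = x$n_train,
    n_features = length(x$vocabulary), n_classes = length(x$classes),
    train_accuracy = mean(x$train_pred == x$train_labels),
    seed = x$seed
  )
}

#' One-row summary of a term-group partition
#'
#' @param x A [cluster_terms()] result.
#' @param ... Unused.
#' @return Tibble: `kind`, `n_terms`, `n_groups`, `modularity`.
#' @export
glance.pulse_term_groups <- function(x, ...) {
  tibble(
    kind = attr(x, "kind"),
    n_terms = nrow(x),
    n_groups = length(unique(x$group_id)),
    modularity = attr(x, "modularity")
  )
}
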