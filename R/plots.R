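# ggplot2 displays for fitted models, restart evaluations and attention.

#' @export
autoplot.bt_passage_model <- function(object, ...) plot_history(object$history)

#' @export
autoplot.bt_triage_model <- function(object, ...) plot_history(object$history)

plot_history <- function(history) {
  if (is.null(history)) abort("model has no training history yet")
  long <- tidyr::pivot_longer(history, -"epoch", names_to = "metric",
                              values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bt_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_restart,
                  ggplot2::aes(x = factor(.data$restart), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean, linetype = "dashed") +
    ggplot2::labs(x = "restart", y = "held-out accuracy",
                  title = sprintf("%s: %.3f ± %.3f", object$task,
                                  object$mean, object$sd)) +
    ggplot2::theme_minimal()
}

#' Plot per-passage attention weights for documents
#'
#' @param weights Output of [attention_weights()].
#' @param max_docs Facet at most this many documents.
#' @return A ggplot object.
#' @export
plot_attention <- function(weights, max_docs = 6L) {
  keep <- head(unique(weights$doc_id), max_docs)
  w <- weights[weights$doc_id %in% keep, ]
  ggplot2::ggplot(w, ggplot2::aes(x = .data$position, y = .data$weight,
                                  fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~doc_id, scales = "free_x") +
    ggplot2::labs(x = "passage", y = "attention weight",
                  title = "Attention over passages") +
    ggplot2::theme_minimal()
}
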