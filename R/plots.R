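# ggplot2 autoplot methods for the main result types.

#' Plot pairwise Jaccard similarity of model interaction sets
#'
#' @param object A `model_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_comparison <- function(object, ...) {
  jac <- object$jaccard
  sym <- dplyr::bind_rows(
    jac,
    dplyr::rename(jac, model_a = "model_b", model_b = "model_a"),
    tibble::tibble(model_a = object$labels, model_b = object$labels,
                   jaccard = 1)
  )
  ggplot2::ggplot(sym, ggplot2::aes(.data$model_a, .data$model_b,
                                    fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$jaccard))) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard",
                  title = "Interaction-set similarity across models")
}

#' Plot a humanness report
#'
#' @param object A `humanness_report`.
#' @param ... Unused.
#' @return A ggplot with one panel per metric.
#' @export
autoplot.humanness_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(topk = .data$topk_identity / 100) |>
    tidyr::pivot_longer(c("ninemer_content", "topk"),
                        names_to = "metric", values_to = "score") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         ninemer_content = "9-mer content",
                                         topk = "top-k identity (fraction)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$chain, .data$score)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "score",
                  title = paste("Humanness vs repertoire:",
                                object$repertoire[1]))
}

#' Plot canonical residue classification along the chains
#'
#' @param object A `canonical_assignment`.
#' @param ... Unused.
#' @return A ggplot tile map of residue flags.
#' @export
autoplot.canonical_assignment <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("type1", "type2", "type3"),
                        names_to = "type", values_to = "flag")
  ggplot2::ggplot(df, ggplot2::aes(.data$resno, .data$type,
                                   fill = .data$flag)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::facet_wrap(~chain, ncol = 1, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "residue", y = NULL, fill = "flagged",
                  title = "Canonical structure-determining residues")
}
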