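# ggplot2 displays for the main result types.

#' Bar chart of diagnostic-confidence tiers
#'
#' @param x An `rp_diagnoses` ([run_pipeline()]) or `rp_replay`
#'   ([replay_fixture()]) tibble.
#' @return A ggplot object.
#' @export
plot_confidence_tiers <- function(x) {
  df <- as_tibble(x) %>%
    filter(!is.na(.data$confidence)) %>%
    count(.data$confidence) %>%
    mutate(confidence = factor(
      .data$confidence,
      levels = c("confident", "probable", "possible", "unreportable")
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$confidence, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "diagnostic confidence", y = "candidate diagnoses",
      title = "Diagnostic confidence tiers"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rp_diagnoses <- function(object, ...) plot_confidence_tiers(object)

#' @exportS3Method ggplot2::autoplot
autoplot.rp_replay <- function(object, ...) plot_confidence_tiers(object)

#' Histogram of SV cluster occurrence counts
#'
#' Shows the cohort SV database occurrence distribution with the common-SV
#' exclusion cut-off.
#'
#' @param object An [sv_database][build_sv_database].
#' @param max_count Rarity cut-off to draw (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sv_database <- function(object, max_count = 10L, ...) {
  ggplot2::ggplot(object$clusters, ggplot2::aes(x = .data$n_participants)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey40") +
    ggplot2::geom_vline(xintercept = max_count - 0.5, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "distinct participants per cluster", y = "clusters",
      title = "SV database occurrence counts",
      subtitle = paste0("clusters with ≥ ", max_count, " occurrences are excluded")
    ) +
    ggplot2::theme_minimal()
}

#' Matched key-feature counts per candidate diagnosis
#'
#' @param diagnoses An `rp_diagnoses` tibble.
#' @return A ggplot object.
#' @export
plot_feature_counts <- function(diagnoses) {
  df <- as_tibble(diagnoses) %>%
    tidyr::pivot_longer(c("major_count", "minor_count"),
                        names_to = "weight", values_to = "count") %>%
    mutate(weight = sub("_count", "", .data$weight))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$participant_id, y = .data$count, fill = .data$weight
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(major = "firebrick", minor = "grey60")) +
    ggplot2::labs(
      x = NULL, y = "matched key features",
      title = "Key clinical features matched per candidate diagnosis"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
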