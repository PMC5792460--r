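# ggplot2 views of the main result types.

#' @describeIn barcoding_gap Overlaid intra/inter distance histogram with
#'   the cutoff marked.
#' @param object A `gap_report`.
#' @param ... Unused.
#' @export
#' @method autoplot gap_report
autoplot.gap_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$histogram, c("intra", "inter"),
    names_to = "class", values_to = "count"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$bin_low, y = .data$count, fill = .data$class
  )) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, just = 0) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(
      x = "pairwise distance (substitutions/site)", y = "pairs",
      title = object$locus %||% NULL,
      subtitle = sprintf(
        "%.1f%% inter > %.2f; %.1f%% intra < %.2f",
        object$frac_inter_above, object$cutoff,
        object$frac_intra_below, object$cutoff
      )
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_combinations Success rates of every combination as
#'   grouped bars (best match, best close match, NJ discrimination).
#' @param object A `combination_ranking`.
#' @param ... Unused.
#' @export
#' @method autoplot combination_ranking
autoplot.combination_ranking <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::select("loci", "bm_success", "bcm_success", "nj_discrimination") |>
    tidyr::pivot_longer(-"loci", names_to = "method", values_to = "rate") |>
    dplyr::mutate(
      method = dplyr::recode(.data$method,
        bm_success = "best match",
        bcm_success = "best close match",
        nj_discrimination = "NJ discrimination"
      ),
      loci = factor(.data$loci, levels = rev(object$loci))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$loci, fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::labs(x = "success rate (%)", y = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' @describeIn label_clusters Per-label discrimination overview.
#' @param object A `discrimination`.
#' @param ... Unused.
#' @export
#' @method autoplot discrimination
autoplot.discrimination <- function(object, ...) {
  df <- object$table |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$discriminated ~ "discriminated",
      .data$is_exclusive ~ "exclusive, not discriminated",
      TRUE ~ "not exclusive"
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$label, fill = .data$status)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::labs(
      x = "specimens", y = NULL,
      title = paste0(
        "clusters by ", object$label_field, " (overall ",
        sprintf("%.1f%%", object$overall_rate), ")"
      )
    ) +
    ggplot2::theme_minimal()
}
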