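#' Plot the three-cohort overlap
#'
#' Bar chart of the seven Venn regions of the ICD-10, treatment-plan and
#' clinical-criteria cohorts.
#'
#' @param object An `hlh_overlap` from [compute_overlap()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hlh_overlap <- function(object, ...) {
  d <- object |> filter(.data$region != "any")
  total <- object$n[object$region == "any"]
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$region, -.data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "patients",
                  title = "Overlap of the three HLH computable phenotypes",
                  subtitle = paste0("union: ", total, " patients")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot criterion prevalence by treatment group
#'
#' Dot plot of each report row's group percentages from an
#' `hlh_comparison`.
#'
#' @param object An `hlh_comparison` from [compare_groups()].
#' @param variables Which `variable` groups to show (default criteria and
#'   outcomes).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hlh_comparison <- function(object,
                                    variables = c("criterion", "outcome"),
                                    ...) {
  d <- object$summary |>
    filter(.data$variable %in% variables) |>
    select("variable", "level", treated = "pct_treated",
           untreated = "pct_untreated") |>
    tidyr::pivot_longer(c("treated", "untreated"), names_to = "group",
                        values_to = "pct")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$level,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$variable), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "% of group", y = NULL, colour = "HLH-directed therapy",
                  title = "Treated vs untreated, criteria cohort") +
    ggplot2::theme_minimal()
}

#' Plot the screening-cohort criterion distribution
#'
#' Grouped bars of criterion prevalence among all ferritin-plus-fever
#' encounters and the strata above/below the criteria threshold.
#'
#' @param object An `hlh_screening_summary` from [screening_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hlh_screening_summary <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$criterion, y = .data$pct,
                               fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of stratum encounters",
                  title = "Criteria among high-ferritin febrile encounters",
                  subtitle = paste0("number needed to screen: ",
                                    attr(object, "nns"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
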