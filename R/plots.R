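#' Plot the annual landmark AUC trajectory
#'
#' AUC(t) against landmark year with the bootstrap percentile band. When
#' the table carries a `model` column (e.g. one row set per domain model
#' plus the combined model), one line is drawn per model.
#'
#' @param object A `cdr_auc_by_year` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdr_auc_by_year
#' @export
autoplot.cdr_auc_by_year <- function(object, ...) {
  df <- as_tibble(object)
  has_model <- "model" %in% names(df)
  aes_line <- if (has_model) {
    ggplot2::aes(x = .data$landmark_year, y = .data$auc,
                 colour = .data$model, fill = .data$model)
  } else {
    ggplot2::aes(x = .data$landmark_year, y = .data$auc)
  }
  p <- ggplot2::ggplot(df[!is.na(df$auc), ], aes_line) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$landmark_year)) +
    ggplot2::labs(x = "Landmark year", y = "AUC(t)",
                  title = "Dynamic AUC by landmark year") +
    ggplot2::theme_minimal()
  p
}

#' Plot a decile calibration curve
#'
#' Observed event rate against mean predicted probability per risk decile,
#' with the identity line; the Brier score is shown in the subtitle.
#'
#' @param object A `cdr_calibration` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdr_calibration
#' @export
autoplot.cdr_calibration <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_predicted,
                                   y = .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::geom_line() +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed event rate",
                  title = "Decile calibration",
                  subtitle = sprintf("Brier score: %.3f",
                                     attr(object, "brier"))) +
    ggplot2::theme_minimal()
}

#' Plot an AUC(t) comparison across domain models
#'
#' Convenience wrapper running [auc_by_year()] for each single-domain model
#' and the combined model, returning the stacked table ready for
#' [autoplot.cdr_auc_by_year()].
#'
#' @param subjects Eligible subject table with `outcome`.
#' @param visits Visit table.
#' @param domains Domain columns (each fitted alone, plus all combined).
#' @param years Landmark years.
#' @param B Bootstrap iterations per year.
#' @param seed Integer seed.
#' @return A `cdr_auc_by_year` tibble with a `model` column.
#' @export
auc_by_year_models <- function(subjects, visits,
                               domains = grep("^domain_", names(visits),
                                              value = TRUE),
                               years = 0:10, B = 200, seed = NULL) {
  seeds <- derive_seeds(seed, length(domains) + 1L)
  tabs <- lapply(seq_along(domains), function(k) {
    tab <- auc_by_year(subjects, visits, domains = domains[k],
                       years = years, B = B, seed = seeds[k])
    tab$model <- domains[k]
    tab
  })
  comb <- auc_by_year(subjects, visits, domains = domains, years = years,
                      B = B, seed = seeds[length(seeds)])
  comb$model <- "combined"
  out <- dplyr::bind_rows(c(tabs, list(comb)))
  class(out) <- c("cdr_auc_by_year", class(out))
  out
}
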