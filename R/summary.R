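#' Baseline characteristics table with group comparison tests
#'
#' Summarizes baseline covariates and baseline cognitive scores by outcome
#' group (incident AD vs cognitively intact) in the style of a cohort
#' descriptive table: mean +/- SD with a Kruskal-Wallis H test for
#' continuous variables, counts (%) with a chi-square test (no continuity
#' correction) for categorical ones.
#'
#' @param subjects Subject table with `ad_status` (or an `outcome` column).
#' @param visits Visit table; baseline rows (`visit_year == 0`) supply the
#'   cognitive scores.
#' @param domains Character vector of score columns to summarize.
#' @return Tibble: `variable`, `level` (categorical rows), `ad`, `intact`
#'   (formatted summaries), `test`, `statistic`, `p_value`.
#' @export
cohort_summary <- function(subjects, visits,
                           domains = grep("^domain_", names(visits),
                                          value = TRUE)) {
  s <- as_tibble(subjects)
  grp <- if ("outcome" %in% names(s)) s$outcome == 1 else
    s$ad_status == "incident_AD"
  if (!any(grp) || !any(!grp)) {
    stop_bad_arg("both outcome groups must be non-empty")
  }
  base <- as_tibble(visits)[visits$visit_year == 0, c("id", domains)]
  s <- dplyr::left_join(s, base, by = "id")
  grp <- if ("outcome" %in% names(s)) s$outcome == 1 else
    s$ad_status == "incident_AD"

  fmt_cont <- function(x, g) sprintf("%.2f ± %.2f",
                                     mean(x[g], na.rm = TRUE),
                                     sd(x[g], na.rm = TRUE))
  rows <- list()
  kw_row <- function(var, x) {
    ok <- !is.na(x)
    kt <- kruskal.test(x[ok], factor(grp[ok]))
    tibble(variable = var, level = NA_character_,
           ad = fmt_cont(x, grp), intact = fmt_cont(x, !grp),
           test = "kruskal_wallis",
           statistic = unname(kt$statistic), p_value = kt$p.value)
  }
  chisq_row <- function(var, x) {
    tab <- table(factor(grp, c(TRUE, FALSE)), x)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    lv <- colnames(tab)
    hdr <- tibble(variable = var, level = lv,
                  ad = sprintf("%d (%.1f%%)", tab[1, ],
                               100 * tab[1, ] / sum(tab[1, ])),
                  intact = sprintf("%d (%.1f%%)", tab[2, ],
                                   100 * tab[2, ] / sum(tab[2, ])),
                  test = "chi_square",
                  statistic = c(unname(ct$statistic),
                                rep(NA_real_, length(lv) - 1L)),
                  p_value = c(ct$p.value, rep(NA_real_, length(lv) - 1L)))
    hdr
  }
  rows <- c(rows, list(kw_row("baseline_age", s$baseline_age)))
  rows <- c(rows, list(chisq_row("sex", s$sex)))
  rows <- c(rows, list(chisq_row("education", s$education)))
  for (d in domains) rows <- c(rows, list(kw_row(d, s[[d]])))
  dplyr::bind_rows(rows)
}
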