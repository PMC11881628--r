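#' Compute cognitive-domain composite scores from raw test scores
#'
#' Standardizes each raw test to a z-score against the cohort's mean and SD
#' and averages the available z-scores within each domain: the composite for
#' a visit and domain is the mean of the non-missing per-test z-scores, and
#' is missing only when every test in the domain is missing. When
#' `stats = "estimate"`, the standardization constants are computed from the
#' baseline visits (`visit_year == 0`) of the input cohort and returned for
#' reuse, so scores at later visits stay on the baseline scale.
#'
#' @param raw Data frame with `id`, `visit_year`, and one column per test.
#' @param test_map Tibble mapping `test` to `domain` (e.g.
#'   [cognitive_test_map()]); every non-identifier column of `raw` must be
#'   mapped.
#' @param stats `"estimate"` (default) or a tibble with columns `test`,
#'   `mean`, `sd` giving fixed standardization constants.
#' @return Tibble with `id`, `visit_year`, one composite column per domain
#'   (in `test_map` order), and the standardization table in attribute
#'   `"standardization"` (also via [composite_stats()]).
#' @examples
#' cfg <- cohort_config(n_subjects = 50)
#' cohort <- generate_cohort(cfg, seed = 1)
#' rt <- generate_raw_tests(cohort$visits, cfg, seed = 2)
#' comp <- compute_domain_composites(rt$raw, rt$test_map)
#' head(comp)
#' @export
compute_domain_composites <- function(raw, test_map, stats = "estimate") {
  id_cols <- intersect(c("id", "visit_year", "age_at_visit"), names(raw))
  test_cols <- setdiff(names(raw), id_cols)
  unmapped <- setdiff(test_cols, test_map$test)
  if (length(unmapped)) {
    stop_bad_arg("unmapped test column(s): %s", paste(unmapped, collapse = ", "))
  }
  tests <- test_map$test[test_map$test %in% test_cols]
  domains <- test_map$domain[match(tests, test_map$test)]

  if (identical(stats, "estimate")) {
    if (!"visit_year" %in% names(raw)) {
      stop_bad_arg("raw table needs a visit_year column to locate baseline visits")
    }
    base <- raw[raw$visit_year == 0, , drop = FALSE]
    stats <- tibble(
      test = tests,
      mean = vapply(tests, function(tc) mean(base[[tc]], na.rm = TRUE),
                    numeric(1), USE.NAMES = FALSE),
      sd = vapply(tests, function(tc) sd(base[[tc]], na.rm = TRUE),
                  numeric(1), USE.NAMES = FALSE))
  } else {
    stats <- as_tibble(stats)
    missing_stats <- setdiff(tests, stats$test)
    if (length(missing_stats)) {
      stop_bad_arg("standardization stats missing for test(s): %s",
                   paste(missing_stats, collapse = ", "))
    }
    stats <- stats[match(tests, stats$test), c("test", "mean", "sd")]
  }
  bad <- !is.finite(stats$sd) | stats$sd <= 0
  if (any(bad)) {
    stop_bad_arg("zero or undefined variance for test(s): %s",
                 paste(stats$test[bad], collapse = ", "))
  }

  Z <- vapply(seq_along(tests), function(k) {
    (raw[[tests[k]]] - stats$mean[k]) / stats$sd[k]
  }, numeric(nrow(raw)))
  if (nrow(raw) == 1L) Z <- matrix(Z, nrow = 1)

  out <- raw[, id_cols, drop = FALSE]
  for (d in unique(domains)) {
    zd <- Z[, domains == d, drop = FALSE]
    avail <- rowSums(!is.na(zd))
    comp <- rowMeans(zd, na.rm = TRUE)
    comp[avail == 0] <- NA_real_
    out[[d]] <- comp
  }
  out <- as_tibble(out)
  attr(out, "standardization") <- stats
  out
}

#' Retrieve the standardization constants attached to a composite table
#' @param composites Output of [compute_domain_composites()].
#' @return Tibble with `test`, `mean`, `sd`.
#' @export
composite_stats <- function(composites) {
  attr(composites, "standardization")
}
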