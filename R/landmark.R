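#' Build the landmark-year analysis dataset
#'
#' Restricts the visit history to what is visible at landmark year `t`: for
#' every subject, visits with `visit_year <= t`; for AD cases additionally
#' only visits strictly before the age of onset; and at most `max_visits`
#' visits per subject (the earliest are kept). Subjects keep their outcome
#' regardless of whether onset precedes `t` — the landmark trims the
#' predictor history, never the outcome.
#'
#' @param subjects Eligible subject table with an `outcome` column (e.g.
#'   `apply_lifetime_eligibility(...)$subjects`).
#' @param visits Visit table.
#' @param t Landmark year, 0-10 (`allow_any_landmark = TRUE` lifts the
#'   range check).
#' @param max_visits Per-subject visit cap (default 11).
#' @param allow_any_landmark Permit landmarks outside 0-10.
#' @return List of class `cdr_landmark`: `subjects`, `visits`, `t`,
#'   `max_visits`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 200), seed = 3)
#' elig <- apply_lifetime_eligibility(cohort$subjects, cohort$visits)
#' lm5 <- build_landmark_dataset(elig$subjects, cohort$visits, t = 5)
#' @export
build_landmark_dataset <- function(subjects, visits, t, max_visits = 11,
                                   allow_any_landmark = FALSE) {
  if (!allow_any_landmark && (t < 0 || t > 10)) {
    stop_bad_arg("landmark year t must be in 0..10 (or set allow_any_landmark = TRUE)")
  }
  s <- as_tibble(subjects)
  if (!"outcome" %in% names(s)) {
    s$outcome <- as.integer(s$ad_status == "incident_AD")
  }
  v <- dplyr::semi_join(as_tibble(visits), s, by = "id")
  v <- v[v$visit_year <= t, , drop = FALSE]
  onset <- if ("onset_age" %in% names(s)) {
    s$onset_age[match(v$id, s$id)]
  } else {
    rep(NA_real_, nrow(v))
  }
  v <- v[is.na(onset) | v$age_at_visit < onset, , drop = FALSE]
  v <- v |>
    dplyr::arrange(.data$id, .data$visit_year) |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_head(n = max_visits) |>
    dplyr::ungroup()
  structure(list(subjects = s, visits = v, t = t, max_visits = max_visits),
            class = "cdr_landmark")
}

#' Build the fixed-horizon exploratory dataset
#'
#' Evaluates risk of AD onset a fixed number of years after the last
#' included visit: AD cases keep visits at ages at or below
#' `onset_age - horizon`; subjects without AD keep visits within 5 years of
#' their last visit. Subjects left with no qualifying visit are dropped and
#' tallied.
#'
#' @param subjects Eligible subject table with an `outcome` column.
#' @param visits Visit table.
#' @param horizon 5 or 10 (years between last included visit and onset).
#' @param max_visits Per-subject visit cap (default 11).
#' @return List of class `cdr_landmark` with `t = NA`, `horizon`, and a
#'   `tally` of dropped subjects.
#' @export
build_horizon_dataset <- function(subjects, visits, horizon, max_visits = 11) {
  if (!horizon %in% c(5, 10)) stop_bad_arg("horizon must be 5 or 10")
  s <- as_tibble(subjects)
  if (!"outcome" %in% names(s)) {
    s$outcome <- as.integer(s$ad_status == "incident_AD")
  }
  v <- dplyr::semi_join(as_tibble(visits), s, by = "id")
  onset <- if ("onset_age" %in% names(s)) {
    s$onset_age[match(v$id, s$id)]
  } else {
    rep(NA_real_, nrow(v))
  }
  is_ad_row <- !is.na(onset)
  keep_ad <- is_ad_row & v$age_at_visit <= onset - horizon
  v_cn <- v[!is_ad_row, , drop = FALSE] |>
    dplyr::group_by(.data$id) |>
    dplyr::filter(.data$visit_year >= max(.data$visit_year) - 5) |>
    dplyr::ungroup()
  v <- dplyr::bind_rows(v[keep_ad, , drop = FALSE], v_cn) |>
    dplyr::arrange(.data$id, .data$visit_year) |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_head(n = max_visits) |>
    dplyr::ungroup()
  dropped <- setdiff(s$id, unique(v$id))
  tally <- tibble(rule = "no_qualifying_visits", n = length(dropped))
  s <- s[!s$id %in% dropped, , drop = FALSE]
  structure(list(subjects = s, visits = v, t = NA_real_, horizon = horizon,
                 max_visits = max_visits, tally = tally),
            class = "cdr_landmark")
}

#' Reduce each subject's history to a fixed number of visits
#'
#' Sensitivity-analysis design: keeps the first and last visit for every
#' subject and draws `k - 2` intermediate visits uniformly without
#' replacement. Subjects with `k` or fewer visits keep all of them.
#'
#' @param visits Visit table.
#' @param k 3 or 4.
#' @param seed Integer seed for the intermediate draws.
#' @return Visit table with at most `k` rows per subject.
#' @export
subsample_visits <- function(visits, k, seed) {
  if (!k %in% c(3, 4)) stop_bad_arg("k must be 3 or 4")
  v <- as_tibble(visits) |> dplyr::arrange(.data$id, .data$visit_year)
  local_seed(seed, {
    idx <- split(seq_len(nrow(v)), v$id)
    keep <- unlist(lapply(idx, function(rows) {
      m <- length(rows)
      if (m <= k) return(rows)
      mid <- rows[-c(1L, m)]
      sort(c(rows[1L], rows[m], sample(mid, k - 2L)))
    }), use.names = FALSE)
    v[sort(keep), , drop = FALSE]
  })
}

#' @export
print.cdr_landmark <- function(x, ...) {
  lab <- if (is.na(x$t)) sprintf("horizon %s y", x$horizon) else
    sprintf("landmark year %s", x$t)
  cat(sprintf("Landmark dataset (%s): %d subjects, %d visits, %d cases\n",
              lab, nrow(x$subjects), nrow(x$visits), sum(x$subjects$outcome)))
  invisible(x)
}
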