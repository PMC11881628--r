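# Shared fixtures: cached synthetic cohorts (generated once per test run)
# and a six-subject toy cohort small enough to trace every filter by hand.

.cdr_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.cdr_cache[[key]])) .cdr_cache[[key]] <- make()
  .cdr_cache[[key]]
}

# default-configuration cohort with eligibility applied
std_cohort <- function(n = 800, seed = 101) {
  key <- sprintf("std_%d_%d", n, seed)
  cached(key, function() {
    co <- generate_cohort(cohort_config(n_subjects = n), seed = seed)
    el <- apply_lifetime_eligibility(co$subjects, co$visits)
    list(cohort = co, subjects = el$subjects, visits = co$visits,
         tally = el$tally)
  })
}

# Six subjects covering every lifetime-eligibility rule:
#   A clean cognitively-intact; B impaired at baseline; C non-AD dementia;
#   D intact with MCI at 12 y (late); E AD with MCI at 12 y (retained: the
#   late-MCI rule applies only to non-progressors); F intact with MCI at 4 y.
toy_subjects <- function() {
  tibble::tibble(
    id = c("A", "B", "C", "D", "E", "F"),
    baseline_age = c(80, 75, 76, 77, 78, 70),
    sex = c(1, 0, 1, 1, 0, 1),
    education = c(3, 2, 1, 3, 2, 0),
    ad_status = c("cognitively_intact", "cognitively_intact",
                  "cognitively_intact", "cognitively_intact",
                  "incident_AD", "cognitively_intact"),
    onset_age = c(NA, NA, NA, NA, 84, NA),
    death_age = c(88, NA, NA, NA, 90, 84),
    last_contact_age = c(88, 75, 76, 77, 83, 80),
    mci_flag = c(NA, NA, NA, 12, 12, 4),
    non_ad_dementia_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    baseline_impaired_flag = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    cohort_label = "synthetic")
}

# Visit histories for the three subjects that survive the lifetime filter:
#   A years 0..8, E years 0..5 (ages 78..83, all before onset at 84),
#   F years 0..10.
toy_visits <- function() {
  yrs <- list(A = 0:8, E = 0:5, F = 0:10)
  ids <- rep(names(yrs), lengths(yrs))
  vy <- unlist(yrs, use.names = FALSE)
  base <- c(A = 80, E = 78, F = 70)
  tibble::tibble(
    id = ids, visit_year = vy, age_at_visit = base[ids] + vy,
    domain_1 = round(sin(seq_along(ids)), 3))
}

expect_tally <- function(filtered, expected) {
  got <- setNames(filtered$tally$n, filtered$tally$rule)
  for (rule in names(expected)) {
    expect_identical(unname(got[rule]), as.integer(expected[[rule]]),
                     label = sprintf("tally[%s]", rule))
  }
}

# exhaustive case-control pair enumeration (independent AUC oracle)
auc_by_enumeration <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  cmp <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
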