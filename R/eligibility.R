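#' Apply the lifetime-risk eligibility rules
#'
#' Filters a subject table to the analysis population for lifetime AD risk
#' (probability of developing AD before death). Rules are applied in order,
#' each subject tallied at the first rule that removes it:
#' \enumerate{
#'   \item `baseline_impaired` — MCI or dementia at the baseline visit;
#'   \item `non_ad_dementia` — developed dementia other than AD;
#'   \item `late_mci` — did not progress to AD but developed MCI more than
#'     10 years after baseline (non-progressors with MCI within 10 years
#'     are retained);
#'   \item `no_evaluations` — no clinical evaluation (no visit record);
#'   \item `missing_covariates` — sex, education or baseline age absent.
#' }
#' The filter is idempotent: applying it to its own output removes nobody.
#'
#' @param subjects Subject table (see [generate_cohort()] for the schema).
#' @param visits Visit table used for the `no_evaluations` rule.
#' @return List of class `cdr_filtered`: `subjects` (with an `outcome`
#'   column, 1 = incident AD) and `tally` (tibble `rule`, `n`).
#' @export
apply_lifetime_eligibility <- function(subjects, visits) {
  s <- as_tibble(subjects)
  removed <- rep(NA_character_, nrow(s))
  mark <- function(removed, cond, rule) {
    ifelse(is.na(removed) & cond, rule, removed)
  }
  removed <- mark(removed, isTRUE_vec(s$baseline_impaired_flag),
                  "baseline_impaired")
  removed <- mark(removed, isTRUE_vec(s$non_ad_dementia_flag),
                  "non_ad_dementia")
  removed <- mark(removed,
                  s$ad_status != "incident_AD" &
                    !is.na(s$mci_flag) & s$mci_flag > 10,
                  "late_mci")
  removed <- mark(removed, !s$id %in% unique(visits$id), "no_evaluations")
  removed <- mark(removed,
                  is.na(s$sex) | is.na(s$education) | is.na(s$baseline_age),
                  "missing_covariates")

  rules <- c("baseline_impaired", "non_ad_dementia", "late_mci",
             "no_evaluations", "missing_covariates")
  tally <- tibble(rule = rules,
                  n = vapply(rules, function(r) sum(removed == r, na.rm = TRUE),
                             integer(1)))
  out <- s[is.na(removed), , drop = FALSE]
  out$outcome <- as.integer(out$ad_status == "incident_AD")
  structure(list(subjects = out, tally = tally), class = "cdr_filtered")
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & x
}

#' Apply the age-bounded (pre-85 / pre-90) eligibility rules
#'
#' Redefines the outcome as AD onset before `age_cut`. Removes cognitively
#' intact subjects who died at or before the cut (`cn_died_before_cut`) and
#' AD subjects whose onset came after the cut (`ad_onset_after_cut`);
#' retains intact subjects surviving past the cut (outcome 0) and AD
#' subjects with onset at or before the cut (outcome 1). Intact subjects
#' with no recorded death are kept only when their last contact is already
#' past the cut; otherwise their outcome before the cut is unresolved and
#' they are removed (`unresolved_before_cut`).
#'
#' @param subjects Lifetime-eligible subject table (the `subjects` element
#'   of [apply_lifetime_eligibility()] output, or an equivalent table).
#' @param age_cut 85 or 90 (other values require `allow_any_cut = TRUE`).
#' @param allow_any_cut Permit non-standard cut ages.
#' @return List of class `cdr_filtered` with redefined `outcome` and tally.
#' @export
apply_age_bounded_eligibility <- function(subjects, age_cut,
                                          allow_any_cut = FALSE) {
  if (!allow_any_cut && !age_cut %in% c(85, 90)) {
    stop_bad_arg("age_cut must be 85 or 90 (or set allow_any_cut = TRUE)")
  }
  s <- as_tibble(subjects)
  is_ad <- s$ad_status == "incident_AD"
  removed <- rep(NA_character_, nrow(s))
  removed[!is_ad & !is.na(s$death_age) & s$death_age <= age_cut] <-
    "cn_died_before_cut"
  removed[!is_ad & is.na(s$death_age) &
            !(!is.na(s$last_contact_age) & s$last_contact_age > age_cut)] <-
    "unresolved_before_cut"
  removed[is_ad & s$onset_age > age_cut] <- "ad_onset_after_cut"

  rules <- c("cn_died_before_cut", "ad_onset_after_cut",
             "unresolved_before_cut")
  tally <- tibble(rule = rules,
                  n = vapply(rules, function(r) sum(removed == r, na.rm = TRUE),
                             integer(1)))
  out <- s[is.na(removed), , drop = FALSE]
  out$outcome <- as.integer(out$ad_status == "incident_AD" &
                              out$onset_age <= age_cut)
  structure(list(subjects = out, tally = tally), class = "cdr_filtered")
}

#' @export
print.cdr_filtered <- function(x, ...) {
  cat(sprintf("Eligible subjects: %d (%d removed)\n", nrow(x$subjects),
              sum(x$tally$n)))
  removed <- x$tally[x$tally$n > 0, ]
  if (nrow(removed)) {
    for (i in seq_len(nrow(removed))) {
      cat(sprintf("  %-22s %d\n", removed$rule[i], removed$n[i]))
    }
  }
  invisible(x)
}
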