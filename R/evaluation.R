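#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Computes the probability that a randomly chosen case outscores a randomly
#' chosen control, with ties counted one half — the rank-based Mann-Whitney
#' form of the AUC.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (0/1), same length.
#' @return AUC in \[0, 1\].
#' @examples
#' compute_auc(c(0.9, 0.1, 0.6), c(1, 0, 0))
#' @export
compute_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_bad_arg("length mismatch")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- as.integer(labels[ok])
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_bad_arg("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score of probability predictions
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; 0 for perfect predictions, bounded by 1.
#'
#' @param probs Predicted probabilities in \[0, 1\].
#' @param outcomes Binary outcomes (0/1).
#' @return The Brier score.
#' @export
brier_score <- function(probs, outcomes) {
  if (length(probs) != length(outcomes)) stop_bad_arg("length mismatch")
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    stop_bad_arg("probabilities must lie in [0, 1]")
  }
  mean((probs - as.numeric(outcomes))^2)
}

#' Decile calibration of predicted risk
#'
#' Splits subjects into deciles of predicted risk (quantile-based bins, ties
#' assigned to the lower bin) and contrasts each decile's mean predicted
#' probability with its observed event rate; the overall Brier score is
#' attached. With fewer than 10 distinct predictions the bins collapse to
#' the distinct values, with a warning.
#'
#' @param probs Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @return A tibble of class `cdr_calibration`: `bin`, `n`, `mean_predicted`,
#'   `observed_rate`; attributes `brier` and `n_total`.
#' @export
calibration_deciles <- function(probs, outcomes) {
  if (length(probs) < 10L) stop_bad_arg("need at least 10 subjects")
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    stop_bad_arg("probabilities must lie in [0, 1]")
  }
  outcomes <- as.numeric(outcomes)
  if (length(unique(probs)) < 10L) {
    warn("fewer than 10 distinct predictions; using distinct-value bins")
    bin <- match(probs, sort(unique(probs)))
  } else {
    edges <- unique(quantile(probs, probs = seq(0, 1, 0.1), type = 7))
    bin <- cut(probs, breaks = edges, include.lowest = TRUE,
               right = TRUE, labels = FALSE)
  }
  out <- tibble(bin = bin, p = probs, y = outcomes) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_predicted = mean(.data$p),
                     observed_rate = mean(.data$y), .groups = "drop")
  attr(out, "brier") <- brier_score(probs, outcomes)
  attr(out, "n_total") <- length(probs)
  class(out) <- c("cdr_calibration", class(out))
  out
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores measured on the same subjects using
#' the placement-value (structural component) covariance estimator and a
#' two-sided normal reference.
#'
#' @param scores_a,scores_b Paired score vectors on identical subjects.
#' @param labels Binary labels (0/1).
#' @return A tibble: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop_bad_arg("scores_a, scores_b and labels must have equal length")
  }
  labels <- as.integer(labels)
  cases <- labels == 1L
  n1 <- sum(cases)
  n0 <- sum(!cases)
  if (n1 == 0L || n0 == 0L) stop_bad_arg("both classes must be present")

  # Placement values: for score s, V10_i = mean_j psi(x_i, y_j) over
  # controls; V01_j = mean_i psi(x_i, y_j) over cases; psi = 1, 1/2, 0.
  placements <- function(s) {
    x <- s[cases]
    yv <- s[!cases]
    r_all <- rank(c(x, yv), ties.method = "average")
    rx <- rank(x, ties.method = "average")
    ry <- rank(yv, ties.method = "average")
    v10 <- (r_all[seq_len(n1)] - rx) / n0
    v01 <- 1 - (r_all[n1 + seq_len(n0)] - ry) / n1
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- var(pa$v10 - pb$v10)
  s01 <- var(pa$v01 - pb$v01)
  v <- s10 / n1 + s01 / n0
  d <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    if (abs(d) > 1e-12) {
      warn("zero DeLong variance with unequal AUCs; p reported as 1")
    }
    z <- 0
    p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  tibble(auc_a = pa$auc, auc_b = pb$auc, z = z, p_value = p)
}
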