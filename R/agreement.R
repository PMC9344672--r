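# Agreement between the two relapse criteria: percent agreement with a
# Wilson 95% interval and Cohen's kappa with the Fleiss-Cohen-Everitt
# large-sample standard error.

wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ctr - hw, ctr + hw)
}

# large-sample variance of Cohen's kappa (Fleiss, Cohen & Everitt 1969),
# written for the general square table; p is the joint proportion matrix
kappa_se <- function(p, n) {
  pi_ <- rowSums(p)
  p_j <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pi_ * p_j)
  k <- (po - pe) / (1 - pe)
  a <- sum(diag(p) * (1 - (pi_ + p_j) * (1 - k))^2)
  b <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (i != j) b <- b + p[i, j] * (p_j[i] + pi_[j])^2
  }
  b <- (1 - k)^2 * b
  cc <- (k - pe * (1 - k))^2
  sqrt((a + b - cc) / (n * (1 - pe)^2))
}

agreement_from_table <- function(n11, n10, n01, n00, conf = 0.95,
                                 labels = c("RJ", "TI")) {
  n <- n11 + n10 + n01 + n00
  if (n <= 0) pmr_stop("pmr_empty_error", "agreement: empty contingency table")
  tab <- matrix(c(n11, n01, n10, n00), 2, 2,
                dimnames = list(c("pos", "neg"), c("pos", "neg")))
  names(dimnames(tab)) <- labels
  p <- tab / n
  po <- (n11 + n00) / n
  a_pos <- n11 + n10
  b_pos <- n11 + n01
  pe <- (a_pos * b_pos + (n - a_pos) * (n - b_pos)) / n^2
  pe_neg <- (n - a_pos) * (n - b_pos) / n^2
  if (pe >= 1) {
    pmr_stop("pmr_degenerate_error",
             "agreement: degenerate marginals (expected chance agreement = 1), kappa undefined")
  }
  kap <- (po - pe) / (1 - pe)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- kappa_se(p, n)
  structure(list(
    table = tab, n = n, po = po, pe = pe, pe_negative_cell = pe_neg,
    kappa = kap, kappa_se = se,
    po_ci = wilson_ci(n11 + n00, n, conf),
    kappa_ci = c(kap - z * se, kap + z * se),
    conf = conf, labels = labels
  ), class = "pmr_agreement")
}

#' Kappa and chance agreement from printed marginals
#'
#' Recovers the full agreement decomposition from summary numbers alone:
#' the number of units, the positive count under each criterion, and the
#' observed proportion of agreement. Useful for desk-checking published
#' agreement statistics, since for two binary raters
#' `pe = (a+ b+ + a- b-) / N^2` and `kappa = (po - pe) / (1 - pe)` depend
#' only on these marginals.
#'
#' @param total number of classified units.
#' @param a_pos,b_pos positive counts under criteria A and B.
#' @param po observed agreement proportion.
#' @return list with `pe` (expected chance agreement),
#'   `pe_negative_cell` (the double-negative cell's contribution to `pe`)
#'   and `kappa`.
#' @examples
#' # visit-level agreement of the two relapse criteria from marginal counts
#' kappa_from_marginals(2422, 399, 321, 0.87)
#' @export
kappa_from_marginals <- function(total, a_pos, b_pos, po) {
  if (a_pos > total || b_pos > total || a_pos < 0 || b_pos < 0) {
    pmr_stop("pmr_contract_error", "kappa_from_marginals: marginals must lie in [0, total]")
  }
  if (!is_probability(po)) {
    pmr_stop("pmr_contract_error", "kappa_from_marginals: po must be a probability")
  }
  # implied diagonal cells: n11 = (a+ + b+ - N(1-po))/2 must be feasible
  n11 <- (a_pos + b_pos - total * (1 - po)) / 2
  n00 <- total * po - n11
  if (n11 < -1e-9 || n00 < -1e-9 || n11 > min(a_pos, b_pos) + 1e-9) {
    pmr_stop("pmr_contract_error",
             "kappa_from_marginals: marginals and po imply negative cell counts")
  }
  pe <- (a_pos * b_pos + (total - a_pos) * (total - b_pos)) / total^2
  pe_neg <- (total - a_pos) * (total - b_pos) / total^2
  if (pe >= 1) {
    pmr_stop("pmr_degenerate_error",
             "kappa_from_marginals: degenerate marginals (expected chance agreement = 1)")
  }
  list(pe = pe, pe_negative_cell = pe_neg, kappa = (po - pe) / (1 - pe))
}

#' Visit-level agreement between the RJ and TI relapse criteria
#'
#' Cross-classifies the debounced RJ and TI relapse flags over all eligible
#' visits of the cohort and returns percent agreement (Wilson 95% CI),
#' expected chance agreement with its double-negative component, and
#' Cohen's kappa with an asymptotic 95% CI.
#'
#' @param adjudicated output of [adjudicate()].
#' @param conf confidence level.
#' @return an object of class `"pmr_agreement"`.
#' @export
visit_level_agreement <- function(adjudicated, conf = 0.95) {
  el <- adjudicated[!is.na(adjudicated$rj_relapse), , drop = FALSE]
  if (nrow(el) == 0L) {
    pmr_stop("pmr_empty_error", "visit_level_agreement: no eligible visits")
  }
  rj <- el$rj_relapse
  ti <- el$ti_relapse
  agreement_from_table(sum(rj & ti), sum(rj & !ti), sum(!rj & ti), sum(!rj & !ti),
                       conf = conf, labels = c("RJ", "TI"))
}

#' Patient-level agreement on cumulative relapse within a horizon
#'
#' A patient is positive under a criterion iff they have at least one
#' adjudicated relapse with `event_day <= horizon * 365.25`. The RJ and TI
#' positivity indicators are then cross-classified over all patients.
#'
#' @param events_rj,events_ti event streams from [relapse_events()].
#' @param patients patient table (defines the denominator).
#' @param horizon horizon in years (default 1).
#' @param conf confidence level.
#' @return an object of class `"pmr_agreement"`.
#' @export
patient_level_agreement <- function(events_rj, events_ti, patients,
                                    horizon = 1, conf = 0.95) {
  if (nrow(patients) == 0L) {
    pmr_stop("pmr_empty_error", "patient_level_agreement: empty cohort")
  }
  if (!is_scalar_number(horizon) || horizon <= 0) {
    pmr_stop("pmr_contract_error", "patient_level_agreement: horizon must be positive")
  }
  cut <- horizon * DAYS_PER_YEAR
  pos <- function(ev) patients$patient_id %in% ev$patient_id[ev$event_day <= cut]
  rj <- pos(events_rj)
  ti <- pos(events_ti)
  agreement_from_table(sum(rj & ti), sum(rj & !ti), sum(!rj & ti), sum(!rj & !ti),
                       conf = conf, labels = c("RJ", "TI"))
}

#' @export
print.pmr_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("Agreement between %s and %s (n = %d)\n",
              x$labels[1], x$labels[2], x$n))
  print(x$table)
  cat(sprintf("  observed agreement: %.0f%% (%.0f%% CI %.2f-%.2f)\n",
              100 * x$po, 100 * x$conf, x$po_ci[1], x$po_ci[2]))
  cat(sprintf("  chance agreement:   %.3f (double-negative cell %.0f%%)\n",
              x$pe, 100 * x$pe_negative_cell))
  cat(sprintf("  Cohen's kappa:      %.*f (%.0f%% CI %.2f-%.2f)\n",
              digits, x$kappa, 100 * x$conf, x$kappa_ci[1], x$kappa_ci[2]))
  invisible(x)
}
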