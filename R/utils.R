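# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed package error
#'
#' All user-facing failures raise conditions subclassed under `"pmr_error"`,
#' so callers can distinguish configuration errors, parse errors, integrity
#' errors and degenerate-input errors programmatically.
#'
#' @param class condition subclass, e.g. `"pmr_config_error"`.
#' @param message human-readable message.
#' @noRd
pmr_stop <- function(class, message) {
  stop(errorCondition(message, class = c(class, "pmr_error", "error", "condition")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# weeks -> months conversion used for the symptom-duration predictor
WEEKS_PER_MONTH <- 4.345

DAYS_PER_YEAR <- 365.25

# inverse logit
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Concordance statistic (area under the ROC curve)
#'
#' Rank-based c-statistic: the probability that a randomly chosen positive
#' case has a higher score than a randomly chosen negative case, ties
#' counting 1/2. Equivalent to the Wilcoxon/Mann-Whitney estimator of the
#' AUC.
#'
#' @param score numeric risk scores (higher = more likely positive).
#' @param y logical or 0/1 outcome vector.
#' @return AUC in `[0, 1]`.
#' @export
cstat <- function(score, y) {
  y <- as.logical(y)
  if (anyNA(score) || anyNA(y)) pmr_stop("pmr_contract_error", "cstat: missing values in score or outcome")
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    pmr_stop("pmr_degenerate_error", "cstat: outcome has only one class")
  }
  r <- rank(score)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
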