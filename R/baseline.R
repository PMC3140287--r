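#' Solve the baseline per-case thrombosis risk
#'
#' A patient without any panel condition thromboses with probability p0; a
#' carrier of condition i thromboses with probability min(RR_i * p0, K),
#' where K is the per-condition risk cap. p0 is chosen so that the cohort
#' average risk equals the observed complication rate r:
#'
#'   sum_i pi_i * min(RR_i * p0, K) + (1 - sum_i pi_i) * p0 = r
#'
#' The left side is continuous and strictly increasing in p0 (each summand is
#' nondecreasing and the non-carrier term strictly increasing), so the root
#' is unique. The cap makes the balance function piecewise linear with kinks
#' at K / RR_i, so it is solved numerically ([stats::uniroot()] at absolute
#' tolerance 1e-12) rather than by a closed form.
#'
#' @param panel a [thrombo_panel()]
#' @param params a [model_params()] list
#' @param tol absolute solver tolerance on p0
#' @return list of class `baseline_risk` with `p0`, `cap_active` (names of
#'   conditions whose per-carrier risk is capped), and `residual` (absolute
#'   balance-equation mismatch at p0)
#' @examples
#' solve_baseline_risk(default_panel(), default_params())$p0  # ~0.01798
#' @export
solve_baseline_risk <- function(panel, params, tol = 1e-12) {
  r <- params$complication_rate
  K <- params$risk_cap
  if (nrow(panel) == 0) {
    return(structure(list(p0 = r, cap_active = character(0), residual = 0),
                     class = "baseline_risk"))
  }
  pi_ <- panel$prevalence
  rr <- panel$relative_risk
  balance <- function(p) sum(pi_ * pmin(rr * p, K)) + (1 - sum(pi_)) * p - r
  # If every carrier risk were capped the cohort mean would still have to
  # reach r through the non-carrier term; upper bracket covers that extreme.
  hi <- r / (1 - sum(pi_))
  if (balance(0) > 0 || balance(hi) < 0)
    abort_tf("infeasible parameters: no baseline risk solves the balance equation")
  root <- stats::uniroot(balance, lower = 0, upper = hi, tol = tol)
  p0 <- root$root
  structure(list(p0 = p0,
                 cap_active = panel$name[rr * p0 >= K],
                 residual = abs(balance(p0))),
            class = "baseline_risk")
}

#' @export
print.baseline_risk <- function(x, ...) {
  cat(sprintf("Baseline per-case thrombosis risk p0 = %.6g (residual %.2e)\n",
              x$p0, x$residual))
  if (length(x$cap_active))
    cat("Risk cap active for:", paste(x$cap_active, collapse = ", "), "\n")
  invisible(x)
}

#' Per-condition model predictions
#'
#' For each condition in the panel, derives (all unrounded):
#' \describe{
#'   \item{per_carrier_risk}{min(RR_i * p0, K)}
#'   \item{expected_carriers}{N * pi_i}
#'   \item{expected_complications}{carriers times per-carrier risk}
#'   \item{detected_complications}{expected complications times assay
#'     sensitivity: the complications occurring in carriers a screen would
#'     find}
#'   \item{expected_test_positives}{N * pi_i * s_i}
#' }
#'
#' @param panel a `thrombo_panel`
#' @param params a `model_params` list
#' @param baseline a solved [solve_baseline_risk()] result
#' @return data.frame of class `condition_predictions`, one row per condition
#' @export
predict_conditions <- function(panel, params, baseline) {
  N <- params$cohort_size
  rho <- pmin(panel$relative_risk * baseline$p0, params$risk_cap)
  carriers <- N * panel$prevalence
  m <- carriers * rho
  out <- data.frame(name = panel$name,
                    per_carrier_risk = rho,
                    expected_carriers = carriers,
                    expected_complications = m,
                    detected_complications = panel$sensitivity * m,
                    expected_test_positives = carriers * panel$sensitivity,
                    stringsAsFactors = FALSE)
  class(out) <- c("condition_predictions", "data.frame")
  out
}

#' Expected screen-positive patients under the full panel
#'
#' N times the sum over conditions of prevalence times sensitivity. With no
#' false positives modelled (assay specificity fixed at 1), this is the
#' expected number of patients put on prophylaxis when every condition is
#' screened.
#'
#' @inheritParams predict_conditions
#' @return expected count, unrounded
#' @export
total_test_positive <- function(panel, params) {
  params$cohort_size * sum(panel$prevalence * panel$sensitivity)
}

#' Fraction and absolute rate of complications attributable to thrombophilia
#'
#' By default uses detected complications (sensitivity-weighted), the basis
#' on which the screening panel can act; `basis = "expected"` uses the raw
#' expected complications among carriers regardless of detectability.
#'
#' @param predictions output of [predict_conditions()]
#' @param params a `model_params` list
#' @param basis `"detected"` (default) or `"expected"`
#' @return list with `attributable_fraction` (share of all complications) and
#'   `absolute_rate` (share of all cases)
#' @export
attributable_summary <- function(predictions, params,
                                 basis = c("detected", "expected")) {
  basis <- match.arg(basis)
  tot <- if (basis == "detected") sum(predictions$detected_complications)
         else sum(predictions$expected_complications)
  N <- params$cohort_size
  list(attributable_fraction = tot / (N * params$complication_rate),
       absolute_rate = tot / N)
}

#' Select a limited screening panel
#'
#' Ranks conditions by model-predicted detected complications (descending;
#' ties broken by lower assay cost, then name) and keeps either the top `k`
#' conditions or the smallest prefix whose cumulative detected complications
#' reach `capture_target` of the panel total.
#'
#' @param predictions output of [predict_conditions()]
#' @param panel the `thrombo_panel` the predictions came from
#' @param k number of conditions to keep (exclusive with `capture_target`)
#' @param capture_target fraction in (0, 1] of detected complications the
#'   limited panel must capture
#' @return the `thrombo_panel` subset, with attributes `capture_fraction` and
#'   `panel_cost`
#' @examples
#' params <- default_params(); panel <- default_panel()
#' pred <- predict_conditions(panel, params, solve_baseline_risk(panel, params))
#' lim <- select_limited_panel(pred, panel, k = 5)
#' attr(lim, "panel_cost")        # 572
#' attr(lim, "capture_fraction")  # ~0.87
#' @export
select_limited_panel <- function(predictions, panel, k = NULL,
                                 capture_target = NULL) {
  if (is.null(k) == is.null(capture_target))
    abort_tf("supply exactly one of k or capture_target")
  ord <- order(-predictions$detected_complications, panel$assay_cost,
               panel$name)
  d_sorted <- predictions$detected_complications[ord]
  total <- sum(d_sorted)
  if (!is.null(k)) {
    if (!is_count(k) || k < 1 || k > nrow(panel))
      abort_tf("k must be an integer in 1..", nrow(panel))
    keep <- ord[seq_len(k)]
  } else {
    if (!is.numeric(capture_target) || capture_target <= 0 ||
        capture_target > 1)
      abort_tf("capture_target must lie in (0, 1]")
    cum <- cumsum(d_sorted) / total
    keep <- ord[seq_len(which(cum >= capture_target - 1e-12)[1])]
  }
  sub <- panel[sort(keep), , drop = FALSE]
  rownames(sub) <- NULL
  class(sub) <- c("thrombo_panel", "data.frame")
  attr(sub, "capture_fraction") <-
    sum(predictions$detected_complications[keep]) / total
  attr(sub, "panel_cost") <- sum(panel$assay_cost[keep])
  sub
}
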