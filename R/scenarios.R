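#' Define an intervention scenario
#'
#' Three shapes exist: the baseline (no screening, no prophylaxis), a
#' screening scenario (screen every patient for a subset of conditions and
#' give prophylaxis to positives), and all-therapy (no screen, everyone gets
#' prophylaxis).
#'
#' @param name scenario label
#' @param screened_conditions character vector of condition names to screen
#'   for; empty for baseline and all-therapy
#' @param treat_all logical; TRUE only for all-therapy
#' @return list of class `scenario_spec`
#' @export
scenario_spec <- function(name, screened_conditions = character(0),
                          treat_all = FALSE) {
  if (treat_all && length(screened_conditions) > 0)
    abort_tf("treat_all scenarios do not screen")
  structure(list(name = name,
                 screened_conditions = as.character(screened_conditions),
                 treat_all = isTRUE(treat_all)),
            class = "scenario_spec")
}

#' Evaluate a scenario on the cohort
#'
#' Per-patient accounting: every patient pays the screening cost S (sum of
#' assay costs over the screened subset); therapy cost accrues to expected
#' test positives, so the per-patient therapy cost is
#' A = C_rx * sum over screened i of pi_i * s_i (or C_rx itself under
#' treat_all). Expected complications are
#' X = N * r - e * sum over screened i of D_i: false negatives and carriers of
#' unscreened conditions retain their full risk, and prophylaxis averts a
#' fraction e of the detected complications. Under treat_all,
#' X = N * r * (1 - e).
#'
#' @param spec a [scenario_spec()]
#' @param panel the full `thrombo_panel`
#' @param params a `model_params` list
#' @param baseline a solved [solve_baseline_risk()] result
#' @return list of class `scenario_result` with `name`, `screening_cost`
#'   (S, per patient), `therapy_cost` (A, per patient), `expected_complications`
#'   (X, unrounded), `cost_per_patient_at` (function of complication cost C:
#'   S + A + X * C / N), and `evaluated_cost_per_patient` at C = the params'
#'   complication cost
#' @examples
#' params <- default_params(); panel <- default_panel()
#' bl <- solve_baseline_risk(panel, params)
#' evaluate_scenario(scenario_spec("All therapy", treat_all = TRUE),
#'                   panel, params, bl)$expected_complications  # 58.8
#' @export
evaluate_scenario <- function(spec, panel, params, baseline) {
  N <- params$cohort_size
  r <- params$complication_rate
  e <- params$therapy_efficacy
  x_base <- N * r
  if (spec$treat_all) {
    S <- 0
    A <- params$therapy_cost
    X <- x_base * (1 - e)
  } else if (length(spec$screened_conditions) == 0) {
    S <- 0
    A <- 0
    X <- x_base
  } else {
    idx <- match(spec$screened_conditions, panel$name)
    if (anyNA(idx))
      abort_tf("unknown conditions in scenario: ",
               paste(spec$screened_conditions[is.na(idx)], collapse = ", "))
    pred <- predict_conditions(panel, params, baseline)
    S <- sum(panel$assay_cost[idx])
    A <- params$therapy_cost *
      sum(panel$prevalence[idx] * panel$sensitivity[idx])
    X <- x_base - e * sum(pred$detected_complications[idx])
  }
  cost_at <- function(C) S + A + X * C / N
  structure(list(name = spec$name, screening_cost = S, therapy_cost = A,
                 expected_complications = X,
                 cost_per_patient_at = cost_at,
                 evaluated_cost_per_patient = cost_at(params$complication_cost)),
            class = "scenario_result")
}

#' Break-even complication cost of a scenario against baseline
#'
#' The complication cost C* at which the scenario's per-patient cost equals
#' the baseline's: C* = (S + A - S0 - A0) / ((X0 - X) / N). Reported values
#' are rounded to the nearest $1000; the unrounded value is always returned.
#'
#' @param scenario,baseline `scenario_result` objects
#' @param params a `model_params` list
#' @return list with `unrounded` and `reported` dollars
#' @export
break_even <- function(scenario, baseline, params) {
  dX <- baseline$expected_complications - scenario$expected_complications
  if (dX <= 0)
    abort_tf("no break-even: scenario averts no complications relative to baseline")
  dfix <- (scenario$screening_cost + scenario$therapy_cost) -
    (baseline$screening_cost + baseline$therapy_cost)
  cstar <- dfix / (dX / params$cohort_size)
  # sanity: per-patient costs coincide at C*
  gap <- scenario$cost_per_patient_at(cstar) - baseline$cost_per_patient_at(cstar)
  stopifnot(abs(gap) <= 1e-6 * max(1, abs(cstar)))
  list(unrounded = cstar, reported = round_to_unit(cstar, 1000))
}

#' Incremental cost-effectiveness ratio against baseline
#'
#' Dollars spent per avoided thrombotic complication at the configured
#' complication cost:
#' ICER = (N * (S + A - S0 - A0) - (X0 - X) * C_comp) / (X0 - X),
#' which is identically the unrounded break-even cost minus C_comp.
#'
#' @inheritParams break_even
#' @return ICER in dollars per avoided complication, unrounded
#' @export
icer <- function(scenario, baseline, params) {
  dX <- baseline$expected_complications - scenario$expected_complications
  if (dX <= 0)
    abort_tf("ICER undefined: scenario averts no complications relative to baseline")
  dfix <- (scenario$screening_cost + scenario$therapy_cost) -
    (baseline$screening_cost + baseline$therapy_cost)
  (params$cohort_size * dfix - dX * params$complication_cost) / dX
}

#' Per-patient cost as a function of complication cost
#'
#' Evaluates each scenario's affine per-patient cost line over a grid of
#' complication costs, the data behind the break-even figure.
#'
#' @param scenarios list of `scenario_result` objects
#' @param params a `model_params` list
#' @param c_grid nonnegative complication costs to evaluate
#' @return data.frame with columns `scenario`, `complication_cost`,
#'   `cost_per_patient`
#' @export
cost_sweep <- function(scenarios, params, c_grid) {
  if (length(c_grid) == 0) abort_tf("empty complication-cost grid")
  if (any(c_grid < 0)) abort_tf("complication costs must be >= 0")
  do.call(rbind, lapply(scenarios, function(sc)
    data.frame(scenario = sc$name, complication_cost = c_grid,
               cost_per_patient = vapply(c_grid, sc$cost_per_patient_at,
                                         numeric(1)))))
}

#' The four published scenarios
#'
#' Builds and evaluates Baseline, Full panel, Limited panel (top `k`
#' conditions by detected complications) and All therapy, returning both the
#' raw results and a summary table with break-even points and ICERs.
#'
#' @param panel the full `thrombo_panel`
#' @param params a `model_params` list
#' @param limited_k size of the limited panel
#' @return list with `results` (named list of `scenario_result`) and `table`
#'   (data.frame: scenario, screening/therapy cost, expected complications
#'   unrounded and displayed, per-patient cost at the configured complication
#'   cost, break-even unrounded/reported, ICER)
#' @export
standard_scenarios <- function(panel, params, limited_k = 5) {
  bl_risk <- solve_baseline_risk(panel, params)
  pred <- predict_conditions(panel, params, bl_risk)
  limited <- select_limited_panel(pred, panel, k = limited_k)
  specs <- list(
    scenario_spec("Baseline"),
    scenario_spec("Full panel", screened_conditions = panel$name),
    scenario_spec("Limited panel", screened_conditions = limited$name),
    scenario_spec("All therapy", treat_all = TRUE)
  )
  results <- lapply(specs, evaluate_scenario, panel = panel, params = params,
                    baseline = bl_risk)
  names(results) <- vapply(results, `[[`, character(1), "name")
  base <- results[["Baseline"]]
  rows <- lapply(results, function(sc) {
    is_base <- sc$name == "Baseline"
    be <- if (is_base) list(unrounded = NA_real_, reported = NA_real_)
          else break_even(sc, base, params)
    data.frame(scenario = sc$name,
               screening_cost = sc$screening_cost,
               therapy_cost = sc$therapy_cost,
               expected_complications = sc$expected_complications,
               complications_displayed =
                 round_half_up(sc$expected_complications),
               cost_per_patient = sc$evaluated_cost_per_patient,
               break_even_unrounded = be$unrounded,
               break_even_reported = be$reported,
               icer = if (is_base) NA_real_ else icer(sc, base, params))
  })
  list(results = results, baseline_risk = bl_risk, predictions = pred,
       limited_panel = limited, table = do.call(rbind, rows))
}
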