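#' Patient-level Monte-Carlo simulation of a scenario
#'
#' Simulates the same generative assumptions the deterministic model takes
#' expectations over, as a brute-force check and a tool for exploring
#' sampling variability. Per patient: a condition (or none) is drawn from the
#' categorical distribution over prevalences; the per-case thrombosis risk is
#' the capped per-carrier risk for carriers and p0 otherwise; if the scenario
#' screens the patient's condition they test positive with the assay
#' sensitivity; treated patients (positives, or everyone under treat_all)
#' have their risk multiplied by one minus the therapy efficacy; one
#' Bernoulli draw decides the complication. Costs accumulate as in the
#' deterministic accounting (screening for all, therapy for the treated,
#' complication cost per event).
#'
#' Each replicate uses its own stream seeded `seed + replicate - 1`, so a
#' fixed seed replays bit-identically and replicates are independent.
#'
#' @param spec a [scenario_spec()]
#' @param panel the full `thrombo_panel`
#' @param params a `model_params` list
#' @param baseline a solved [solve_baseline_risk()] result
#' @param n_patients patients per replicate
#' @param n_replicates number of independent replicates
#' @param seed integer seed
#' @return list of class `sim_result`: for complications, test positives,
#'   treated count and total cost, the replicate mean and standard error;
#'   plus `per_condition` mean complication counts and the per-replicate
#'   draws in `replicates`
#' @export
simulate_cohort <- function(spec, panel, params, baseline,
                            n_patients = 10000, n_replicates = 1,
                            seed = 1) {
  if (!is_count(n_patients)) abort_tf("n_patients must be a nonnegative integer")
  if (!is_count(n_replicates) || n_replicates < 1)
    abort_tf("n_replicates must be a positive integer")
  m <- nrow(panel)
  probs <- c(panel$prevalence, 1 - sum(panel$prevalence))
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12)
    abort_tf("invalid condition probabilities")
  rho <- c(pmin(panel$relative_risk * baseline$p0, params$risk_cap),
           baseline$p0)
  if (any(rho < 0 | rho > 1)) abort_tf("per-case risks outside [0, 1]")
  screened <- if (spec$treat_all) rep(FALSE, m)
              else panel$name %in% spec$screened_conditions
  sens <- panel$sensitivity
  S <- if (spec$treat_all) 0 else sum(panel$assay_cost[screened])
  e <- params$therapy_efficacy

  one_rep <- function(rep_seed) {
    set.seed(rep_seed)
    if (n_patients == 0) {
      return(c(complications = 0, test_positive = 0, treated = 0,
               total_cost = 0, rep(0, m)))
    }
    # condition index m+1 = no thrombophilia
    cond <- sample.int(m + 1, n_patients, replace = TRUE, prob = probs)
    is_carrier <- cond <= m
    positive <- rep(FALSE, n_patients)
    if (any(screened)) {
      scr <- is_carrier & screened[pmin(cond, m)]
      positive[scr] <- stats::runif(sum(scr)) < sens[cond[scr]]
    }
    treated <- if (spec$treat_all) rep(TRUE, n_patients) else positive
    risk <- rho[cond]
    risk[treated] <- risk[treated] * (1 - e)
    comp <- stats::runif(n_patients) < risk
    per_cond <- vapply(seq_len(m), function(i) sum(comp & cond == i),
                       numeric(1))
    total_cost <- n_patients * S + sum(treated) * params$therapy_cost +
      sum(comp) * params$complication_cost
    c(complications = sum(comp), test_positive = sum(positive),
      treated = sum(treated), total_cost = total_cost, per_cond)
  }

  draws <- vapply(seq_len(n_replicates) - 1L, function(k) one_rep(seed + k),
                  numeric(4 + m))
  draws <- t(draws)
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  summ <- function(j) c(mean = mean(draws[, j]), se = se(draws[, j]))
  per_condition <- if (m > 0) {
    data.frame(name = panel$name,
               mean_complications = colMeans(draws[, 4 + seq_len(m),
                                                   drop = FALSE]))
  } else data.frame(name = character(), mean_complications = numeric())
  structure(list(scenario = spec$name, n_patients = n_patients,
                 n_replicates = n_replicates, seed = seed,
                 complications = summ(1), test_positive = summ(2),
                 treated = summ(3), total_cost = summ(4),
                 per_condition = per_condition,
                 replicates = draws[, 1:4, drop = FALSE]),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Microsimulation '%s': %d x %d patients (seed %d)\n",
              x$scenario, x$n_replicates, x$n_patients, x$seed))
  cat(sprintf("  complications %.2f (se %.2f), test positive %.2f, treated %.2f\n",
              x$complications["mean"], x$complications["se"],
              x$test_positive["mean"], x$treated["mean"]))
  invisible(x)
}
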