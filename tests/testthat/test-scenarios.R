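params <- default_params()
panel <- default_panel()
bl <- solve_baseline_risk(panel, params)
pred <- predict_conditions(panel, params, bl)
scen <- standard_scenarios(panel, params)
base <- scen$results[["Baseline"]]

test_that("scenario expectations match the published cohort counts", {
  expect_equal(base$expected_complications, 490)
  expect_equal(base$screening_cost + base$therapy_cost, 0)
  at <- scen$results[["All therapy"]]
  expect_equal(at$expected_complications, 58.8)
  expect_equal(round_half_up(at$expected_complications), 59)
  expect_equal(at$therapy_cost, 2100)
  # reconstruction gives ~171.7 / ~213.0 (printed table shows 171 / 212)
  expect_equal(scen$results[["Full panel"]]$expected_complications, 171.74,
               tolerance = 1e-4)
  expect_equal(scen$results[["Limited panel"]]$expected_complications, 213.04,
               tolerance = 1e-4)
  expect_equal(scen$results[["Full panel"]]$screening_cost, 1206)
  expect_equal(scen$results[["Limited panel"]]$screening_cost, 572)
})

test_that("scenario edge cases behave", {
  perfect <- model_params(therapy_efficacy = 1)
  at <- evaluate_scenario(scenario_spec("all", treat_all = TRUE), panel,
                          perfect, solve_baseline_risk(panel, perfect))
  expect_equal(at$expected_complications, 0)
  expect_error(evaluate_scenario(
    scenario_spec("bad", screened_conditions = "no such condition"),
    panel, params, bl), "unknown conditions")
  expect_error(scenario_spec("x", screened_conditions = "a", treat_all = TRUE),
               "do not screen")
})

test_that("break-even points reproduce the published thresholds", {
  be_at <- break_even(scen$results[["All therapy"]], base, params)
  expect_equal(be_at$unrounded, 2100 / (0.88 * 0.049), tolerance = 1e-9)
  expect_equal(be_at$reported, 49000)
  expect_equal(break_even(scen$results[["Limited panel"]], base,
                          params)$reported, 39000)
  expect_equal(break_even(scen$results[["Full panel"]], base,
                          params)$reported, 57000)
  expect_error(break_even(base, base, params), "no break-even")
})

test_that("ICERs reproduce and obey the break-even identity", {
  expect_equal(icer(scen$results[["All therapy"]], base, params), 25455.3,
               tolerance = 1e-4)
  expect_equal(icer(scen$results[["Full panel"]], base, params), 33707,
               tolerance = 1e-3)
  expect_equal(icer(scen$results[["Limited panel"]], base, params), 15755,
               tolerance = 1e-3)
  free <- model_params(complication_cost = 0)
  sc <- evaluate_scenario(scenario_spec("all", treat_all = TRUE), panel, free,
                          solve_baseline_risk(panel, free))
  b0 <- evaluate_scenario(scenario_spec("Baseline"), panel, free,
                          solve_baseline_risk(panel, free))
  expect_equal(icer(sc, b0, free), break_even(sc, b0, free)$unrounded)
})

test_that("ICER identity holds on random panels", {
  for (seed in 101:115) {
    pan <- generate_random_panel(m = 6, seed = seed)
    blr <- solve_baseline_risk(pan, params)
    b <- evaluate_scenario(scenario_spec("Baseline"), pan, params, blr)
    sc <- evaluate_scenario(
      scenario_spec("screen", screened_conditions = pan$name[1:3]),
      pan, params, blr)
    be <- break_even(sc, b, params)
    expect_equal(icer(sc, b, params), be$unrounded - params$complication_cost,
                 tolerance = 1e-9)
    # universal prophylaxis always averts at least as much as any screen
    at <- evaluate_scenario(scenario_spec("all", treat_all = TRUE), pan,
                            params, blr)
    expect_lte(at$expected_complications, sc$expected_complications + 1e-9)
  }
})

test_that("cost sweep lines are affine with slope X/N", {
  grid <- c(0, 23246, 60000)
  sw <- cost_sweep(scen$results, params, grid)
  for (nm in names(scen$results)) {
    rows <- sw[sw$scenario == nm, ]
    expect_equal(diff(rows$cost_per_patient) / diff(rows$complication_cost),
                 rep(scen$results[[nm]]$expected_complications /
                       params$cohort_size, 2))
    expect_true(all(diff(rows$cost_per_patient) > 0))
  }
  # at C = 0, scenarios order by fixed cost
  at0 <- sw[sw$complication_cost == 0, ]
  fixed <- vapply(scen$results,
                  function(s) s$screening_cost + s$therapy_cost, numeric(1))
  expect_equal(at0$cost_per_patient[order(at0$scenario)],
               unname(fixed[order(names(fixed))]))
  # inserting the exact break-even cost makes the two lines cross
  cstar <- break_even(scen$results[["Full panel"]], base, params)$unrounded
  sw2 <- cost_sweep(scen$results[c("Baseline", "Full panel")], params, cstar)
  expect_equal(sw2$cost_per_patient[1], sw2$cost_per_patient[2])
  expect_error(cost_sweep(scen$results, params, numeric(0)), "empty")
})

test_that("scenario summary table is internally consistent", {
  tab <- scen$table
  expect_equal(tab$complications_displayed,
               round_half_up(tab$expected_complications))
  expect_equal(tab$complications_displayed[match(
    c("Baseline", "Full panel", "Limited panel", "All therapy"),
    tab$scenario)], c(490, 172, 213, 59))
  expect_true(all(is.na(tab$icer[tab$scenario == "Baseline"])))
  expect_equal(tab$break_even_reported[tab$scenario == "All therapy"], 49000)
})
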