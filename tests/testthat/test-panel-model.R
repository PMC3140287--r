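params <- default_params()
panel <- default_panel()

test_that("panel constructor enforces its invariants", {
  expect_error(thrombo_panel("a", 1.2, 2, 1, 10), "\\(0, 1\\)")
  expect_error(thrombo_panel(c("a", "a"), c(0.1, 0.1), c(2, 2), c(1, 1),
                             c(10, 10)), "unique")
  expect_error(thrombo_panel(c("a", "b"), c(0.6, 0.5), c(2, 2), c(1, 1),
                             c(10, 10)), "mutually exclusive")
  expect_error(thrombo_panel("a", 0.1, 0.5, 1, 10), ">= 1")
  expect_error(thrombo_panel("a", 0.1, 2, 0, 10), "\\(0, 1\\]")
})

test_that("panel CSV round-trips through percent units", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(panel, tmp)
  back <- read_panel_csv(tmp)
  expect_equal(back, panel, ignore_attr = TRUE)
  expect_equal(panel_cost(panel), 1206)
})

test_that("params config reads YAML and JSON and validates ranges", {
  expect_equal(params$cohort_size, 10000)
  expect_equal(params$complication_rate, 0.049)
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(complication_rate = 0.03, therapy_cost = 1000),
                       tmp, auto_unbox = TRUE)
  p2 <- read_params(tmp)
  expect_equal(p2$complication_rate, 0.03)
  expect_equal(p2$therapy_cost, 1000)
  expect_equal(p2$risk_cap, 0.5) # default fills in
  expect_error(model_params(complication_rate = 0.6, risk_cap = 0.5),
               "below the risk cap")
  bad <- validate_inputs(panel, list(complication_rate = 0.6, risk_cap = 0.5,
                                     therapy_efficacy = 0.88))
  expect_false(all(bad$ok))
  expect_true(all(validate_inputs(panel, params)$ok))
})

test_that("baseline solve degenerates correctly for trivial panels", {
  empty <- thrombo_panel(character(), numeric(), numeric(), numeric(),
                         numeric())
  expect_equal(solve_baseline_risk(empty, params)$p0, 0.049)
  flat <- thrombo_panel(c("a", "b"), c(0.1, 0.2), c(1, 1), c(1, 1), c(5, 5))
  expect_equal(solve_baseline_risk(flat, params)$p0, 0.049, tolerance = 1e-10)
})

test_that("solver agrees with the independent bisection oracle", {
  bl <- solve_baseline_risk(panel, params)
  expect_equal(bl$p0, oracle_p0(panel, params), tolerance = 1e-10)
  expect_equal(bl$p0, 0.0179776, tolerance = 1e-5)
  expect_setequal(bl$cap_active,
                  c("Antithrombin deficiency", "Protein S deficiency"))
  expect_lt(bl$residual, 1e-10)
})

test_that("cohort risk is conserved at the solved baseline", {
  for (seed in 1:20) {
    pan <- generate_random_panel(m = sample(2:8, 1), seed = seed)
    bl <- solve_baseline_risk(pan, params)
    pred <- predict_conditions(pan, params, bl)
    lhs <- sum(pred$expected_complications) +
      params$cohort_size * (1 - sum(pan$prevalence)) * bl$p0
    expect_equal(lhs, params$cohort_size * params$complication_rate,
                 tolerance = 1e-9)
    # cap consistency: risk equals cap exactly iff flagged
    expect_setequal(pan$name[pred$per_carrier_risk >= params$risk_cap],
                    bl$cap_active)
  }
})

test_that("baseline risk is monotone in the complication rate and relative risks", {
  for (seed in 21:30) {
    pan <- generate_random_panel(m = 5, seed = seed)
    p_lo <- solve_baseline_risk(pan, model_params(complication_rate = 0.03))$p0
    p_hi <- solve_baseline_risk(pan, model_params(complication_rate = 0.06))$p0
    expect_lt(p_lo, p_hi)
    # a strictly higher RR lowers p0, provided that condition is not capped
    # (a capped condition's carrier risk no longer responds to its RR)
    bl0 <- solve_baseline_risk(pan, params)
    idx <- which(pan$relative_risk * bl0$p0 < params$risk_cap)[1]
    if (!is.na(idx)) {
      bump <- pan
      bump$relative_risk[idx] <- bump$relative_risk[idx] + 5
      expect_lt(solve_baseline_risk(bump, params)$p0, bl0$p0)
    }
  }
})

test_that("cap-free solves reproduce the closed form", {
  for (seed in 31:45) {
    pan <- generate_random_panel(m = 4, seed = seed)
    loose <- model_params(risk_cap = 1)
    bl <- solve_baseline_risk(pan, loose)
    if (max(pan$relative_risk) * bl$p0 < 1) {
      expect_equal(bl$p0, closed_form_p0(pan, loose), tolerance = 1e-10)
      expect_length(bl$cap_active, 0)
    }
  }
})

test_that("per-condition predictions match the published panel rows", {
  bl <- solve_baseline_risk(panel, params)
  pred <- predict_conditions(panel, params, bl)
  row <- function(nm) pred[pred$name == nm, ]
  ps <- row("Protein S deficiency")
  expect_equal(ps$expected_carriers, 70)
  expect_equal(ps$per_carrier_risk, 0.5)
  expect_equal(ps$detected_complications, 35)
  at <- row("Antithrombin deficiency")
  expect_equal(at$detected_complications, 8.5)
  expect_equal(round_half_up(at$detected_complications), 9)
  # reconstruction gives 22.47 (the printed 23 corresponds to rounding the
  # baseline risk to 0.018 before multiplying)
  hh <- row("Hyperhomocysteinemia")
  expect_equal(hh$detected_complications, 22.47, tolerance = 1e-3)
  # reconstruction exceeds the printed 45 for lupus anticoagulant
  la <- row("Lupus anticoagulant")
  expect_equal(la$detected_complications, 49.44, tolerance = 1e-3)
  expect_true(all(pred$detected_complications <=
                    pred$expected_complications + 1e-12))
  expect_true(all(pred$per_carrier_risk <= params$risk_cap))
})

test_that("expected screen positives follow prevalence times sensitivity", {
  expect_equal(total_test_positive(panel, params), 2888.5)
  expect_equal(round_half_up(total_test_positive(panel, params)), 2889)
  blind <- panel
  blind$sensitivity <- rep(1e-12, nrow(panel)) # constructor forbids exact 0
  expect_equal(total_test_positive(blind, params), 0, tolerance = 1e-6)
  one <- thrombo_panel("a", 0.1, 2, 0.9, 10)
  expect_equal(total_test_positive(one, model_params(cohort_size = 1000)), 90)
})

test_that("attributable burden summarises detected complications", {
  bl <- solve_baseline_risk(panel, params)
  pred <- predict_conditions(panel, params, bl)
  att <- attributable_summary(pred, params)
  expect_equal(att$absolute_rate, 0.0362, tolerance = 1e-3)
  expect_equal(att$attributable_fraction, 0.738, tolerance = 1e-3)
  att_m <- attributable_summary(pred, params, basis = "expected")
  expect_gte(att_m$attributable_fraction, att$attributable_fraction)
  empty <- predict_conditions(
    thrombo_panel(character(), numeric(), numeric(), numeric(), numeric()),
    params, solve_baseline_risk(
      thrombo_panel(character(), numeric(), numeric(), numeric(), numeric()),
      params))
  expect_equal(attributable_summary(empty, params)$attributable_fraction, 0)
})

test_that("limited panel selection ranks by detected complications", {
  bl <- solve_baseline_risk(panel, params)
  pred <- predict_conditions(panel, params, bl)
  lim <- select_limited_panel(pred, panel, k = 5)
  expect_setequal(lim$name, c("Factor VIII excess",
                              "Activated protein C resistance",
                              "Lupus anticoagulant",
                              "Protein S deficiency",
                              "Hyperhomocysteinemia"))
  expect_equal(attr(lim, "panel_cost"), 572)
  expect_equal(attr(lim, "capture_fraction"), 0.87, tolerance = 0.005)
  full <- select_limited_panel(pred, panel, k = nrow(panel))
  expect_equal(attr(full, "panel_cost"), 1206)
  by_target <- select_limited_panel(pred, panel, capture_target = 1)
  expect_setequal(by_target$name, panel$name)
  expect_error(select_limited_panel(pred, panel, k = 0), "k must be")
  expect_error(select_limited_panel(pred, panel, capture_target = 0),
               "capture_target")
  expect_error(select_limited_panel(pred, panel), "exactly one")
})
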