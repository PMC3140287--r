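# Independent oracles, deliberately coded apart from the package internals.

# Baseline-risk oracle: plain 200-iteration bisection of the cohort balance
# function on [0, r / (1 - sum(prev))]. Brackets shrink below 1e-12 well
# before 200 halvings.
oracle_p0 <- function(panel, params) {
  r <- params$complication_rate
  K <- params$risk_cap
  f <- function(p) {
    carriers <- sum(panel$prevalence * pmin(panel$relative_risk * p, K))
    carriers + (1 - sum(panel$prevalence)) * p - r
  }
  lo <- 0
  hi <- r / (1 - sum(panel$prevalence))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Closed form valid only when no per-carrier risk hits the cap.
closed_form_p0 <- function(panel, params) {
  params$complication_rate /
    (sum(panel$prevalence * panel$relative_risk) + 1 - sum(panel$prevalence))
}

# A tiny two-condition panel used across tests.
tiny_panel <- function() {
  thrombo_panel(name = c("a", "b"),
                prevalence = c(0.05, 0.02),
                relative_risk = c(4, 12),
                sensitivity = c(1, 0.8),
                assay_cost = c(100, 50))
}
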