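#' Construct a thrombophilia panel
#'
#' A panel is an ordered set of thrombophilia conditions, each described by
#' its population prevalence, its relative risk of a first venous
#' thromboembolism (used as the proxy relative risk for a thrombotic flap
#' complication), the sensitivity of the screening assay, and the assay cost.
#' Carriers are modelled as mutually exclusive (at most one condition per
#' patient), so prevalences must sum to below 1.
#'
#' @param name character vector of unique condition labels
#' @param prevalence carrier fraction in (0, 1) per condition
#' @param relative_risk relative risk (>= 1) of thrombosis per condition
#' @param sensitivity assay sensitivity in (0, 1] per condition
#' @param assay_cost per-patient assay cost in dollars (>= 0)
#' @return a data.frame of class `thrombo_panel` with one row per condition
#' @examples
#' panel <- thrombo_panel(
#'   name = c("factor V Leiden", "prothrombin G20210A"),
#'   prevalence = c(0.05, 0.02),
#'   relative_risk = c(7.5, 5.2),
#'   sensitivity = c(1, 1),
#'   assay_cost = c(116, 202)
#' )
#' panel_cost(panel)
#' @export
thrombo_panel <- function(name, prevalence, relative_risk, sensitivity,
                          assay_cost) {
  n <- length(name)
  if (n == 0) {
    panel <- data.frame(name = character(), prevalence = numeric(),
                        relative_risk = numeric(), sensitivity = numeric(),
                        assay_cost = numeric(), stringsAsFactors = FALSE)
    class(panel) <- c("thrombo_panel", "data.frame")
    return(panel)
  }
  stopifnot(length(prevalence) == n, length(relative_risk) == n,
            length(sensitivity) == n, length(assay_cost) == n)
  name <- as.character(name)
  if (anyDuplicated(name)) abort_tf("condition names must be unique")
  if (any(prevalence <= 0 | prevalence >= 1))
    abort_tf("prevalences must lie in (0, 1)")
  if (sum(prevalence) >= 1)
    abort_tf("prevalences sum to ", sum(prevalence),
             "; carriers are mutually exclusive, so the sum must be < 1")
  if (any(relative_risk < 1)) abort_tf("relative risks must be >= 1")
  if (any(sensitivity <= 0 | sensitivity > 1))
    abort_tf("sensitivities must lie in (0, 1]")
  if (any(assay_cost < 0)) abort_tf("assay costs must be >= 0")
  panel <- data.frame(name = name, prevalence = prevalence,
                      relative_risk = relative_risk, sensitivity = sensitivity,
                      assay_cost = assay_cost, stringsAsFactors = FALSE)
  class(panel) <- c("thrombo_panel", "data.frame")
  panel
}

#' Total assay cost of a panel
#'
#' @param panel a [thrombo_panel()]
#' @return total per-patient screening cost in dollars
#' @export
panel_cost <- function(panel) sum(panel$assay_cost)

#' Read a thrombophilia panel from CSV
#'
#' The file carries percent units (as the source tables do) with header
#' `name,prevalence_pct,relative_risk,sensitivity_pct,assay_cost`; the
#' conversion to fractions happens here and nowhere else.
#'
#' @param path CSV file path
#' @return a `thrombo_panel`
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "prevalence_pct", "relative_risk", "sensitivity_pct",
            "assay_cost")
  if (!all(need %in% names(df)))
    abort_tf("panel CSV must have columns: ", paste(need, collapse = ", "))
  thrombo_panel(df$name, df$prevalence_pct / 100, df$relative_risk,
                df$sensitivity_pct / 100, df$assay_cost)
}

#' Write a panel to CSV (percent units)
#'
#' @param panel a `thrombo_panel`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_panel_csv <- function(panel, path) {
  out <- data.frame(name = panel$name,
                    prevalence_pct = panel$prevalence * 100,
                    relative_risk = panel$relative_risk,
                    sensitivity_pct = panel$sensitivity * 100,
                    assay_cost = panel$assay_cost)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged nine-condition thrombophilia panel
#'
#' Prevalences, proxy relative risks for a first venous thromboembolism,
#' assay sensitivities and institutional assay costs for the nine most common
#' thrombophilias. Full panel cost is $1206.
#'
#' @return a `thrombo_panel` with nine conditions
#' @export
default_panel <- function() {
  read_panel_csv(system.file("extdata", "thrombophilia_panel.csv",
                             package = "thromboflap", mustWork = TRUE))
}

#' Cohort-level model parameters
#'
#' Assembles the assumptions of the decision model: cohort size, observed
#' thrombotic complication rate, the per-condition risk cap, prophylaxis
#' efficacy and cost, the incremental cost of a thrombotic complication, and
#' the flap cancellation rate (held at 0: a positive screen changes therapy,
#' not the decision to operate).
#'
#' @param cohort_size number of patients in the theoretical cohort
#' @param complication_rate observed thrombotic complication fraction
#' @param risk_cap ceiling on any condition's per-carrier complication
#'   probability (conservative model constraint)
#' @param therapy_efficacy fraction of complications averted by prophylaxis
#'   in treated patients
#' @param therapy_cost per-patient cost of the prophylaxis course, dollars
#' @param complication_cost incremental direct cost of one thrombotic
#'   complication, dollars
#' @param cancellation_rate fraction of positive screens leading to
#'   cancellation
#' @return a list of class `model_params`
#' @export
model_params <- function(cohort_size = 10000,
                         complication_rate = 0.049,
                         risk_cap = 0.5,
                         therapy_efficacy = 0.88,
                         therapy_cost = 2100,
                         complication_cost = 23246,
                         cancellation_rate = 0) {
  if (!is_count(cohort_size) || cohort_size < 1)
    abort_tf("cohort_size must be a positive integer")
  if (!is_prob(complication_rate) || complication_rate <= 0)
    abort_tf("complication_rate must lie in (0, 1)")
  if (!is_prob(risk_cap) || risk_cap <= 0)
    abort_tf("risk_cap must lie in (0, 1]")
  if (complication_rate >= risk_cap)
    abort_tf("complication_rate must be below the risk cap")
  if (!is_prob(therapy_efficacy)) abort_tf("therapy_efficacy must lie in [0, 1]")
  if (therapy_cost < 0 || complication_cost < 0)
    abort_tf("costs must be >= 0")
  if (!is_prob(cancellation_rate)) abort_tf("cancellation_rate must lie in [0, 1]")
  structure(list(cohort_size = cohort_size,
                 complication_rate = complication_rate,
                 risk_cap = risk_cap,
                 therapy_efficacy = therapy_efficacy,
                 therapy_cost = therapy_cost,
                 complication_cost = complication_cost,
                 cancellation_rate = cancellation_rate),
            class = "model_params")
}

#' Read model parameters from a YAML or JSON config
#'
#' Keys mirror the arguments of [model_params()]; missing keys take the
#' packaged defaults. Format is chosen by file extension (.yaml/.yml/.json).
#'
#' @param path config file path
#' @return a `model_params` list
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
                 yaml = , yml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 abort_tf("unsupported config extension: .", ext))
  known <- names(formals(model_params))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0)
    abort_tf("unknown parameter keys: ", paste(extra, collapse = ", "))
  do.call(model_params, vals)
}

#' Packaged default model parameters
#'
#' The defaults of the published analysis: a cohort of 10,000 patients, a
#' 4.9\% thrombotic complication rate, a 50\% per-condition risk cap, 88\%
#' prophylaxis efficacy at $2100 per course, a $23,246 complication cost, and
#' no flap cancellations.
#'
#' @return a `model_params` list
#' @export
default_params <- function() {
  read_params(system.file("extdata", "model_params.yaml",
                          package = "thromboflap", mustWork = TRUE))
}

#' Validate model inputs without running the model
#'
#' Checks panel and parameter ranges (prevalence in (0,1), prevalence sum
#' below 1, relative risks >= 1, sensitivities in (0,1], complication rate
#' below the risk cap, efficacy in [0,1]) and returns a diagnostics table
#' rather than stopping, so a caller can report all violations at once.
#'
#' @param panel a `thrombo_panel` or a raw data.frame with panel columns
#' @param params a `model_params` list (validated lazily: raw lists allowed)
#' @return data.frame with columns `check`, `ok`, `detail`
#' @export
validate_inputs <- function(panel, params) {
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(check = check, ok = ok,
                                                detail = detail)
  }
  add("prevalence in (0,1)", all(panel$prevalence > 0 & panel$prevalence < 1),
      paste0("range ", min(panel$prevalence), "-", max(panel$prevalence)))
  add("prevalence sum < 1", sum(panel$prevalence) < 1,
      paste0("sum = ", signif(sum(panel$prevalence), 6)))
  add("relative risks >= 1", all(panel$relative_risk >= 1), "")
  add("sensitivity in (0,1]",
      all(panel$sensitivity > 0 & panel$sensitivity <= 1), "")
  add("assay costs >= 0", all(panel$assay_cost >= 0), "")
  add("complication rate below risk cap",
      params$complication_rate < params$risk_cap,
      paste0("r = ", params$complication_rate, ", cap = ", params$risk_cap))
  add("therapy efficacy in [0,1]",
      params$therapy_efficacy >= 0 && params$therapy_efficacy <= 1, "")
  do.call(rbind, checks)
}
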