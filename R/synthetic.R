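#' Generate a synthetic flap registry
#'
#' Draws flap types from configured weights, thrombotic complications per
#' type from configured probabilities, and flap losses among the thrombotic
#' cases, producing records in the same shape the registry readers consume.
#'
#' @param n_cases number of flaps
#' @param flap_type_weights named numeric vector of type probabilities
#'   (must sum to 1)
#' @param per_type_complication_prob named numeric vector of per-type
#'   thrombotic-complication probabilities; names must cover the types
#' @param loss_given_complication probability a thrombotic case loses the flap
#' @param year_range integer pair, inclusive range of operative years
#' @param seed integer seed (fixed seed replays identically)
#' @return data.frame of flap records
#' @export
generate_registry <- function(n_cases, flap_type_weights,
                              per_type_complication_prob,
                              loss_given_complication = 0.4,
                              year_range = c(2004, 2009), seed = 1) {
  if (!is_count(n_cases) || n_cases < 1) abort_tf("n_cases must be >= 1")
  if (abs(sum(flap_type_weights) - 1) > 1e-9)
    abort_tf("flap_type_weights must sum to 1")
  if (any(flap_type_weights < 0)) abort_tf("weights must be >= 0")
  types <- names(flap_type_weights)
  if (is.null(types) || !all(types %in% names(per_type_complication_prob)))
    abort_tf("per_type_complication_prob must name every flap type")
  p <- per_type_complication_prob[types]
  if (any(p < 0 | p > 1)) abort_tf("complication probabilities must lie in [0, 1]")
  if (!is_prob(loss_given_complication))
    abort_tf("loss_given_complication must lie in [0, 1]")
  set.seed(seed)
  flap_type <- sample(types, n_cases, replace = TRUE,
                      prob = flap_type_weights)
  thrombotic <- stats::runif(n_cases) < p[flap_type]
  loss <- thrombotic & (stats::runif(n_cases) < loss_given_complication)
  data.frame(flap_type = flap_type,
             year = sample(seq(year_range[1], year_range[2]), n_cases,
                           replace = TRUE),
             indication = "synthetic",
             reoperation_vascular = thrombotic,
             thrombotic_idiopathic = thrombotic,
             flap_loss = loss,
             stringsAsFactors = FALSE)
}

#' Generate synthetic matched billing pairs
#'
#' Comparator admission costs are drawn from a lognormal distribution
#' (positive support, right-skewed, as hospital direct costs are);
#' differentials are drawn Normal(mean_differential, differential_sd) and
#' added to the comparator cost, so negative differentials occur. Index
#' costs are truncated at zero.
#'
#' @param n_pairs number of matched pairs (>= 1)
#' @param comparator_meanlog,comparator_sdlog lognormal parameters of the
#'   comparator cost (defaults give a median near $27,000 with spread
#'   covering roughly $16,000-$69,000)
#' @param mean_differential mean incremental cost of a complication, dollars
#' @param differential_sd standard deviation of the differential, dollars
#' @param seed integer seed
#' @return data.frame of cost pairs
#' @export
generate_cost_pairs <- function(n_pairs,
                                comparator_meanlog = log(27000),
                                comparator_sdlog = 0.35,
                                mean_differential = 23246,
                                differential_sd = 20000,
                                seed = 1) {
  if (!is_count(n_pairs) || n_pairs < 1) abort_tf("n_pairs must be >= 1")
  if (comparator_sdlog < 0 || differential_sd < 0)
    abort_tf("dispersions must be >= 0")
  set.seed(seed)
  comparator <- stats::rlnorm(n_pairs, comparator_meanlog, comparator_sdlog)
  diff <- stats::rnorm(n_pairs, mean_differential, differential_sd)
  index <- pmax(comparator + diff, 0)
  data.frame(flap_type = "synthetic",
             index_year = 2008, index_cost = index,
             comparator_year = 2008, comparator_cost = comparator,
             indication = "synthetic",
             stringsAsFactors = FALSE)
}

#' Generate a random thrombophilia panel
#'
#' Draws a valid panel with known ground truth for property testing of the
#' solver and the economic identities: prevalences scaled so their sum stays
#' below 0.9, relative risks in [1, 40], sensitivities in (0.5, 1], assay
#' costs in [20, 500].
#'
#' @param m number of conditions (>= 1)
#' @param seed integer seed
#' @return a `thrombo_panel`
#' @export
generate_random_panel <- function(m, seed = 1) {
  if (!is_count(m) || m < 1) abort_tf("m must be >= 1")
  set.seed(seed)
  raw <- stats::runif(m, 0.001, 0.2)
  total <- stats::runif(1, 0.05, 0.85)
  prev <- raw / sum(raw) * total
  thrombo_panel(name = sprintf("condition_%02d", seq_len(m)),
                prevalence = prev,
                relative_risk = stats::runif(m, 1, 40),
                sensitivity = stats::runif(m, 0.5 + 1e-9, 1),
                assay_cost = round(stats::runif(m, 20, 500)))
}
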