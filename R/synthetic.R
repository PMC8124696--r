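#' Configuration for the synthetic case generator
#'
#' The generator produces random but structurally valid inputs for every
#' pipeline stage: monotone cumulative rate curves, Dirichlet-distributed
#' event-tree branch probabilities, log-uniform benefit-per-ton values and
#' random rank-bin MCDA instances. With `dirichlet_concentration = 1`
#' branch/scenario probabilities are uniform over the simplex; the
#' log-uniform dollars-per-ton range mirrors the order-of-magnitude spread
#' seen across real sector benefit-per-ton estimates.
#'
#' @param seed Integer RNG seed; identical seed and config give identical
#'   output.
#' @param n_factors,n_levels,n_alternatives,n_scenarios,n_criteria Counts
#'   (all >= 1).
#' @param n_knots Interior knots per cumulative curve (>= 0).
#' @param rate_range Range of annual increase rates covered by curves.
#' @param dollars_per_ton_range Log-uniform sampling range for benefit
#'   per ton (USD/ton).
#' @param dirichlet_concentration Positive concentration for simplex
#'   sampling.
#' @param band_width Half-width of the optional cumulative-probability
#'   uncertainty band (0 disables spread; the band still brackets the
#'   curve).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed, n_factors = 3, n_levels = 3,
                             n_alternatives = 3, n_scenarios = 3,
                             n_criteria = 3, n_knots = 4,
                             rate_range = c(0, 0.02),
                             dollars_per_ton_range = c(5e4, 4e5),
                             dirichlet_concentration = 1,
                             band_width = 0) {
  counts <- c(n_factors, n_levels, n_alternatives, n_scenarios, n_criteria)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("counts must be positive integers", call. = FALSE)
  if (n_knots < 0) stop("`n_knots` must be >= 0", call. = FALSE)
  if (diff(rate_range) <= 0 || diff(dollars_per_ton_range) <= 0 ||
      any(dollars_per_ton_range <= 0))
    stop("ranges must be non-degenerate (and monetary range positive)",
         call. = FALSE)
  if (dirichlet_concentration <= 0)
    stop("`dirichlet_concentration` must be positive", call. = FALSE)
  if (band_width < 0) stop("`band_width` must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), n_factors = n_factors,
                 n_levels = n_levels, n_alternatives = n_alternatives,
                 n_scenarios = n_scenarios, n_criteria = n_criteria,
                 n_knots = n_knots, rate_range = rate_range,
                 dollars_per_ton_range = dollars_per_ton_range,
                 dirichlet_concentration = dirichlet_concentration,
                 band_width = band_width),
            class = "generator_config")
}

# One Dirichlet draw via normalized gammas.
rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha, rate = 1)
  g / sum(g)
}

level_labels <- function(n) {
  if (n == 3) c("High", "Medium", "Low") else paste0("L", seq_len(n))
}

#' Random monotone cumulative rate curve
#'
#' Builds a piecewise-linear CDF from sorted uniform knots over the
#' configured rate range, with endpoints pinned to cumulative
#' probabilities 0 and 1, plus an optional symmetric uncertainty band.
#'
#' @param config A [generator_config()].
#' @param factor_name Label for the generated curve.
#' @return A [rate_curve()].
#' @export
random_cdf <- function(config, factor_name = "synthetic factor") {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  r <- config$rate_range
  rates <- c(r[1], sort(stats::runif(config$n_knots, r[1], r[2])), r[2])
  # guard against coincident knots from runif ties (astronomically rare)
  rates <- unique(rates)
  p <- c(0, sort(stats::runif(length(rates) - 2)), 1)
  if (config$band_width > 0) {
    w <- config$band_width
    rate_curve(rates, p, factor_name,
               lower = pmax(0, p - w), upper = pmin(1, p + w))
  } else {
    rate_curve(rates, p, factor_name,
               lower = p, upper = p)
  }
}

#' Random event tree
#'
#' Each factor's level probabilities are a Dirichlet draw; each joint
#' level tuple is mapped to a uniformly chosen consequence category
#' (deterministic leaf map), giving a tree that satisfies every
#' event-tree invariant by construction.
#'
#' @param config A [generator_config()].
#' @param categories Consequence category labels.
#' @return An [event_tree()].
#' @export
random_event_tree <- function(config,
                              categories = c("High", "Medium", "Low")) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  labs <- level_labels(config$n_levels)
  factors <- lapply(seq_len(config$n_factors), function(i) {
    p <- rdirichlet1(config$n_levels,
                     rep(config$dirichlet_concentration, config$n_levels))
    level_distribution(paste0("factor_", i), stats::setNames(p, labs))
  })
  grid <- expand.grid(rep(list(labs), config$n_factors),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- paste0("factor_", seq_len(config$n_factors))
  grid$consequence <- sample(categories, nrow(grid), replace = TRUE)
  event_tree(factors, grid, categories = categories)
}

#' Random decision problem
#'
#' Generates a set of mitigation alternatives (log-uniform benefit per
#' ton, Dirichlet scenario probabilities, uniform success probabilities)
#' over a random set of increase scenarios.
#'
#' @param config A [generator_config()].
#' @param standard Baseline standard in µg/m³.
#' @return A list with `scenarios` ([increase_scenarios()]) and
#'   `alternatives` (list of [mitigation_alternative()]).
#' @export
random_decision_problem <- function(config, standard = 12) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_s <- config$n_scenarios
  rates <- sort(stats::runif(n_s, 0.02, 0.4), decreasing = TRUE)
  labs <- if (n_s == 3) c("High", "Medium", "Low")
          else paste0("S", seq_len(n_s))
  scenarios <- increase_scenarios(stats::setNames(rates, labs),
                                  standard = standard)
  lo <- log(config$dollars_per_ton_range[1])
  hi <- log(config$dollars_per_ton_range[2])
  alternatives <- lapply(seq_len(config$n_alternatives), function(i) {
    mitigation_alternative(
      name = paste0("alternative_", i),
      dollars_per_ton = exp(stats::runif(1, lo, hi)),
      scenario_prob = stats::setNames(
        rdirichlet1(n_s, rep(config$dirichlet_concentration, n_s)), labs),
      success_prob = stats::setNames(stats::runif(n_s), labs))
  })
  list(scenarios = scenarios, alternatives = alternatives)
}

#' Random rank-bin MCDA instance
#'
#' Generates numeric criteria with contiguous random bins, random raw
#' assessments inside the binned domain, and a random Dirichlet weight
#' vector.
#'
#' @param config A [generator_config()].
#' @param n_bins Bins (ranks) per criterion.
#' @return A list with `criteria`, `assessments`, `weights` and the
#'   assembled `card` ([score_card()]).
#' @export
random_mcda_instance <- function(config, n_bins = 4) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  k <- config$n_criteria
  crit_names <- paste0("criterion_", seq_len(k))
  criteria <- stats::setNames(lapply(crit_names, function(nm) {
    edges <- cumsum(c(0, stats::runif(n_bins, 0.5, 2)))
    criterion(nm, data.frame(lower = edges[-length(edges)],
                             upper = edges[-1], rank = seq_len(n_bins)))
  }), crit_names)
  n_a <- config$n_alternatives
  assessments <- stats::setNames(lapply(seq_len(n_a), function(i) {
    stats::setNames(lapply(criteria, function(cr)
      stats::runif(1, min(cr$bins$lower), max(cr$bins$upper))), crit_names)
  }), paste0("alternative_", seq_len(n_a)))
  weights <- criterion_weights(stats::setNames(
    rdirichlet1(k, rep(config$dirichlet_concentration, k)), crit_names))
  list(criteria = criteria, assessments = assessments, weights = weights,
       card = score_card(assessments, criteria))
}
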