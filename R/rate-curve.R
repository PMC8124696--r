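#' Cumulative probability curve of a risk factor's annual increase rate
#'
#' Represents a decision-maker's belief about how fast a risk factor
#' (population, economy, temperature) will grow per year, as a cumulative
#' distribution function over the annual increase rate. The curve is a
#' piecewise-linear interpolation through the supplied knots; an optional
#' lower/upper envelope carries elicitation uncertainty (a confidence band)
#' and is used only by synthetic sampling, never by point-estimate
#' operations.
#'
#' @param rates Numeric vector of annual increase rates (fractions per
#'   year), strictly increasing.
#' @param cum_prob Numeric vector of cumulative probabilities at `rates`,
#'   non-decreasing, starting at 0 and ending at 1.
#' @param factor_name Label of the risk factor.
#' @param lower,upper Optional envelope curves (same length as `rates`)
#'   bracketing `cum_prob` pointwise.
#'
#' @return An object of class `rate_curve`.
#' @examples
#' pop <- rate_curve(c(0, 0.003, 0.006, 0.010), c(0, 0.2, 0.5, 1),
#'                   factor_name = "population growth")
#' cdf_at(pop, 0.006)
#' @export
rate_curve <- function(rates, cum_prob, factor_name = "factor",
                       lower = NULL, upper = NULL) {
  rates <- as.numeric(rates)
  cum_prob <- as.numeric(cum_prob)
  if (length(rates) != length(cum_prob) || length(rates) < 2)
    stop("`rates` and `cum_prob` must have equal length >= 2", call. = FALSE)
  if (any(diff(rates) <= 0))
    stop("rates must be strictly increasing", call. = FALSE)
  if (any(diff(cum_prob) < 0))
    stop("cumulative probabilities must be non-decreasing", call. = FALSE)
  if (any(cum_prob < 0 | cum_prob > 1))
    stop("cumulative probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(cum_prob[1]) > 1e-12 || abs(cum_prob[length(cum_prob)] - 1) > 1e-12)
    stop("curve must start at cumulative probability 0 and end at 1",
         call. = FALSE)
  band <- NULL
  if (!is.null(lower) || !is.null(upper)) {
    if (is.null(lower) || is.null(upper) ||
        length(lower) != length(rates) || length(upper) != length(rates))
      stop("band needs both `lower` and `upper` at every knot", call. = FALSE)
    if (any(lower > cum_prob + 1e-12) || any(upper < cum_prob - 1e-12))
      stop("band envelopes must bracket the central curve pointwise",
           call. = FALSE)
    band <- list(lower = pmin(as.numeric(lower), cum_prob),
                 upper = pmax(as.numeric(upper), cum_prob))
  }
  structure(list(factor_name = factor_name, rates = rates,
                 cum_prob = cum_prob, band = band),
            class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat("<rate_curve> ", x$factor_name, ": ", length(x$rates),
      " knots over rates [", min(x$rates), ", ", max(x$rates), "]",
      if (!is.null(x$band)) " with uncertainty band", "\n", sep = "")
  invisible(x)
}

#' Evaluate a rate curve's CDF
#'
#' Piecewise-linear interpolation between knots; constant 0 below the first
#' knot and 1 above the last.
#'
#' @param curve A [rate_curve()].
#' @param rate Numeric vector of rates at which to evaluate.
#' @return Cumulative probabilities at `rate`.
#' @export
cdf_at <- function(curve, rate) {
  stopifnot(inherits(curve, "rate_curve"))
  stats::approx(curve$rates, curve$cum_prob, xout = rate,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' Discretization of a rate axis into named levels
#'
#' Maps contiguous half-open rate intervals `[lower, upper)` to ordered
#' level labels (e.g. High/Medium/Low); the topmost interval is closed so a
#' boundary rate such as 0.6%/year belongs to the higher level, matching
#' the convention that touching bin edges resolve upward.
#'
#' @param factor_name Label of the risk factor the binning applies to.
#' @param levels Character vector of level labels, ordered from the lowest
#'   rate interval upward is NOT assumed: `breaks` pairs with `levels`
#'   positionally.
#' @param breaks Numeric vector of interval edges, length
#'   `length(levels) + 1`, strictly increasing; level `i` covers
#'   `[breaks[i], breaks[i + 1])`.
#' @return An object of class `level_binning`.
#' @examples
#' level_binning("population growth",
#'               levels = c("Low", "Medium", "High"),
#'               breaks = c(0, 0.003, 0.006, 0.010))
#' @export
level_binning <- function(factor_name, levels, breaks) {
  breaks <- as.numeric(breaks)
  if (length(breaks) != length(levels) + 1)
    stop("`breaks` must have length(levels) + 1 entries", call. = FALSE)
  if (any(diff(breaks) <= 0))
    stop("interval edges must be strictly increasing", call. = FALSE)
  if (anyDuplicated(levels))
    stop("level labels must be unique", call. = FALSE)
  structure(list(factor_name = factor_name,
                 levels = as.character(levels), breaks = breaks),
            class = "level_binning")
}

#' @export
print.level_binning <- function(x, ...) {
  cat("<level_binning> ", x$factor_name, "\n", sep = "")
  for (i in seq_along(x$levels))
    cat(sprintf("  %-8s [%g, %g%s\n", x$levels[i], x$breaks[i],
                x$breaks[i + 1],
                if (i == length(x$levels)) "]" else ")"))
  invisible(x)
}

#' Probability of each discrete level of a risk factor
#'
#' Integrates a cumulative rate curve over each level's rate interval:
#' `P(level) = CDF(upper) - CDF(lower)` under piecewise-linear
#' interpolation. This is the step that turns a continuous belief curve
#' into the branch probabilities of an event tree.
#'
#' @param curve A [rate_curve()].
#' @param binning A [level_binning()] whose intervals lie within the
#'   curve's rate range.
#' @return An object of class `level_distribution`: a list with
#'   `factor_name`, `levels` and a named `prob` vector summing to 1.
#' @examples
#' pop <- rate_curve(c(0, 0.003, 0.006, 0.010), c(0, 0.2, 0.5, 1),
#'                   "population growth")
#' bins <- level_binning("population growth", c("Low", "Medium", "High"),
#'                       c(0, 0.003, 0.006, 0.010))
#' level_probabilities(pop, bins)
#' @export
level_probabilities <- function(curve, binning) {
  stopifnot(inherits(curve, "rate_curve"), inherits(binning, "level_binning"))
  rng <- range(curve$rates)
  if (min(binning$breaks) < rng[1] - 1e-12 ||
      max(binning$breaks) > rng[2] + 1e-12)
    stop("binning intervals lie outside the curve's rate range [",
         rng[1], ", ", rng[2], "]", call. = FALSE)
  cp <- cdf_at(curve, binning$breaks)
  prob <- diff(cp)
  names(prob) <- binning$levels
  total <- sum(prob)
  if (abs(total - 1) > 1e-9)
    stop("level probabilities sum to ", total,
         "; binning must cover the curve's full mass", call. = FALSE)
  level_distribution(curve$factor_name, prob)
}

#' Discrete level distribution of a risk factor
#'
#' @param factor_name Label of the factor.
#' @param prob Named probability vector (one entry per level) summing to 1.
#' @return An object of class `level_distribution`.
#' @export
level_distribution <- function(factor_name, prob) {
  prob <- unlist(prob)
  if (is.null(names(prob)) || any(!nzchar(names(prob))))
    stop("`prob` must be a named vector of level probabilities",
         call. = FALSE)
  if (any(prob < -1e-12 | prob > 1 + 1e-12))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(prob) - 1) > 1e-9)
    stop("level probabilities must sum to 1 (got ", sum(prob), ")",
         call. = FALSE)
  structure(list(factor_name = factor_name, levels = names(prob),
                 prob = pmin(pmax(prob, 0), 1)),
            class = "level_distribution")
}

#' @export
print.level_distribution <- function(x, ...) {
  cat("<level_distribution> ", x$factor_name, "\n", sep = "")
  print(round(x$prob, 6))
  invisible(x)
}

#' @export
as.data.frame.level_distribution <- function(x, ...) {
  data.frame(factor = x$factor_name, level = x$levels,
             probability = unname(x$prob), stringsAsFactors = FALSE)
}
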