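#' Scenarios of future PM2.5 concentration increase
#'
#' Defines the High/Medium/Low concentration-increase scenarios relative
#' to a baseline ambient standard: each scenario's future concentration is
#' `standard * (1 + increase_rate)` and the reduction needed to return to
#' the standard is the difference.
#'
#' @param increase_rates Named fractions of concentration increase over
#'   the planning horizon (defaults: High 20%, Medium 10%, Low 5%).
#' @param standard Baseline annual standard in µg/m³ (default 12, the US
#'   NAAQS annual PM2.5 standard).
#' @return A data frame of class `increase_scenarios` with columns
#'   `label`, `increase_rate`, `concentration`, `reduction` (µg/m³).
#' @examples
#' increase_scenarios()
#' @export
increase_scenarios <- function(increase_rates = c(High = 0.20,
                                                  Medium = 0.10,
                                                  Low = 0.05),
                               standard = 12) {
  if (standard <= 0) stop("`standard` must be positive", call. = FALSE)
  if (is.null(names(increase_rates)) || any(increase_rates <= 0))
    stop("`increase_rates` must be named, positive fractions",
         call. = FALSE)
  out <- data.frame(label = names(increase_rates),
                    increase_rate = unname(increase_rates),
                    concentration = standard * (1 + unname(increase_rates)),
                    stringsAsFactors = FALSE)
  out$reduction <- out$concentration - standard
  attr(out, "standard") <- standard
  class(out) <- c("increase_scenarios", "data.frame")
  out
}

#' A mitigation sector under valuation
#'
#' Bundles the inputs needed to monetize an emission-control investment in
#' one sector: the health benefit per ton of directly emitted PM2.5
#' reduced (from benefit-per-ton studies, 2010 USD), the sector-specific
#' probability of each increase scenario, and the probability that the
#' intervention succeeds under each scenario.
#'
#' @param name Sector name.
#' @param dollars_per_ton Benefit per ton of PM2.5 reduced (USD/ton, > 0).
#' @param scenario_prob Named probabilities of each increase scenario
#'   (must sum to 1; override with `check_probs = FALSE` when reproducing
#'   a published table verbatim).
#' @param success_prob Named per-scenario probabilities of success.
#' @param check_probs Validate that `scenario_prob` sums to 1.
#' @return An object of class `mitigation_alternative`.
#' @examples
#' mitigation_alternative("refineries", 370000,
#'                        c(High = 0.5, Medium = 0.4, Low = 0.1),
#'                        c(High = 0.75, Medium = 0.8, Low = 0.5))
#' @export
mitigation_alternative <- function(name, dollars_per_ton, scenario_prob,
                                   success_prob, check_probs = TRUE) {
  if (dollars_per_ton <= 0)
    stop("`dollars_per_ton` must be positive", call. = FALSE)
  scenario_prob <- unlist(scenario_prob)
  success_prob <- unlist(success_prob)
  if (is.null(names(scenario_prob)) || is.null(names(success_prob)))
    stop("scenario and success probabilities must be named by scenario",
         call. = FALSE)
  if (!setequal(names(scenario_prob), names(success_prob)))
    stop("scenario and success probabilities must cover the same scenarios",
         call. = FALSE)
  if (any(scenario_prob < 0 | scenario_prob > 1) ||
      any(success_prob < 0 | success_prob > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (check_probs && abs(sum(scenario_prob) - 1) > 1e-9)
    stop("scenario probabilities for '", name, "' sum to ",
         sum(scenario_prob), ", not 1", call. = FALSE)
  structure(list(name = name, dollars_per_ton = dollars_per_ton,
                 scenario_prob = scenario_prob,
                 success_prob = success_prob[names(scenario_prob)]),
            class = "mitigation_alternative")
}

#' @export
print.mitigation_alternative <- function(x, ...) {
  cat("<mitigation_alternative> ", x$name, " ($",
      format(x$dollars_per_ton, big.mark = ","), "/ton)\n", sep = "")
  print(rbind(scenario = round(x$scenario_prob, 4),
              success = round(x$success_prob, 4)))
  invisible(x)
}

#' Mass of PM2.5 to remove for a concentration reduction
#'
#' Converts a concentration reduction (µg/m³) over an air volume V (m³)
#' into metric tons: `mass = reduction * V * 1e-12` (1 t = 1e12 µg).
#' The air volume above the study region is symbolic; results are linear
#' in V, so `volume = 1` yields the per-unit-volume coefficient.
#'
#' @param reduction Concentration reduction in µg/m³ (>= 0).
#' @param volume Air volume in m³ (> 0, default 1).
#' @return Mass in metric tons.
#' @examples
#' mass_to_reduce(2.4)          # 2.4e-12 t per m³ of air
#' mass_to_reduce(1, 1e12)      # 1 t
#' @export
mass_to_reduce <- function(reduction, volume = 1) {
  if (any(volume <= 0)) stop("`volume` must be positive", call. = FALSE)
  if (any(reduction < 0)) stop("`reduction` must be non-negative",
                               call. = FALSE)
  reduction * volume * 1e-12
}

#' Per-scenario monetary value of a mitigation alternative
#'
#' `MV = P(success) * dollars_per_ton * mass_to_reduce(scenario)`: the
#' expected monetized health benefit if the scenario occurs and the
#' intervention is attempted.
#'
#' @param alt A [mitigation_alternative()].
#' @param scenarios An [increase_scenarios()] table.
#' @param volume Air volume in m³.
#' @return Named vector of monetary values (USD), one per scenario.
#' @export
scenario_monetary_value <- function(alt, scenarios, volume = 1) {
  stopifnot(inherits(alt, "mitigation_alternative"),
            inherits(scenarios, "increase_scenarios"))
  missing <- setdiff(scenarios$label, names(alt$scenario_prob))
  if (length(missing))
    stop("alternative '", alt$name, "' lacks scenario(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  mass <- mass_to_reduce(scenarios$reduction, volume)
  mv <- alt$success_prob[scenarios$label] * alt$dollars_per_ton * mass
  stats::setNames(unname(mv), scenarios$label)
}

#' Expected monetary value of a mitigation alternative
#'
#' The scenario-probability-weighted sum of per-scenario monetary values:
#' `EMV = sum_i P_i * MV_i`.
#'
#' @inheritParams scenario_monetary_value
#' @return EMV in USD (scalar).
#' @export
emv <- function(alt, scenarios, volume = 1) {
  mv <- scenario_monetary_value(alt, scenarios, volume)
  sum(alt$scenario_prob[names(mv)] * mv)
}

#' Expected exponential utility of a mitigation alternative
#'
#' Exponential (constant-absolute-risk-aversion) utility with risk
#' tolerance `R`: `u(v) = 1 - exp(-v / R)`. The default mode computes a
#' per-scenario utility and weights by scenario probability,
#' `EU = sum_i P_i * u(MV_i)`; the aggregate mode applies the utility to
#' the EMV itself, `U(EMV) = 1 - exp(-EMV / R)`. The two agree to first
#' order when monetary values are small relative to R.
#'
#' @inheritParams scenario_monetary_value
#' @param R Risk tolerance, in the same monetary units as the values
#'   (> 0). Small R is risk-averse; as R grows, `R * EU` approaches EMV.
#' @param mode `"per_scenario"` (default) or `"aggregate"`.
#' @return Expected utility (dimensionless scalar) with attribute
#'   `utilities` (per-scenario utilities) in per-scenario mode.
#' @export
expected_utility <- function(alt, scenarios, volume = 1, R,
                             mode = c("per_scenario", "aggregate")) {
  if (R <= 0) stop("risk tolerance `R` must be positive", call. = FALSE)
  mode <- match.arg(mode)
  if (mode == "aggregate")
    return(1 - exp(-emv(alt, scenarios, volume) / R))
  mv <- scenario_monetary_value(alt, scenarios, volume)
  u <- 1 - exp(-mv / R)
  out <- sum(alt$scenario_prob[names(mv)] * u)
  attr(out, "utilities") <- u
  out
}

#' Valuation table across alternatives
#'
#' Runs the EMV (and optionally EU) valuation for every alternative and
#' collects the per-scenario detail, mirroring a decision-tree summary.
#'
#' @param alternatives List of [mitigation_alternative()] objects.
#' @param scenarios An [increase_scenarios()] table.
#' @param volume Air volume in m³.
#' @param R Optional vector of risk tolerances; when supplied, an
#'   `eu_R<value>` column per tolerance is added to the summary.
#' @return A list with `detail` (alternative x scenario rows: probability,
#'   mass, monetary value) and `summary` (one row per alternative: EMV and
#'   any EU columns), both plain data frames.
#' @export
valuation_table <- function(alternatives, scenarios, volume = 1,
                            R = NULL) {
  if (inherits(alternatives, "mitigation_alternative"))
    alternatives <- list(alternatives)
  if (!length(alternatives))
    stop("at least one alternative is required", call. = FALSE)
  detail <- do.call(rbind, lapply(alternatives, function(a) {
    mv <- scenario_monetary_value(a, scenarios, volume)
    data.frame(alternative = a$name, scenario = scenarios$label,
               probability = unname(a$scenario_prob[scenarios$label]),
               success = unname(a$success_prob[scenarios$label]),
               mass_ton = mass_to_reduce(scenarios$reduction, volume),
               monetary_value = unname(mv), stringsAsFactors = FALSE)
  }))
  summary <- data.frame(
    alternative = vapply(alternatives, `[[`, "", "name"),
    emv = vapply(alternatives, emv, 0, scenarios, volume),
    stringsAsFactors = FALSE)
  for (r in R)
    summary[[paste0("eu_R", format(r))]] <-
      vapply(alternatives, function(a)
        as.numeric(expected_utility(a, scenarios, volume, R = r)), 0)
  rownames(detail) <- rownames(summary) <- NULL
  list(detail = detail, summary = summary)
}

#' Rank alternatives by a valuation criterion
#'
#' Descending order of EMV or EU. Ties (differences below `1e-12`
#' relative) keep input order and are reported via the `ties` attribute.
#'
#' @param summary The `summary` data frame from [valuation_table()].
#' @param criterion Column to rank by (e.g. `"emv"` or an `eu_R*` column).
#' @return Character vector of alternative names, best first.
#' @export
rank_alternatives <- function(summary, criterion = "emv") {
  if (!nrow(summary)) stop("empty valuation summary", call. = FALSE)
  if (!criterion %in% names(summary))
    stop("no column '", criterion, "' in the valuation summary",
         call. = FALSE)
  v <- summary[[criterion]]
  ord <- order(-v)  # stable: preserves input order among ties
  out <- summary$alternative[ord]
  scale <- max(abs(v), 1e-300)
  d <- abs(diff(v[ord])) / scale
  tied_pairs <- which(d < 1e-12)
  attr(out, "ties") <- if (length(tied_pairs))
    lapply(tied_pairs, function(i) out[c(i, i + 1L)]) else list()
  out
}

#' Ratio of two alternatives' EMVs
#'
#' How many times more worthy of investment alternative `a` is than `b`
#' under the EMV criterion. Reported at full precision with the
#' 2-significant-figure headline value as attribute `rounded`.
#'
#' @param a,b Alternative names present in `summary`.
#' @param summary The `summary` data frame from [valuation_table()].
#' @return `EMV(a) / EMV(b)`.
#' @export
emv_ratio <- function(a, b, summary) {
  get1 <- function(nm) {
    i <- match(nm, summary$alternative)
    if (is.na(i)) stop("unknown alternative '", nm, "'", call. = FALSE)
    summary$emv[i]
  }
  denom <- get1(b)
  if (denom <= 0)
    stop("EMV of '", b, "' is not positive; ratio undefined",
         call. = FALSE)
  out <- get1(a) / denom
  attr(out, "rounded") <- signif(out, 2)
  out
}
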