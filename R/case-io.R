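#' Load and validate a case configuration
#'
#' Reads a YAML (or JSON) case file describing the three pipeline stages
#' — risk structure, decision valuation, MCDA — validates every block,
#' and assembles the package's domain objects. Validation failures name
#' the offending field with a path such as
#' `decision/alternatives[2]/scenario_prob`.
#'
#' @param path Path to the configuration file.
#' @param warn_inconsistent Warn when an alternative carries an
#'   `elicited_scenario_prob` block that differs from the
#'   `scenario_prob` actually used (default `TRUE`).
#' @return An object of class `pm25_case`.
#' @seealso [la_lbma_case()] for the packaged case study,
#'   [run_pipeline()] to execute all stages.
#' @export
load_case <- function(path, warn_inconsistent = TRUE) {
  if (!file.exists(path))
    stop("case file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  with_path <- function(p, expr) {
    tryCatch(expr, error = function(e)
      stop(p, ": ", conditionMessage(e), call. = FALSE))
  }
  need <- function(block, field, p) {
    if (is.null(block[[field]]))
      stop(p, "/", field, ": missing required field", call. = FALSE)
    block[[field]]
  }
  check_prob_block <- function(x, p) {
    v <- unlist(x)
    if (any(v < 0 | v > 1))
      stop(p, ": probabilities must lie in [0, 1] (got ",
           paste(v[v < 0 | v > 1], collapse = ", "), ")", call. = FALSE)
    x
  }

  risk <- cfg$risk
  curves <- list()
  for (i in seq_along(risk$curves)) {
    cu <- risk$curves[[i]]
    p <- sprintf("risk/curves[%d]", i)
    curves[[need(cu, "factor", p)]] <- with_path(p, rate_curve(
      need(cu, "rates", p), need(cu, "cum_prob", p),
      factor_name = cu$factor, lower = cu$lower, upper = cu$upper))
  }
  binnings <- list()
  for (i in seq_along(risk$binnings)) {
    bi <- risk$binnings[[i]]
    p <- sprintf("risk/binnings[%d]", i)
    binnings[[need(bi, "factor", p)]] <- with_path(p, level_binning(
      bi$factor, need(bi, "levels", p), need(bi, "breaks", p)))
  }
  cons <- NULL
  if (!is.null(risk$consequence_distribution)) {
    cd <- risk$consequence_distribution
    cd$provenance <- NULL
    cons <- with_path("risk/consequence_distribution",
                      as_consequence_distribution(unlist(cd)))
  }
  risk_table <- NULL
  if (!is.null(risk$conditional_risk_table)) {
    rt <- risk$conditional_risk_table
    as_rt_df <- function(rows, p) {
      d <- do.call(rbind, lapply(rows, function(r)
        data.frame(factor = r$factor, level = r$level,
                   consequence = r$consequence,
                   probability = as.numeric(r$probability),
                   stringsAsFactors = FALSE)))
      check_prob_block(d$probability, p)
      d
    }
    risk_table <- with_path("risk/conditional_risk_table",
      new_conditional_risk_table(
        as_rt_df(rt$forward, "risk/conditional_risk_table/forward"),
        as_rt_df(rt$inverse, "risk/conditional_risk_table/inverse")))
  }
  marg <- NULL
  if (!is.null(risk$factor_high_marginals)) {
    m <- risk$factor_high_marginals
    m$provenance <- NULL
    marg <- unlist(m)
    check_prob_block(marg, "risk/factor_high_marginals")
  }

  dec <- cfg$decision
  scenarios <- with_path("decision", increase_scenarios(
    unlist(need(dec, "increase_rates", "decision")),
    standard = need(dec, "standard", "decision")))
  alternatives <- list()
  alt_meta <- list()
  for (i in seq_along(dec$alternatives)) {
    al <- dec$alternatives[[i]]
    p <- sprintf("decision/alternatives[%d]", i)
    sp <- check_prob_block(unlist(need(al, "scenario_prob", p)),
                           paste0(p, "/scenario_prob"))
    if (abs(sum(sp) - 1) > 1e-9)
      stop(p, "/scenario_prob: sums to ", sum(sp), ", not 1",
           call. = FALSE)
    alternatives[[need(al, "name", p)]] <- with_path(p,
      mitigation_alternative(al$name, need(al, "dollars_per_ton", p),
                             sp,
                             check_prob_block(
                               unlist(need(al, "success_prob", p)),
                               paste0(p, "/success_prob"))))
    if (!is.null(al$elicited_scenario_prob)) {
      el <- unlist(al$elicited_scenario_prob)
      alt_meta[[al$name]] <- list(elicited_scenario_prob = el)
      if (warn_inconsistent && !isTRUE(all.equal(el[names(sp)], sp)))
        warning("alternative '", al$name, "': elicited scenario ",
                "probabilities (", paste(el, collapse = "/"),
                ") differ from the ones used (",
                paste(sp, collapse = "/"), ")", call. = FALSE)
    }
  }

  mc <- cfg$mcda
  criteria <- list()
  for (i in seq_along(mc$criteria)) {
    cr <- mc$criteria[[i]]
    p <- sprintf("mcda/criteria[%d]", i)
    bins <- do.call(rbind, lapply(cr$bins, function(b)
      as.data.frame(b, stringsAsFactors = FALSE)))
    criteria[[need(cr, "name", p)]] <- with_path(p,
                                                 criterion(cr$name, bins))
  }
  wts <- NULL
  if (!is.null(mc$weights)) {
    w <- mc$weights
    w$provenance <- NULL
    wts <- with_path("mcda/weights", criterion_weights(unlist(w)))
  }
  assessments <- mc$assessments
  assessments$provenance <- NULL
  card <- if (length(assessments) && length(criteria))
    with_path("mcda/assessments", score_card(assessments, criteria))
  weight_scenarios <- list()
  ws <- mc$weight_scenarios
  ws$provenance <- NULL
  for (nm in names(ws))
    weight_scenarios[[nm]] <- with_path(
      paste0("mcda/weight_scenarios/", nm),
      criterion_weights(unlist(ws[[nm]])))

  structure(list(
    metadata = cfg$metadata,
    risk = list(categories = unlist(risk$categories), curves = curves,
                binnings = binnings, consequence_distribution = cons,
                risk_table = risk_table, factor_high_marginals = marg),
    decision = list(scenarios = scenarios, alternatives = alternatives,
                    alternative_metadata = alt_meta,
                    volume = if (is.null(dec$volume)) 1 else dec$volume,
                    risk_tolerances = unlist(dec$risk_tolerances)),
    mcda = list(criteria = criteria, weights = wts, card = card,
                assessments = assessments,
                weight_scenarios = weight_scenarios,
                grid_step = if (is.null(mc$grid_step)) 0.01
                            else mc$grid_step),
    raw = cfg), class = "pm25_case")
}

#' Write a case configuration back to YAML
#'
#' Serializes the raw configuration the case was loaded from, so a
#' save/load round trip reproduces the same case.
#'
#' @param case A `pm25_case`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_case <- function(case, path) {
  stopifnot(inherits(case, "pm25_case"))
  yaml::write_yaml(case$raw, path)
  invisible(path)
}

#' @export
print.pm25_case <- function(x, ...) {
  cat("<pm25_case> ", x$metadata$title %||% "untitled", "\n",
      "  risk: ", length(x$risk$curves), " curves, ",
      length(x$risk$binnings), " binnings\n",
      "  decision: ", length(x$decision$alternatives),
      " alternatives x ", nrow(x$decision$scenarios), " scenarios\n",
      "  mcda: ", length(x$mcda$criteria), " criteria, ",
      length(x$mcda$weight_scenarios), " weight scenarios\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged LA-LBMA case study
#'
#' Loads the Los Angeles - Long Beach Metro Area configuration shipped
#' with the package: three risk factors (population growth, economic
#' growth, temperature increase), three mitigation sectors (ocean-going
#' vessels, refineries, electricity-generating units), and the published
#' conditional risk table, benefit-per-ton values, and MCDA scorecard.
#' Blocks whose numbers were reconstructed rather than published are
#' labelled `derived` in the file.
#'
#' @inheritParams load_case
#' @return A `pm25_case`.
#' @examples
#' case <- la_lbma_case(warn_inconsistent = FALSE)
#' case
#' @export
la_lbma_case <- function(warn_inconsistent = TRUE) {
  load_case(system.file("extdata", "la_lbma_case.yaml",
                        package = "pm25decide", mustWork = TRUE),
            warn_inconsistent = warn_inconsistent)
}

#' Best-effort reconstructed event tree for a case
#'
#' Builds factor level distributions from the case's cumulative curves
#' and binnings and maps each joint level tuple to a consequence via a
#' severity score (High level = 2, Medium = 1, Low = 0, summed across
#' factors; total >= 4 is a High consequence, >= 2 Medium, else Low).
#' This is a reconstruction for exploration and property testing — the
#' published conditional risk table is carried verbatim in the case and
#' is the authoritative source for headline numbers.
#'
#' @param case A `pm25_case` with curves and binnings.
#' @return An [event_tree()].
#' @export
reconstructed_tree <- function(case) {
  stopifnot(inherits(case, "pm25_case"))
  factors <- lapply(names(case$risk$curves), function(f)
    level_probabilities(case$risk$curves[[f]], case$risk$binnings[[f]]))
  sev <- c(High = 2, Medium = 1, Low = 0)
  map <- function(levels) {
    s <- sum(sev[levels])
    if (s >= 4) "High" else if (s >= 2) "Medium" else "Low"
  }
  event_tree(factors, map, categories = case$risk$categories)
}

#' Run the full risk-and-decision pipeline on a case
#'
#' Executes, in order: risk-factor level probabilities from the
#' cumulative curves; conditional risk rating and critical-factor
#' selection; EMV and expected-utility valuation of the mitigation
#' alternatives; MCDA weighted scoring; discrete and continuous weight
#' sensitivity with pairwise decision boundaries. All stages are pure
#' functions of the configuration, so identical cases give identical
#' reports.
#'
#' @param case A `pm25_case`.
#' @param volume Air volume override (m³); defaults to the case value.
#' @param grid_step Simplex grid step override.
#' @return An object of class `pm25_report` (a named list of stage
#'   outputs).
#' @export
run_pipeline <- function(case, volume = NULL, grid_step = NULL) {
  stopifnot(inherits(case, "pm25_case"))
  volume <- volume %||% case$decision$volume
  grid_step <- grid_step %||% case$mcda$grid_step

  level_probs <- do.call(rbind, lapply(names(case$risk$curves),
    function(f) as.data.frame(level_probabilities(
      case$risk$curves[[f]], case$risk$binnings[[f]]))))

  risk_table <- case$risk$risk_table
  critical <- if (!is.null(risk_table))
    select_critical_factor(risk_table) else NA_character_

  # Bayes re-inversion of the forward conditionals against the stated
  # marginals, for comparison with the published inverse column.
  bayes <- NULL
  if (!is.null(risk_table) && !is.null(case$risk$factor_high_marginals) &&
      !is.null(case$risk$consequence_distribution)) {
    fwd <- risk_table$forward
    hi <- fwd[fwd$level == "High" & fwd$consequence == "High", ]
    marg <- case$risk$factor_high_marginals
    p_c <- unclass(case$risk$consequence_distribution)[["High"]]
    bayes <- data.frame(
      factor = hi$factor,
      p_inverse = vapply(seq_len(nrow(hi)), function(i)
        as.numeric(bayes_invert(hi$probability[i], marg[[hi$factor[i]]],
                                p_c)), 0),
      stringsAsFactors = FALSE)
  }

  val <- valuation_table(case$decision$alternatives,
                         case$decision$scenarios, volume = volume,
                         R = case$decision$risk_tolerances)
  rankings <- lapply(stats::setNames(nm = setdiff(names(val$summary),
                                                  "alternative")),
                     function(cr) as.character(
                       rank_alternatives(val$summary, cr)))
  best <- rankings$emv[1]
  others <- setdiff(val$summary$alternative, best)
  ratios <- data.frame(
    numerator = rep(best, length(others)), denominator = others,
    ratio = vapply(others, function(b)
      as.numeric(emv_ratio(best, b, val$summary)), 0),
    stringsAsFactors = FALSE)
  rownames(ratios) <- NULL

  card <- case$mcda$card
  mcda_scores <- if (!is.null(card) && !is.null(case$mcda$weights))
    weighted_score(card, case$mcda$weights)
  sensitivity <- if (!is.null(card) &&
                     length(case$mcda$weight_scenarios))
    discrete_sensitivity(card, case$mcda$weight_scenarios)
  surface <- if (!is.null(card) && length(case$mcda$criteria) == 3L)
    sensitivity_surface(card, grid_step)
  boundaries <- NULL
  if (!is.null(card) && length(case$mcda$criteria) == 3L) {
    alts <- card$alternatives
    pairs <- utils::combn(alts, 2, simplify = FALSE)
    boundaries <- lapply(pairs, function(p)
      decision_boundary(card, p[1], p[2]))
    names(boundaries) <- vapply(pairs, paste, "", collapse = " vs ")
  }

  structure(list(
    level_probabilities = level_probs, risk_table = risk_table,
    critical_factor = critical, bayes_inverse = bayes,
    valuation = val, rankings = rankings, emv_ratios = ratios,
    score_card = card, mcda_scores = mcda_scores,
    discrete_sensitivity = sensitivity, surface = surface,
    boundaries = boundaries,
    settings = list(volume = volume, grid_step = grid_step)),
    class = "pm25_report")
}

#' @export
print.pm25_report <- function(x, ...) {
  cat("<pm25_report>\n")
  if (!is.na(x$critical_factor))
    cat("  critical risk factor: ", x$critical_factor, " (P = ",
        attr(x$critical_factor, "probability"), ")\n", sep = "")
  cat("  EMV ranking: ", paste(x$rankings$emv, collapse = " > "), "\n",
      sep = "")
  if (!is.null(x$mcda_scores)) {
    o <- order(-x$mcda_scores)
    cat("  MCDA ranking: ",
        paste(sprintf("%s (%.2f)", names(x$mcda_scores)[o],
                      x$mcda_scores[o]), collapse = " > "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the tabular stage outputs as CSV files and a JSON summary
#' (critical factor, rankings, EMV ratios, MCDA scores, per-scenario
#' argmax, boundary coefficients) into a directory.
#'
#' @param report A `pm25_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pm25_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put_csv <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  put_csv(report$level_probabilities, "level_probabilities")
  if (!is.null(report$risk_table)) {
    put_csv(report$risk_table$forward, "risk_table_forward")
    put_csv(report$risk_table$inverse, "risk_table_inverse")
  }
  put_csv(report$valuation$detail, "valuation_detail")
  put_csv(report$valuation$summary, "valuation_summary")
  put_csv(report$discrete_sensitivity, "discrete_sensitivity")
  put_csv(report$surface, "sensitivity_surface")
  summary <- list(
    critical_factor = as.character(report$critical_factor),
    rankings = report$rankings,
    emv_ratios = report$emv_ratios,
    mcda_scores = as.list(report$mcda_scores),
    discrete_argmax = as.list(attr(report$discrete_sensitivity,
                                   "argmax")),
    boundaries = lapply(report$boundaries, function(b)
      b[c("a", "b", "coef_x", "coef_y", "intercept", "degenerate")]),
    settings = report$settings)
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, jp))
}
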