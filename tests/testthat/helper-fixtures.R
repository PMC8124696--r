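# Shared fixtures built in code.

# A loaded LA-LBMA case, inconsistency warning silenced for tests that
# are not about the warning itself.
lalbma <- function() la_lbma_case(warn_inconsistent = FALSE)

# Random monotone CDF knots on [0, rmax]: rates strictly increasing,
# cumulative probabilities non-decreasing with endpoints 0 and 1.
random_curve <- function(seed, n_interior = 5, rmax = 0.02) {
  set.seed(seed)
  rates <- c(0, sort(runif(n_interior, 0, rmax)), rmax)
  rates <- unique(rates)
  p <- c(0, sort(runif(length(rates) - 2)), 1)
  rate_curve(rates, p, paste0("curve_", seed))
}

# Independent oracle for level probabilities: numerically difference the
# interpolated CDF on a fine grid (no use of level_probabilities()).
grid_level_probs <- function(curve, binning, n_grid = 200001) {
  xs <- seq(min(curve$rates), max(curve$rates), length.out = n_grid)
  cdf <- approx(curve$rates, curve$cum_prob, xout = xs, rule = 2,
                ties = "ordered")$y
  vapply(seq_along(binning$levels), function(i) {
    lo <- binning$breaks[i]; hi <- binning$breaks[i + 1]
    approx(xs, cdf, xout = hi)$y - approx(xs, cdf, xout = lo)$y
  }, 0)
}

# Brute-force joint enumeration oracle for event trees with a
# deterministic data-frame consequence map: returns the full joint table
# of (levels..., category, probability) computed straight from first
# principles (no package tree functions).
joint_table_oracle <- function(factors, map_df) {
  lv <- lapply(factors, function(f) f$levels)
  names(lv) <- vapply(factors, `[[`, "", "factor_name")
  grid <- expand.grid(lv, stringsAsFactors = FALSE)
  p <- rep(1, nrow(grid))
  for (f in names(lv)) {
    fac <- factors[[match(f, names(lv))]]
    p <- p * unname(fac$prob[grid[[f]]])
  }
  cons <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    key <- rep(TRUE, nrow(map_df))
    for (f in names(lv)) key <- key & map_df[[f]] == grid[i, f]
    cons[i] <- map_df$consequence[key]
  }
  cbind(grid, data.frame(probability = p, consequence = cons,
                         stringsAsFactors = FALSE))
}

# The three published mitigation alternatives, built directly in code.
paper_alternatives <- function() {
  list(
    mitigation_alternative("ocean-going vessels", 53000,
                           c(High = 0.40, Medium = 0.38, Low = 0.22),
                           c(High = 0.95, Medium = 0.90, Low = 0.90)),
    mitigation_alternative("refineries", 370000,
                           c(High = 0.50, Medium = 0.40, Low = 0.10),
                           c(High = 0.75, Medium = 0.80, Low = 0.50)),
    mitigation_alternative("electricity-generating units", 150000,
                           c(High = 0.45, Medium = 0.40, Low = 0.15),
                           c(High = 0.60, Medium = 0.50, Low = 0.30)))
}

# The published MCDA instance, built directly in code.
paper_mcda <- function() {
  criteria <- list(
    "investment efficiency" = criterion(
      "investment efficiency",
      data.frame(lower = c(100, 300, 500, 700),
                 upper = c(300, 500, 700, 900), rank = 1:4)),
    "implementation difficulty" = criterion(
      "implementation difficulty",
      data.frame(category = c("Easy", "Medium", "Hard",
                              "Extremely hard"), rank = 1:4)),
    "time to become effective" = criterion(
      "time to become effective",
      data.frame(lower = c(0, 5, 10, 15), upper = c(5, 10, 15, 20),
                 rank = 1:4)))
  assessments <- list(
    "ocean-going vessels" = list(
      "investment efficiency" = 200,
      "implementation difficulty" = "Medium",
      "time to become effective" = 2.5),
    "refineries" = list(
      "investment efficiency" = 600,
      "implementation difficulty" = "Hard",
      "time to become effective" = 7.5),
    "electricity-generating units" = list(
      "investment efficiency" = 800,
      "implementation difficulty" = "Medium",
      "time to become effective" = 12.5))
  list(criteria = criteria, assessments = assessments,
       card = score_card(assessments, criteria),
       weights = criterion_weights(c(
         "investment efficiency" = 0.6,
         "implementation difficulty" = 0.3,
         "time to become effective" = 0.1)))
}
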