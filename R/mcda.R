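#' An MCDA criterion with rank bins
#'
#' A criterion maps a raw assessment — either a number (e.g. investment
#' efficiency in $M per ton, time to become effective in years) or an
#' ordinal category (e.g. implementation difficulty Easy/Medium/Hard) —
#' to a rank 1..max, rank 1 being the most preferred bin. Numeric bins
#' are half-open `[lower, upper)` with the topmost bin closed, so a value
#' sitting exactly on a shared edge belongs to the upper bin.
#'
#' @param name Criterion name.
#' @param bins For a numeric criterion, a data frame with columns
#'   `lower`, `upper`, `rank`; for an ordinal criterion, a data frame
#'   with columns `category`, `rank`. Ranks must be consecutive from 1.
#' @return An object of class `mcda_criterion`.
#' @examples
#' ie <- criterion("investment efficiency",
#'                 data.frame(lower = c(100, 300, 500, 700),
#'                            upper = c(300, 500, 700, 900),
#'                            rank = 1:4))
#' rank_of(250, ie)  # 1
#' rank_of(300, ie)  # 2: shared edges resolve upward
#' @export
criterion <- function(name, bins) {
  if (!is.data.frame(bins) || !"rank" %in% names(bins))
    stop("`bins` must be a data frame with a `rank` column", call. = FALSE)
  bins <- bins[order(bins$rank), , drop = FALSE]
  if (!identical(as.integer(bins$rank), seq_len(nrow(bins))))
    stop("ranks must be consecutive integers starting at 1", call. = FALSE)
  if (all(c("lower", "upper") %in% names(bins))) {
    kind <- "numeric"
    o <- order(bins$lower)
    if (any(bins$upper <= bins$lower) ||
        any(abs(bins$lower[o][-1] - bins$upper[o][-nrow(bins)]) > 1e-12))
      stop("numeric bins must be contiguous, non-degenerate intervals",
           call. = FALSE)
  } else if ("category" %in% names(bins)) {
    kind <- "ordinal"
    if (anyDuplicated(bins$category))
      stop("ordinal categories must be unique", call. = FALSE)
  } else {
    stop("`bins` must have lower/upper columns or a category column",
         call. = FALSE)
  }
  structure(list(name = name, kind = kind, bins = bins,
                 max_rank = nrow(bins)),
            class = "mcda_criterion")
}

#' @export
print.mcda_criterion <- function(x, ...) {
  cat("<mcda_criterion> ", x$name, " (", x$kind, ", ranks 1..",
      x$max_rank, ")\n", sep = "")
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Rank of a raw assessment under a criterion
#'
#' @param value Numeric value or ordinal category label.
#' @param criterion An [criterion()] object.
#' @return Integer rank in `1..max_rank`.
#' @export
rank_of <- function(value, criterion) {
  stopifnot(inherits(criterion, "mcda_criterion"))
  b <- criterion$bins
  if (criterion$kind == "ordinal") {
    i <- match(as.character(value), b$category)
    if (is.na(i))
      stop("'", value, "' is not a category of criterion '",
           criterion$name, "'", call. = FALSE)
    return(b$rank[i])
  }
  value <- as.numeric(value)
  top <- which.max(b$upper)
  hit <- which(value >= b$lower & (value < b$upper |
                 (seq_len(nrow(b)) == top & value == b$upper)))
  if (length(hit) != 1L)
    stop("value ", value, " is outside the bins of criterion '",
         criterion$name, "' [", min(b$lower), ", ", max(b$upper), "]",
         call. = FALSE)
  b$rank[hit]
}

#' Convert a rank to a preference score
#'
#' Scores reverse ranks so that the most preferred bin (rank 1) receives
#' the highest score: `score = max_rank + 1 - rank` (with four bins,
#' rank 1 scores 4 and rank 4 scores 1).
#'
#' @param rank Integer rank(s) in `1..max_rank`.
#' @param max_rank Number of bins.
#' @return Score(s) in `1..max_rank`.
#' @export
rank_to_score <- function(rank, max_rank) {
  if (any(rank < 1 | rank > max_rank) || any(rank != round(rank)))
    stop("rank must be an integer in 1..max_rank", call. = FALSE)
  max_rank + 1 - rank
}

#' Criterion weight vector
#'
#' @param weights Named non-negative weights summing to 1.
#' @return An object of class `criterion_weights` (named numeric vector).
#' @export
criterion_weights <- function(weights) {
  weights <- unlist(weights)
  if (is.null(names(weights)))
    stop("weights must be named by criterion", call. = FALSE)
  if (any(weights < 0 | weights > 1))
    stop("weights must lie in [0, 1]", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", sum(weights), ")", call. = FALSE)
  structure(weights, class = "criterion_weights")
}

#' Score card of alternatives against criteria
#'
#' Bins every alternative's raw assessments through the criteria's rank
#' bins and converts ranks to preference scores.
#'
#' @param assessments A named list (one entry per alternative) of named
#'   lists/vectors giving the raw value per criterion; criterion names
#'   must match `criteria`.
#' @param criteria A named list of [criterion()] objects.
#' @return An object of class `score_card` holding matrices `raw` (as
#'   character), `ranks` and `scores` (alternatives x criteria).
#' @examples
#' ie <- criterion("IE", data.frame(lower = c(0, 10), upper = c(10, 20),
#'                                  rank = 1:2))
#' sc <- score_card(list(a = list(IE = 5), b = list(IE = 15)),
#'                  list(IE = ie))
#' sc$scores
#' @export
score_card <- function(assessments, criteria) {
  if (is.null(names(assessments)) || is.null(names(criteria)))
    stop("`assessments` and `criteria` must be named", call. = FALSE)
  alts <- names(assessments)
  crits <- names(criteria)
  ranks <- matrix(NA_integer_, length(alts), length(crits),
                  dimnames = list(alts, crits))
  raw <- matrix(NA_character_, length(alts), length(crits),
                dimnames = list(alts, crits))
  for (a in alts) {
    vals <- assessments[[a]]
    missing <- setdiff(crits, names(vals))
    if (length(missing))
      stop("alternative '", a, "' lacks assessment(s) for: ",
           paste(missing, collapse = ", "), call. = FALSE)
    for (k in crits) {
      ranks[a, k] <- rank_of(vals[[k]], criteria[[k]])
      raw[a, k] <- as.character(vals[[k]])
    }
  }
  scores <- ranks
  for (k in crits)
    scores[, k] <- rank_to_score(ranks[, k], criteria[[k]]$max_rank)
  structure(list(raw = raw, ranks = ranks, scores = scores,
                 criteria = crits, alternatives = alts),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat("<score_card> scores (higher is better):\n")
  print(x$scores)
  invisible(x)
}

#' Weighted decision score
#'
#' The weighted additive MCDA model: `DS = sum_j w_j * s_j` over the
#' criteria.
#'
#' @param scores Named numeric vector of criterion scores (one
#'   alternative), or a [score_card()] to score every alternative.
#' @param weights A [criterion_weights()] vector on the same criteria.
#' @return A scalar decision score, or a named vector (one per
#'   alternative) when given a score card.
#' @export
weighted_score <- function(scores, weights) {
  weights <- criterion_weights(weights)
  if (inherits(scores, "score_card")) {
    m <- scores$scores
    if (!setequal(colnames(m), names(weights)))
      stop("weights and score card cover different criteria",
           call. = FALSE)
    return(drop(m[, names(weights), drop = FALSE] %*% unclass(weights)))
  }
  if (!setequal(names(scores), names(weights)))
    stop("weights and scores cover different criteria", call. = FALSE)
  sum(unclass(weights) * scores[names(weights)])
}

#' Decision scores under several discrete weight scenarios
#'
#' Evaluates the weighted additive model for each alternative under each
#' supplied weight scenario and records the per-scenario best
#' alternative.
#'
#' @param card A [score_card()].
#' @param weight_scenarios A named list of weight vectors (each passed
#'   through [criterion_weights()]).
#' @return A data frame with one row per (scenario, alternative) and
#'   columns `scenario`, `alternative`, `score`, `best` (logical);
#'   attribute `argmax` names the best alternative per scenario.
#' @export
discrete_sensitivity <- function(card, weight_scenarios) {
  stopifnot(inherits(card, "score_card"))
  if (!length(weight_scenarios))
    stop("at least one weight scenario is required", call. = FALSE)
  if (is.null(names(weight_scenarios)))
    names(weight_scenarios) <- paste0("scenario_",
                                      seq_along(weight_scenarios))
  rows <- lapply(names(weight_scenarios), function(s) {
    ds <- weighted_score(card, weight_scenarios[[s]])
    data.frame(scenario = s, alternative = names(ds), score = unname(ds),
               best = seq_along(ds) == which.max(ds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "argmax") <- stats::setNames(
    vapply(rows, function(r) r$alternative[r$best], ""),
    names(weight_scenarios))
  out
}

#' Continuous decision-score surface over the weight simplex
#'
#' With three criteria, weights live on the simplex
#' `{(x, y): x >= 0, y >= 0, x + y <= 1}` where `x` weights the first
#' criterion, `y` the second, and `1 - x - y` the third. Each
#' alternative's decision score is affine in `(x, y)`; this evaluates the
#' scores on a regular grid and records the best alternative at every
#' point, flagging ties (score differences below `1e-12`).
#'
#' @param card A [score_card()] with exactly three criteria; the simplex
#'   axes follow the card's criterion order (x = first, y = second).
#' @param grid_step Grid spacing in weight units, in `(0, 0.5]`.
#' @return A data frame with columns `x`, `y`, one score column per
#'   alternative, `best` and `tie`.
#' @export
sensitivity_surface <- function(card, grid_step = 0.01) {
  stopifnot(inherits(card, "score_card"))
  if (length(card$criteria) != 3L)
    stop("the weight-simplex surface requires exactly three criteria",
         call. = FALSE)
  if (grid_step <= 0 || grid_step > 0.5)
    stop("`grid_step` must lie in (0, 0.5]", call. = FALSE)
  ax <- seq(0, 1, by = grid_step)
  g <- expand.grid(x = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$x + g$y <= 1 + 1e-12, , drop = FALSE]
  s <- card$scores  # alternatives x (c1, c2, c3)
  sc <- matrix(NA_real_, nrow(g), nrow(s),
               dimnames = list(NULL, rownames(s)))
  for (a in rownames(s))
    sc[, a] <- s[a, 1] * g$x + s[a, 2] * g$y + s[a, 3] * (1 - g$x - g$y)
  top <- apply(sc, 1, max)
  best_i <- apply(sc, 1, which.max)
  tie <- apply(sc, 1, function(r) sum(r > max(r) - 1e-12) > 1L)
  out <- cbind(g, as.data.frame(sc),
               data.frame(best = colnames(sc)[best_i], tie = tie,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Decision boundary between two alternatives in the weight simplex
#'
#' The score difference `DS_a - DS_b` is affine in `(x, y)`:
#' `difference = coef_x * x + coef_y * y + intercept`; alternative `a` is
#' preferred on the open half-plane where the difference is positive.
#' When all three coefficients vanish the alternatives are scored
#' identically everywhere (degenerate boundary).
#'
#' @param card A [score_card()] with exactly three criteria.
#' @param a,b Names of two alternatives on the card.
#' @return A list of class `decision_boundary` with `coef_x`, `coef_y`,
#'   `intercept`, `preferred_when` (text form of the inequality) and
#'   `degenerate`.
#' @examples
#' # scores a = (4, 3, 4), b = (2, 2, 3) give difference 1 + x > 0:
#' # a preferred on the whole simplex, no interior boundary.
#' @export
decision_boundary <- function(card, a, b) {
  stopifnot(inherits(card, "score_card"))
  if (length(card$criteria) != 3L)
    stop("the weight-simplex boundary requires exactly three criteria",
         call. = FALSE)
  if (a == b)
    stop("`a` and `b` must be distinct alternatives", call. = FALSE)
  for (nm in c(a, b))
    if (!nm %in% rownames(card$scores))
      stop("unknown alternative '", nm, "'", call. = FALSE)
  d <- card$scores[a, ] - card$scores[b, ]
  coef_x <- d[[1]] - d[[3]]
  coef_y <- d[[2]] - d[[3]]
  intercept <- d[[3]]
  degenerate <- all(abs(c(coef_x, coef_y, intercept)) < 1e-12)
  structure(list(
    a = a, b = b, coef_x = coef_x, coef_y = coef_y,
    intercept = intercept, degenerate = degenerate,
    preferred_when = if (degenerate) "never (identical scores)" else
      sprintf("%s preferred iff %g*x + %g*y + %g > 0", a, coef_x,
              coef_y, intercept)),
    class = "decision_boundary")
}

#' @export
print.decision_boundary <- function(x, ...) {
  cat("<decision_boundary> ", x$a, " vs ", x$b, ": ",
      x$preferred_when, "\n", sep = "")
  invisible(x)
}

#' Evaluate a decision boundary's score difference at simplex points
#'
#' @param boundary A [decision_boundary()].
#' @param x,y Weight coordinates (vectors).
#' @return `DS_a - DS_b` at each point.
#' @export
boundary_difference <- function(boundary, x, y) {
  stopifnot(inherits(boundary, "decision_boundary"))
  boundary$coef_x * x + boundary$coef_y * y + boundary$intercept
}
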