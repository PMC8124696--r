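#' Event tree over independent risk-factor levels
#'
#' An event tree enumerates every joint combination of discrete risk-factor
#' levels (one branch per level, factors assumed independent) and assigns
#' each leaf a consequence category for the resulting PM2.5
#' concentration-increase outcome. The leaf assignment may be
#' deterministic (one category per leaf) or probabilistic (a distribution
#' over categories per leaf).
#'
#' @param factors A list of [level_distribution()] objects, one per risk
#'   factor; factor names are taken from each distribution.
#' @param consequence_map Either a function taking a named character
#'   vector of levels (one per factor) and returning a single category
#'   label, or a data frame with one column per factor plus either a
#'   `consequence` column (deterministic) or one numeric column per
#'   category whose rows sum to 1 (probabilistic).
#' @param categories Ordered category labels of the consequence.
#' @return An object of class `event_tree`.
#' @examples
#' pop <- level_distribution("population", c(High = 0.5, Medium = 0.3, Low = 0.2))
#' eco <- level_distribution("economy", c(High = 0.7, Medium = 0.2, Low = 0.1))
#' worst <- function(lv) if (any(lv == "High")) "High" else "Low"
#' tree <- event_tree(list(pop, eco), worst, categories = c("High", "Low"))
#' consequence_distribution(tree)
#' @export
event_tree <- function(factors, consequence_map,
                       categories = c("High", "Medium", "Low")) {
  if (inherits(factors, "level_distribution")) factors <- list(factors)
  if (!length(factors) || !all(vapply(factors, inherits, TRUE,
                                      "level_distribution")))
    stop("`factors` must be a list of level_distribution objects",
         call. = FALSE)
  fnames <- vapply(factors, `[[`, "", "factor_name")
  if (anyDuplicated(fnames))
    stop("factor names must be unique", call. = FALSE)
  names(factors) <- fnames
  structure(list(factors = factors, consequence_map = consequence_map,
                 categories = as.character(categories)),
            class = "event_tree")
}

#' @export
print.event_tree <- function(x, ...) {
  nl <- vapply(x$factors, function(f) length(f$levels), 0L)
  cat("<event_tree> ", length(x$factors), " factors (",
      paste(names(x$factors), collapse = ", "), "), ",
      prod(nl), " joint level tuples, categories: ",
      paste(x$categories, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# Resolve the leaf -> category distribution for one joint level tuple.
# Returns a named probability vector over tree$categories.
leaf_category_probs <- function(tree, levels) {
  cm <- tree$consequence_map
  cats <- tree$categories
  if (is.function(cm)) {
    out <- cm(levels)
    if (is.character(out)) {
      if (!out %in% cats)
        stop("consequence map returned unknown category '", out, "'",
             call. = FALSE)
      p <- stats::setNames(as.numeric(cats == out), cats)
      return(p)
    }
    p <- unlist(out)[cats]
  } else if (is.data.frame(cm)) {
    key <- rep(TRUE, nrow(cm))
    for (f in names(levels)) {
      if (!f %in% names(cm))
        stop("consequence map lacks a column for factor '", f, "'",
             call. = FALSE)
      key <- key & cm[[f]] == levels[[f]]
    }
    row <- which(key)
    if (length(row) != 1L)
      stop("consequence map has no unique row for tuple (",
           paste(levels, collapse = ", "), ")", call. = FALSE)
    if ("consequence" %in% names(cm)) {
      out <- cm$consequence[row]
      p <- stats::setNames(as.numeric(cats == out), cats)
      if (sum(p) == 0)
        stop("unknown category '", out, "' in consequence map",
             call. = FALSE)
      return(p)
    }
    p <- vapply(cats, function(k) {
      if (!k %in% names(cm))
        stop("consequence map lacks a probability column for category '",
             k, "'", call. = FALSE)
      as.numeric(cm[[k]][row])
    }, 0)
  } else {
    stop("`consequence_map` must be a function or a data frame",
         call. = FALSE)
  }
  if (anyNA(p) || abs(sum(p) - 1) > 1e-9)
    stop("leaf category distribution for tuple (",
         paste(levels, collapse = ", "), ") must sum to 1", call. = FALSE)
  p
}

#' Enumerate every path of an event tree
#'
#' Each row is one joint level tuple (fanned out over categories when the
#' leaf map is probabilistic) with its path probability (product of branch
#' probabilities times the leaf category probability) and consequence.
#'
#' @param tree An [event_tree()].
#' @return A data frame with one column per factor plus `probability` and
#'   `consequence`; probabilities sum to 1.
#' @export
enumerate_paths <- function(tree) {
  stopifnot(inherits(tree, "event_tree"))
  lv <- lapply(tree$factors, `[[`, "levels")
  grid <- expand.grid(lv, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(tree$factors)
  branch_p <- rep(1, nrow(grid))
  for (f in names(tree$factors))
    branch_p <- branch_p * unname(tree$factors[[f]]$prob[grid[[f]]])
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    levels <- stats::setNames(as.character(grid[i, , drop = TRUE]),
                              names(grid))
    p_cat <- leaf_category_probs(tree, levels)
    keep <- p_cat > 0
    rows[[i]] <- cbind(grid[rep(i, sum(keep)), , drop = FALSE],
                       data.frame(probability = branch_p[i] * p_cat[keep],
                                  consequence = names(p_cat)[keep],
                                  stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(abs(sum(out$probability) - 1) < 1e-9)
  out
}

#' Distribution over consequence categories
#'
#' Sums path probabilities by consequence category: the overall chance of
#' a High/Medium/Low PM2.5 concentration increase implied by the tree.
#'
#' @param tree An [event_tree()].
#' @return An object of class `consequence_distribution` (named numeric
#'   vector over categories, in tree order).
#' @export
consequence_distribution <- function(tree) {
  paths <- enumerate_paths(tree)
  p <- vapply(tree$categories, function(k)
    sum(paths$probability[paths$consequence == k]), 0)
  structure(p, class = "consequence_distribution")
}

#' Literal consequence distribution (e.g. from a published table)
#'
#' Wraps externally stated category probabilities without forcing them to
#' sum to 1 (published tables occasionally carry rounding slack);
#' `renormalize = TRUE` rescales to unit mass.
#'
#' @param prob Named probability vector over categories.
#' @param renormalize Rescale to sum to 1 (default `FALSE`, keeping the
#'   printed values verbatim).
#' @return A `consequence_distribution`.
#' @export
as_consequence_distribution <- function(prob, renormalize = FALSE) {
  prob <- unlist(prob)
  if (is.null(names(prob)))
    stop("`prob` must be named by category", call. = FALSE)
  if (any(prob < 0 | prob > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  s <- sum(prob)
  if (abs(s - 1) > 0.05)
    stop("category probabilities sum to ", s,
         "; too far from 1 to be a distribution", call. = FALSE)
  if (renormalize) prob <- prob / s
  structure(prob, class = "consequence_distribution")
}

#' @export
print.consequence_distribution <- function(x, ...) {
  cat("<consequence_distribution> (sum = ", format(sum(x)), ")\n", sep = "")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Consequence distribution conditional on one factor's level
#'
#' Restricts the path enumeration to paths where `factor` takes `level`
#' and renormalizes by that level's probability:
#' `P(consequence | factor = level)`.
#'
#' @param tree An [event_tree()].
#' @param factor Factor name.
#' @param level Level label of that factor.
#' @return Named probability vector over categories.
#' @export
conditional_consequence_given_factor <- function(tree, factor, level) {
  stopifnot(inherits(tree, "event_tree"))
  if (!factor %in% names(tree$factors))
    stop("unknown factor '", factor, "'", call. = FALSE)
  f <- tree$factors[[factor]]
  if (!level %in% f$levels)
    stop("unknown level '", level, "' for factor '", factor, "'",
         call. = FALSE)
  p_level <- unname(f$prob[level])
  if (p_level <= 0)
    stop("P(", factor, " = ", level,
         ") = 0: conditional is undefined", call. = FALSE)
  paths <- enumerate_paths(tree)
  sub <- paths[paths[[factor]] == level, , drop = FALSE]
  vapply(tree$categories, function(k)
    sum(sub$probability[sub$consequence == k]) / p_level, 0)
}

#' Invert a conditional probability by Bayes' rule
#'
#' `P(factor = level | consequence) =
#'  P(consequence | factor = level) * P(factor = level) / P(consequence)`.
#' Inputs inconsistent with a joint distribution can yield a quotient
#' above 1; the value is then clipped to 1 and flagged via the `clipped`
#' attribute with a warning.
#'
#' @param p_c_given_f Forward conditional `P(consequence | factor)`.
#' @param p_f Marginal probability of the factor level.
#' @param p_c Marginal probability of the consequence (must be > 0).
#' @return The inverse conditional (vectorized over inputs).
#' @examples
#' bayes_invert(0.41, 0.50, 0.49)  # 0.4184 to 4 d.p.
#' @export
bayes_invert <- function(p_c_given_f, p_f, p_c) {
  if (any(p_c <= 0))
    stop("P(consequence) must be > 0 for the inverse conditional",
         call. = FALSE)
  ins <- c(p_c_given_f, p_f, p_c)
  if (any(ins < 0 | ins > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  out <- p_c_given_f * p_f / p_c
  clipped <- out > 1
  if (any(clipped)) {
    warning("Bayes inversion exceeded 1 (inconsistent inputs); ",
            "clipped to 1", call. = FALSE)
    out[clipped] <- 1
  }
  attr(out, "clipped") <- clipped
  out
}

#' Conditional risk table in both directions
#'
#' For every factor and level computes the forward conditional
#' `P(consequence | factor = level)` by restricted path enumeration and
#' the inverse `P(factor = level | consequence)` by Bayes' rule against
#' the tree's marginals. For trees built from an explicit consequence map
#' the two directions are mutually consistent by construction.
#'
#' @param tree An [event_tree()].
#' @return An object of class `conditional_risk_table`: a list of two data
#'   frames `forward` and `inverse`, each with columns `factor`, `level`,
#'   `consequence`, `probability`.
#' @export
conditional_risk_table <- function(tree) {
  stopifnot(inherits(tree, "event_tree"))
  marg <- consequence_distribution(tree)
  fwd <- list(); inv <- list()
  for (f in names(tree$factors)) {
    fac <- tree$factors[[f]]
    for (l in fac$levels) {
      if (fac$prob[[l]] <= 0) next
      pc <- conditional_consequence_given_factor(tree, f, l)
      fwd[[length(fwd) + 1L]] <- data.frame(
        factor = f, level = l, consequence = names(pc),
        probability = unname(pc), stringsAsFactors = FALSE)
      ok <- unclass(marg) > 0
      inv[[length(inv) + 1L]] <- data.frame(
        factor = f, level = l, consequence = names(pc)[ok],
        probability = unname(pc[ok]) * fac$prob[[l]] / unname(marg[ok]),
        stringsAsFactors = FALSE)
    }
  }
  new_conditional_risk_table(do.call(rbind, fwd), do.call(rbind, inv))
}

#' Assemble a conditional risk table from literal data
#'
#' Used when the two directions come from a published table rather than a
#' fully specified tree (the forward and inverse columns are then taken
#' verbatim and no consistency is enforced between them).
#'
#' @param forward,inverse Data frames with columns `factor`, `level`,
#'   `consequence`, `probability`.
#' @return A `conditional_risk_table`.
#' @export
new_conditional_risk_table <- function(forward, inverse) {
  for (d in list(forward, inverse)) {
    if (!all(c("factor", "level", "consequence", "probability") %in%
             names(d)))
      stop("risk-table data frames need columns factor, level, ",
           "consequence, probability", call. = FALSE)
    if (any(d$probability < 0 | d$probability > 1))
      stop("risk-table probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(forward = forward, inverse = inverse),
            class = "conditional_risk_table")
}

#' @export
print.conditional_risk_table <- function(x, ...) {
  cat("<conditional_risk_table>\nForward P(consequence | factor = level):\n")
  print(x$forward, row.names = FALSE)
  cat("Inverse P(factor = level | consequence):\n")
  print(x$inverse, row.names = FALSE)
  invisible(x)
}

#' Select the critical risk factor
#'
#' The critical factor is the one most likely to sit at its High level
#' when the adverse consequence occurs: the argmax over factors of
#' `P(factor = High | consequence = High)`. Ties (differences below
#' `1e-12`) are reported through the `ties` attribute and broken by input
#' order.
#'
#' @param table A [conditional_risk_table()].
#' @param consequence Adverse consequence category (default `"High"`).
#' @param level Factor level examined (default `"High"`).
#' @return The critical factor's name, with attributes `probability` and
#'   `ties`.
#' @export
select_critical_factor <- function(table, consequence = "High",
                                   level = "High") {
  stopifnot(inherits(table, "conditional_risk_table"))
  inv <- table$inverse
  sub <- inv[inv$consequence == consequence & inv$level == level, ,
             drop = FALSE]
  if (!nrow(sub))
    stop("no inverse conditionals for consequence = ", consequence,
         ", level = ", level, call. = FALSE)
  best <- max(sub$probability)
  tied <- sub$factor[sub$probability > best - 1e-12]
  out <- tied[1L]
  attr(out, "probability") <- best
  attr(out, "ties") <- if (length(tied) > 1L) tied else character()
  if (length(tied) > 1L)
    message("critical-factor tie between: ", paste(tied, collapse = ", "),
            "; returning first in input order")
  out
}
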