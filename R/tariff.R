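# Utility valuation: questionnaire responses -> utility index.
#
# The EQ-5D-3L tariff follows the standard UK general-population value set
# structure: utility = 1 minus a constant for any dysfunction, minus
# additive per-dimension, per-level decrements, minus a further constant
# when any dimension is at its worst level (the "N3" term).

EQ5D_DIMENSIONS <- c("mobility", "selfcare", "activity", "pain", "anxiety")
EQ5D_TIMES  <- c("baseline", "4w", "3m", "15m", "24m", "36m")
ICIQ_TIMES  <- c("baseline", "3m", "15m", "24m", "36m")
COST_PERIODS <- c("3m", "15m", "24m", "36m")

#' The default UK EQ-5D-3L valuation tariff
#'
#' Additive decrement table of the UK general population time-trade-off
#' value set for EQ-5D-3L: constant 0.081 for any departure from full
#' health, per-dimension level-2/level-3 decrements, and a 0.269 "N3"
#' decrement when any dimension is at level 3. The all-ones state values
#' to exactly 1 and the worst state (33333) to -0.594.
#'
#' @return a `utility_tariff` object.
#' @export
eq5d_tariff_uk <- function() {
  utility_tariff(
    any_dysfunction = 0.081,
    worst_level = 0.269,
    decrements = data.frame(
      dimension = rep(EQ5D_DIMENSIONS, each = 2L),
      level = rep(c(2L, 3L), times = 5L),
      decrement = c(0.069, 0.314,   # mobility
                    0.104, 0.214,   # self-care
                    0.036, 0.094,   # usual activities
                    0.123, 0.386,   # pain/discomfort
                    0.071, 0.236)   # anxiety/depression
    )
  )
}

#' Construct a utility tariff
#'
#' @param any_dysfunction decrement applied once if any item is above
#'   level 1.
#' @param worst_level decrement applied once if any item is at its worst
#'   level.
#' @param decrements data frame with columns `dimension`, `level`,
#'   `decrement` (level-1 rows may be omitted; they carry no decrement).
#' @param max_level worst level per item (3 for EQ-5D-3L).
#' @return a `utility_tariff` object.
#' @export
utility_tariff <- function(any_dysfunction, worst_level, decrements,
                           max_level = 3L) {
  check_that(is.numeric(any_dysfunction) && any_dysfunction >= 0,
             "any_dysfunction", "must be a non-negative number")
  check_that(is.numeric(worst_level) && worst_level >= 0,
             "worst_level", "must be a non-negative number")
  check_that(is.data.frame(decrements) &&
               all(c("dimension", "level", "decrement") %in% names(decrements)),
             "decrements", "needs columns dimension, level, decrement")
  check_that(all(decrements$decrement >= 0), "decrements",
             "decrements must be >= 0")
  check_that(all(decrements$level >= 2 & decrements$level <= max_level),
             "decrements", "levels must lie in [2, max_level]")
  dims <- unique(decrements$dimension)
  # monotone non-increasing valuation requires decrements non-decreasing
  # in level within each dimension
  for (d in dims) {
    dd <- decrements[decrements$dimension == d, ]
    dd <- dd[order(dd$level), ]
    check_that(!is.unsorted(dd$decrement), "decrements",
               sprintf("decrements for %s must be non-decreasing in level", d))
  }
  structure(list(any_dysfunction = any_dysfunction,
                 worst_level = worst_level,
                 decrements = decrements,
                 dimensions = dims,
                 max_level = as.integer(max_level)),
            class = "utility_tariff")
}

#' @export
print.utility_tariff <- function(x, ...) {
  cat(sprintf("<utility_tariff> %d dimensions, levels 1..%d\n",
              length(x$dimensions), x$max_level))
  cat(sprintf("  constants: any dysfunction %.3f, worst level %.3f\n",
              x$any_dysfunction, x$worst_level))
  cat(sprintf("  range: [%.3f, 1.000]\n", value_response(rep(x$max_level,
              length(x$dimensions)), x)))
  invisible(x)
}

# Shared additive valuation used by both instruments.
value_response <- function(levels, tariff) {
  nd <- length(tariff$dimensions)
  if (length(levels) != nd)
    fail_validation("response", sprintf("expected %d item levels", nd))
  if (anyNA(levels)) return(NA_real_)
  if (any(levels < 1 | levels > tariff$max_level | levels != round(levels)))
    fail_validation("response",
                    sprintf("item levels must be integers in 1..%d",
                            tariff$max_level))
  u <- 1
  if (any(levels > 1)) u <- u - tariff$any_dysfunction
  if (any(levels == tariff$max_level)) u <- u - tariff$worst_level
  d <- tariff$decrements
  for (j in seq_len(nd)) {
    if (levels[j] > 1) {
      hit <- d$dimension == tariff$dimensions[j] & d$level == levels[j]
      if (any(hit)) u <- u - d$decrement[hit][1]
    }
  }
  u
}

#' Value an EQ-5D-3L response with a tariff
#'
#' @param response integer vector of five item levels in `{1, 2, 3}`
#'   (mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression), or a 5-column matrix/data frame of responses.
#'   `NA` anywhere in a response yields `NA` (left for imputation).
#' @param tariff a `utility_tariff`; default [eq5d_tariff_uk()].
#' @return utility value(s); 1 for full health, possibly negative.
#' @export
value_eq5d <- function(response, tariff = eq5d_tariff_uk()) {
  stopifnot(inherits(tariff, "utility_tariff"))
  if (is.data.frame(response)) response <- as.matrix(response)
  if (is.matrix(response))
    return(apply(response, 1L, value_response, tariff = tariff))
  value_response(response, tariff)
}

#' A synthetic condition-specific utility mapping
#'
#' Additive utility mapping for an eight-item, four-level lower urinary
#' tract symptom quality-of-life questionnaire. The published mapping
#' algorithm's coefficients are not reproduced here; this table is a
#' synthetic stand-in of the same additive shape, calibrated so valued
#' utilities for a treated population fall in the narrow 0.94-0.99 band
#' typical of the instrument. It is configuration, not an authority.
#'
#' @return a `utility_tariff` with `max_level = 4`.
#' @export
iciq_mapping_synthetic <- function() {
  items <- paste0("item", 1:8)
  utility_tariff(
    any_dysfunction = 0.004,
    worst_level = 0.020,
    decrements = data.frame(
      dimension = rep(items, each = 3L),
      level = rep(2:4, times = 8L),
      decrement = rep(c(0.004, 0.010, 0.020), times = 8L)
    ),
    max_level = 4L
  )
}

#' Value a condition-specific questionnaire response
#'
#' Applies an additive coefficient mapping (same shape as an EQ-5D
#' tariff) to ordinal item responses. A response with any missing item
#' is marked missing rather than raising an error, so downstream
#' multiple imputation can handle it.
#'
#' @param response integer item levels (or matrix/data frame of them).
#' @param mapping a `utility_tariff`; default [iciq_mapping_synthetic()].
#' @return utility value(s).
#' @export
value_iciq <- function(response, mapping = iciq_mapping_synthetic()) {
  value_eq5d(response, tariff = mapping)
}

#' Read / write a tariff coefficient table
#'
#' CSV format: columns `dimension`, `level`, `decrement`. Constants are
#' carried as rows with dimension `"any_dysfunction"` and
#' `"worst_level"` (level blank).
#'
#' @param path file path.
#' @param tariff a `utility_tariff` (for writing).
#' @param max_level worst level per item.
#' @return `read_tariff` returns a `utility_tariff`.
#' @export
read_tariff <- function(path, max_level = 3L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("dimension", "level", "decrement") %in% names(tab)),
             "tariff file", "needs columns dimension, level, decrement")
  const <- function(name) {
    row <- tab$dimension == name
    if (!any(row)) 0 else tab$decrement[row][1]
  }
  body <- tab[!tab$dimension %in% c("any_dysfunction", "worst_level"), ]
  utility_tariff(any_dysfunction = const("any_dysfunction"),
                 worst_level = const("worst_level"),
                 decrements = body, max_level = max_level)
}

#' @rdname read_tariff
#' @export
write_tariff <- function(tariff, path) {
  stopifnot(inherits(tariff, "utility_tariff"))
  tab <- rbind(
    data.frame(dimension = c("any_dysfunction", "worst_level"),
               level = NA_integer_,
               decrement = c(tariff$any_dysfunction, tariff$worst_level)),
    tariff$decrements[, c("dimension", "level", "decrement")]
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Enumerate all EQ-5D-3L health states
#'
#' @return a 243-row matrix of item levels, one state per row.
#' @export
eq5d_states <- function() {
  g <- as.matrix(expand.grid(rep(list(1:3), 5L)))
  colnames(g) <- EQ5D_DIMENSIONS
  g
}
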