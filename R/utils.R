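# Internal helpers shared across modules.

#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from one master seed; independent
#' components (generation, missingness, imputation, bootstrap) draw from
#' named substreams so that varying one component leaves the others
#' unchanged. The derived seed is always a valid 32-bit R integer.
#'
#' @param master integer master seed.
#' @param stream character name of the substream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% 1000000007
  as.integer((abs(master) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under `seed` without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Named validation error used by all constructors.
fail_validation <- function(field, msg) {
  stop(structure(
    class = c("trialcea_validation_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg), call = NULL)
  ))
}

check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) fail_validation(field, msg)
  invisible(TRUE)
}

# Round to pence; ledgers hold currency at exact 2-decimal precision.
pence <- function(x) round(x, 2)

#' Convert a QALY difference to equivalent days of full health
#'
#' A QALY increment of `q` corresponds to `q * 365.25` days lived at a
#' utility of 1. Used to express small incremental QALYs on an
#' interpretable scale (e.g. 0.005 QALYs is under 2 days of full health).
#'
#' @param qalys numeric QALY value(s).
#' @return days of full health.
#' @export
qalys_to_days <- function(qalys) qalys * 365.25

DAYS_PER_YEAR <- 365.25
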