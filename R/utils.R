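#' Logistic link helpers
#'
#' `invlogit()` maps the real line to (0, 1); `logit()` is its inverse.
#' Thin wrappers around [stats::plogis()] / [stats::qlogis()] kept for
#' readability in model code.
#'
#' @param x Numeric vector.
#' @param p Probabilities in (0, 1).
#' @return Numeric vector.
#' @keywords internal
#' @export
invlogit <- function(x) stats::plogis(x)

#' @rdname invlogit
#' @export
logit <- function(p) stats::qlogis(p)

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  lo <- x <= 30
  out[lo] <- log1p(exp(x[lo]))
  out
}

# Stop unless all values are finite; `what` names the offender in the message.
check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("non-finite values in %s", what))
  }
  invisible(x)
}

# Derive a reproducible stage seed from a master seed. Offsets are fixed per
# stage so stages can be rerun independently; result kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Parse ISO-8601 date strings (passing Date input through); invalid strings
# become NA rather than an error, so callers can report them by row.
parse_dates <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(as.character(x), format = "%Y-%m-%d")
}
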