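# internal helpers: argument checking, seeding, rounding

assert_number <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric and non-missing.", name))
  }
  if (any(x < lower) || any(x > upper)) {
    abort(sprintf("`%s` must lie in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lower ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, lower))
  }
  invisible(as.integer(x))
}

# seed handling: all stochastic entry points take `seed`; NULL leaves the
# caller's RNG stream untouched, an integer gives a local reproducible stream
local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(seed)
}

#' Half-up rounding for reported tables
#'
#' Base `round()` rounds half to even; reported index tables use the
#' conventional half-up rule. Raw values are always retained alongside.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
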