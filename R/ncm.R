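#' Per-OTU occurrence statistics for the neutral model
#'
#' For each OTU: `p`, the mean across sites of its relative abundance, and
#' `freq`, the fraction of sites where its relative abundance reaches the
#' detection limit. `N` is the mean per-site total count and the default
#' detection limit is `1/N` (one read at average depth), the standard
#' convention for Sloan fits.
#'
#' @param table OTU table (sites x OTUs).
#' @param detection_limit relative-abundance detection threshold; default
#'   `1/mean(rowSums(table))`.
#' @return tibble (otu, p, freq) with attributes `N` (mean depth),
#'   `n_sites`, and `detection_limit`.
#' @export
occurrence_stats <- function(table, detection_limit = NULL) {
  m <- unclass(table)
  if (nrow(m) == 0 || ncol(m) == 0) abort("Empty OTU table.")
  totals <- rowSums(m)
  if (any(totals <= 0)) abort("Positive row totals required.")
  N <- mean(totals)
  detection_limit <- detection_limit %||% (1 / N)
  rel <- m / totals
  out <- tibble(otu = colnames(m), p = unname(colMeans(rel)),
                freq = unname(colMeans(rel >= detection_limit)))
  attr(out, "N") <- N
  attr(out, "n_sites") <- nrow(m)
  attr(out, "detection_limit") <- detection_limit
  out
}

ncm_predict <- function(p, m, N) {
  1 - pbeta(1 / N, N * m * p, N * m * (1 - p))
}

#' Fit the Sloan neutral community model
#'
#' The model predicts a taxon's occurrence frequency from its metacommunity
#' mean relative abundance:
#' `Freq_i = 1 - I(1/N | N m p_i, N m (1 - p_i))`, with `I` the beta CDF,
#' `N` the individuals per community and `m` the migration probability. The
#' single free parameter `m` is estimated by bounded least squares on the
#' observed frequencies (coarse log-spaced grid, then golden-section
#' refinement); a fit stuck at a bound is flagged, not silent. `R^2` uses
#' the centered total sum of squares by default (the common reporting
#' convention; `r2 = "uncentered"` for the alternative). Each OTU is
#' partitioned against a Wilson binomial envelope (at `n_sites` trials)
#' around its predicted frequency.
#'
#' @param x an OTU table or the tibble from [occurrence_stats()].
#' @param N individuals per community; taken from `x` when it carries the
#'   `occurrence_stats()` attributes.
#' @param ci_level envelope coverage (default 0.95).
#' @param r2 `"centered"` (default) or `"uncentered"`.
#' @param detection_limit forwarded to [occurrence_stats()] when `x` is a
#'   count table.
#' @return object of class `ncm_fit`: m, N, Nm, r_squared, and a per-OTU
#'   tibble with predicted frequencies, Wilson bounds and partition
#'   (above/within/below).
#' @export
ncm_fit <- function(x, N = NULL, ci_level = 0.95,
                    r2 = c("centered", "uncentered"), detection_limit = NULL) {
  r2 <- match.arg(r2)
  if (is.matrix(x)) x <- occurrence_stats(x, detection_limit = detection_limit)
  N <- N %||% attr(x, "N")
  n_sites <- attr(x, "n_sites") %||% NA_integer_
  if (is.null(N)) abort("Supply `N` (individuals per community).")
  dat <- dplyr::filter(as_tibble(x), .data$p > 0, .data$freq > 0)
  if (nrow(dat) < 10) abort("Need >= 10 OTUs with positive p and freq to fit.")
  sse <- function(m) sum((dat$freq - ncm_predict(dat$p, m, N))^2)
  grid <- 10^seq(-6, 0, length.out = 121)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimise(sse, lower = lo, upper = hi, tol = 1e-10)
  m_hat <- opt$minimum
  boundary <- m_hat >= 1 - 1e-6 || m_hat <= 1.1e-6
  pred <- ncm_predict(dat$p, m_hat, N)
  sst <- if (r2 == "centered") sum((dat$freq - mean(dat$freq))^2) else sum(dat$freq^2)
  r_squared <- 1 - opt$objective / sst
  ci <- wilson_interval(pred, n = n_sites, level = ci_level)
  dat$predicted_freq <- pred
  dat$ci_lower <- ci$lower
  dat$ci_upper <- ci$upper
  dat$partition <- dplyr::case_when(
    dat$freq > dat$ci_upper ~ "above",
    dat$freq < dat$ci_lower ~ "below",
    TRUE ~ "within"
  )
  structure(
    list(m = m_hat, N = N, Nm = N * m_hat, r_squared = r_squared,
         n_sites = n_sites, n_otus = nrow(dat), ci_level = ci_level,
         r2_convention = r2, boundary = boundary, otus = dat),
    class = "ncm_fit"
  )
}

# Wilson score interval for a proportion `p` observed over n trials
wilson_interval <- function(p, n, level = 0.95) {
  if (is.null(n) || is.na(n)) abort("Wilson interval needs the number of sites.")
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf(
    "Sloan neutral community model fit\n  m = %.5g  N = %.5g  Nm = %.5g  R2 = %.4f (%s)\n  %d OTUs over %s sites%s\n",
    x$m, x$N, x$Nm, x$r_squared, x$r2_convention, x$n_otus,
    format(x$n_sites), if (x$boundary) "  [optimizer at bound]" else ""))
  invisible(x)
}

#' @describeIn ncm_fit per-OTU table (p, freq, predicted_freq, Wilson
#'   bounds, partition).
#' @param x an `ncm_fit`.
#' @param ... unused.
#' @export
tidy.ncm_fit <- function(x, ...) x$otus

#' @describeIn ncm_fit one-row model summary (m, N, Nm, r_squared,
#'   partition shares, boundary flag).
#' @export
glance.ncm_fit <- function(x, ...) {
  shares <- prop.table(table(factor(x$otus$partition,
                                    levels = c("below", "within", "above"))))
  tibble(m = x$m, N = x$N, Nm = x$Nm, r_squared = x$r_squared,
         n_otus = x$n_otus, n_sites = x$n_sites,
         frac_below = as.numeric(shares["below"]),
         frac_within = as.numeric(shares["within"]),
         frac_above = as.numeric(shares["above"]),
         boundary = x$boundary)
}
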