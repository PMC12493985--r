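#' TRIX scale coefficients
#'
#' The trophic index maps the log10 product of its four state variables onto
#' a 0-10 scale with an offset `x` and divisor `m` (defaults 1.5 and 1.2,
#' the coastal calibration in routine use). This `m` is a scale divisor, not
#' the neutral-model migration rate.
#'
#' @param x scale offset.
#' @param m scale divisor (non-zero).
#' @return named list used by [trix()].
#' @export
trix_coefficients <- function(x = 1.5, m = 1.2) {
  assert_number(x, "x")
  assert_number(m, "m")
  if (m == 0) abort("TRIX divisor `m` must be non-zero.")
  list(x = x, m = m)
}

#' Dissolved inorganic nitrogen, molar to mass
#'
#' Nutrients are measured in umol/L but the TRIX formula takes ug/L; the
#' conversion uses the atomic mass of nitrogen (14.007 g/mol).
#'
#' @param ammonia,nitrite,nitrate concentrations in umol/L.
#' @return DIN in ug N/L.
#' @export
din_mass <- function(ammonia, nitrite, nitrate) {
  assert_number(ammonia, "ammonia", lower = 0)
  assert_number(nitrite, "nitrite", lower = 0)
  assert_number(nitrate, "nitrate", lower = 0)
  (ammonia + nitrite + nitrate) * 14.007
}

#' Soluble reactive phosphorus, molar to mass
#'
#' @param phosphate concentration in umol/L.
#' @return P in ug P/L (atomic mass 30.974 g/mol).
#' @export
srp_mass <- function(phosphate) {
  assert_number(phosphate, "phosphate", lower = 0)
  phosphate * 30.974
}

#' Oxygen solubility of seawater at 1 atm
#'
#' Weiss (1970) fit of the Benson-Krause solubility data as a function of
#' temperature and salinity; used to turn a measured DO concentration into a
#' percent-saturation deviation when the saturation percentage was not
#' recorded directly.
#'
#' @param temperature deg C.
#' @param salinity practical salinity (dimensionless).
#' @return equilibrium O2 concentration in mg/L.
#' @export
oxygen_saturation <- function(temperature, salinity) {
  assert_number(temperature, "temperature", lower = -2, upper = 40)
  assert_number(salinity, "salinity", lower = 0, upper = 42)
  tk <- temperature + 273.15
  ln_c <- -173.4292 + 249.6339 * (100 / tk) + 143.3483 * log(tk / 100) -
    21.8492 * (tk / 100) +
    salinity * (-0.033096 + 0.014259 * (tk / 100) - 0.0017000 * (tk / 100)^2)
  # mL/L -> mg/L via the molar volume of O2 (1.42905 mg per mL STP)
  exp(ln_c) * 1.42905
}

#' Absolute percent oxygen deviation from saturation
#'
#' If the saturation percentage is available it is used directly; otherwise
#' the saturation concentration is computed from temperature and salinity.
#'
#' @param do dissolved oxygen, mg/L.
#' @param temperature,salinity required when `do_saturation_pct` is `NULL`.
#' @param do_saturation_pct measured saturation, percent.
#' @return aD\%O, percent (absolute deviation from 100\%).
#' @export
oxygen_deviation <- function(do = NULL, temperature = NULL, salinity = NULL,
                             do_saturation_pct = NULL) {
  if (!is.null(do_saturation_pct)) {
    assert_number(do_saturation_pct, "do_saturation_pct", lower = 0)
    return(abs(do_saturation_pct - 100))
  }
  if (is.null(do) || is.null(temperature) || is.null(salinity)) {
    abort("Need either `do_saturation_pct` or all of `do`, `temperature`, `salinity`.")
  }
  assert_number(do, "do", lower = 0)
  abs(100 * do / oxygen_saturation(temperature, salinity) - 100)
}

#' Trophic index (TRIX)
#'
#' `TRIX = (log10(chl_a * adO * din * p) + x) / m`, combining primary
#' production (chlorophyll-a, oxygen deviation) and nutrient state (DIN,
#' SRP) on a log scale. A zero factor makes the index undefined and is an
#' error, never a numeric result.
#'
#' @param chl_a chlorophyll-a, ug/L.
#' @param adO absolute percent oxygen deviation from saturation.
#' @param din dissolved inorganic nitrogen, ug/L.
#' @param p soluble reactive phosphorus, ug/L.
#' @param coeffs see [trix_coefficients()].
#' @return TRIX value (dimensionless).
#' @export
trix <- function(chl_a, adO, din, p, coeffs = trix_coefficients()) {
  for (v in list(chl_a = chl_a, adO = adO, din = din, p = p)) {
    assert_number(v, "TRIX factor", lower = 0)
  }
  prod4 <- chl_a * adO * din * p
  if (any(prod4 == 0)) abort("TRIX undefined (zero factor).")
  (log10(prod4) + coeffs$x) / coeffs$m
}

#' Classify a TRIX value on the three-state scale
#'
#' `TRIX <= 4` oligotrophic, `4 < TRIX <= 5` mesotrophic, `TRIX > 5`
#' eutrophic; boundary values go to the lower-severity class.
#'
#' @param trix_value finite TRIX value(s).
#' @return factor with levels oligotrophic/mesotrophic/eutrophic.
#' @export
classify_trix <- function(trix_value) {
  if (any(!is.finite(trix_value))) abort("TRIX must be finite to classify.")
  cut(trix_value, breaks = c(-Inf, 4, 5, Inf),
      labels = c("oligotrophic", "mesotrophic", "eutrophic"),
      right = TRUE)
}

#' Sediment organic nitrogen
#'
#' `ON = TN x 95%`, total nitrogen in percent dry weight.
#'
#' @param tn total nitrogen, percent dry weight.
#' @return ON, percent dry weight.
#' @export
organic_nitrogen <- function(tn) {
  assert_number(tn, "tn", lower = 0, upper = 100)
  tn * 0.95
}

#' Sediment organic index
#'
#' `OI = TOC x ON`, both in percent dry weight.
#'
#' @param toc total organic carbon, percent dry weight.
#' @param on organic nitrogen, percent dry weight (see [organic_nitrogen()]).
#' @return OI (percent x percent).
#' @export
organic_index <- function(toc, on) {
  assert_number(toc, "toc", lower = 0, upper = 100)
  assert_number(on, "on", lower = 0)
  toc * on
}

#' Default sediment pollution-level thresholds
#'
#' Four levels (I uncontaminated ... IV heavily eutrophic). The OI bounds
#' are the published scheme (<0.05, 0.05-0.20, 0.20-0.50, >=0.50). The ON
#' scheme in circulation is inconsistently transcribed across sources; the
#' defaults fix the outer bounds at 0.0033 and 0.13 and use the common
#' literature value 0.066 for the middle boundary. All bounds configurable.
#'
#' @return list with numeric vectors `oi` and `on` (three ascending bounds).
#' @export
sediment_thresholds <- function() {
  list(oi = c(0.05, 0.20, 0.50), on = c(0.0033, 0.066, 0.13))
}

classify_levels <- function(x, bounds) {
  if (is.unsorted(bounds, strictly = TRUE)) {
    abort("Pollution-level thresholds must be strictly increasing.")
  }
  # lower bound inclusive: x == bounds[i] falls in the higher level
  cut(x, breaks = c(-Inf, bounds, Inf), labels = c("I", "II", "III", "IV"),
      right = FALSE)
}

#' Classify sediment pollution levels from OI and ON
#'
#' @param oi organic index value(s).
#' @param on organic nitrogen value(s), percent.
#' @param thresholds see [sediment_thresholds()].
#' @return tibble with `oi_level` and `on_level` factors (I-IV),
#'   lower-bound-inclusive.
#' @export
classify_sediment <- function(oi, on, thresholds = sediment_thresholds()) {
  tibble(oi_level = classify_levels(oi, thresholds$oi),
         on_level = classify_levels(on, thresholds$on))
}

#' Per-site trophic status of overlying water
#'
#' Pipeline wrapper: molar-to-mass conversion, oxygen deviation, TRIX and its
#' classification for every site in a water-chemistry table. Sites with any
#' missing factor get `NA` (index not computable) rather than a guessed zero.
#'
#' @param water data frame with columns `site_id`, `chl_a` (ug/L),
#'   `ammonia`, `nitrite`, `nitrate`, `phosphate` (umol/L), and either
#'   `do_saturation_pct` or `do` (mg/L) plus `temperature` (deg C) and
#'   `salinity`.
#' @param coeffs see [trix_coefficients()].
#' @return tibble: site_id, din, srp, ado, trix, trix_class.
#' @export
trophic_status <- function(water, coeffs = trix_coefficients()) {
  water <- as_tibble(water)
  need <- c("site_id", "chl_a", "ammonia", "nitrite", "nitrate", "phosphate")
  missing_cols <- setdiff(need, names(water))
  if (length(missing_cols)) {
    abort(sprintf("Water table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  one_site <- function(row) {
    ado <- tryCatch({
      if (!is.null(row$do_saturation_pct) && !is.na(row$do_saturation_pct %||% NA)) {
        oxygen_deviation(do_saturation_pct = row$do_saturation_pct)
      } else {
        oxygen_deviation(do = row$do, temperature = row$temperature,
                         salinity = row$salinity)
      }
    }, error = function(e) NA_real_)
    vals <- c(row$chl_a, row$ammonia, row$nitrite, row$nitrate, row$phosphate, ado)
    if (anyNA(vals)) {
      return(tibble(din = NA_real_, srp = NA_real_, ado = ado,
                    trix = NA_real_))
    }
    din <- din_mass(row$ammonia, row$nitrite, row$nitrate)
    srp <- srp_mass(row$phosphate)
    tx <- tryCatch(trix(row$chl_a, ado, din, srp, coeffs),
                   error = function(e) NA_real_)
    tibble(din = din, srp = srp, ado = ado, trix = tx)
  }
  res <- purrr::map_dfr(seq_len(nrow(water)),
                        function(i) one_site(as.list(water[i, ])))
  out <- dplyr::bind_cols(tibble(site_id = water$site_id), res)
  out$trix_class <- factor(NA, levels = c("oligotrophic", "mesotrophic", "eutrophic"))
  ok <- is.finite(out$trix)
  out$trix_class[ok] <- classify_trix(out$trix[ok])
  out
}

#' Per-site sediment eutrophication status
#'
#' Computes ON and OI from total nitrogen and total organic carbon and
#' assigns pollution levels I-IV. Raw values are retained; `*_report`
#' columns carry the half-up two-decimal values used in summary tables.
#'
#' @param sediment data frame with `site_id`, `toc`, `tn` (percent dry weight).
#' @param thresholds see [sediment_thresholds()].
#' @return tibble: site_id, on, oi, on_report, oi_report, on_level, oi_level.
#' @export
sediment_status <- function(sediment, thresholds = sediment_thresholds()) {
  sediment <- as_tibble(sediment)
  missing_cols <- setdiff(c("site_id", "toc", "tn"), names(sediment))
  if (length(missing_cols)) {
    abort(sprintf("Sediment table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  on <- ifelse(is.na(sediment$tn), NA_real_, sediment$tn * 0.95)
  oi <- ifelse(is.na(sediment$toc) | is.na(on), NA_real_, sediment$toc * on)
  lv <- classify_sediment(oi, on, thresholds)
  tibble(site_id = sediment$site_id, on = on, oi = oi,
         on_report = round_half_up(on, 2), oi_report = round_half_up(oi, 2),
         on_level = lv$on_level, oi_level = lv$oi_level)
}
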