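# Method-performance statistics: matrix effect, intra-day precision,
# calibration linearity, method limit of detection from peak-to-peak S/N,
# and the screening false-positive / false-negative rates.

#' Calibration series
#'
#' Concentration-response (and optionally S/N) pairs for one analyte in one
#' context (solvent standards or matrix-matched standards). The method's
#' working range is 10-500 mg/L before the 100-fold dilution.
#'
#' @param analyte Compound abbreviation.
#' @param concentration Concentrations in mg/L (> 0).
#' @param area Peak areas (counts * s).
#' @param snr Optional peak-to-peak S/N per level.
#' @param context `"solvent"` or `"matrix"`.
#' @return A `calibration_series` data frame with attributes.
#' @export
calibration_series <- function(analyte, concentration, area, snr = NULL,
                               context = c("solvent", "matrix")) {
  context <- match.arg(context)
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (length(unique(concentration)) < 2) {
    stop("need at least 2 distinct concentrations")
  }
  d <- data.frame(concentration = as.numeric(concentration),
                  area = as.numeric(area))
  d$snr <- if (is.null(snr)) NA_real_ else as.numeric(snr)
  d <- d[order(d$concentration), ]
  structure(d, analyte = analyte, context = context,
            class = c("calibration_series", "data.frame"))
}

#' Matrix effect in percent
#'
#' Relative difference between the peak area in matrix-matched solution and
#' in solvent standard at the same concentration:
#' `100 * (area_matrix - area_solvent) / area_solvent`. Negative values are
#' ionization suppression, positive enhancement.
#'
#' @param area_matrix,area_solvent Peak areas (counts * s); `area_solvent`
#'   must be positive.
#' @return Percent (double).
#' @export
matrix_effect_pct <- function(area_matrix, area_solvent) {
  if (any(area_solvent <= 0)) stop("solvent area must be positive")
  100 * (area_matrix - area_solvent) / area_solvent
}

#' Relative standard deviation in percent
#'
#' `100 * sd(values) / mean(values)` (sample standard deviation).
#'
#' @param values At least 2 replicate responses; mean must be nonzero.
#' @return Percent (double).
#' @export
rsd_pct <- function(values) {
  if (length(values) < 2) stop("need at least 2 replicates")
  m <- mean(values)
  if (m == 0) stop("mean of replicates is zero")
  100 * stats::sd(values) / m
}

#' Calibration linearity
#'
#' Ordinary least squares of response area on concentration, with the
#' Pearson correlation coefficient r the method's linearity criterion is
#' stated in (satisfactory calibrations reach r > 0.977 across the working
#' range).
#'
#' @param series A [calibration_series()] with >= 3 levels.
#' @return List: `slope`, `intercept`, `r`.
#' @export
linear_fit <- function(series) {
  if (length(unique(series$concentration)) < 3) {
    stop("need at least 3 distinct concentrations for a meaningful r")
  }
  fit <- stats::lm(area ~ concentration, data = series)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = stats::cor(series$concentration, series$area)
  )
}

#' Method limit of detection from peak-to-peak S/N
#'
#' Straight-line fit of S/N against concentration over the lowest levels
#' with finite S/N; the MLOD is the concentration at which the fitted line
#' reaches the target S/N (default 3), clipped to positive.
#'
#' @param series A [calibration_series()] carrying `snr` values.
#' @param snr_target Target S/N defining the limit, default 3.
#' @param n_levels Number of lowest finite-S/N levels used in the fit;
#'   default all of them.
#' @return MLOD in mg/L.
#' @export
estimate_mlod <- function(series, snr_target = 3.0, n_levels = Inf) {
  ok <- is.finite(series$snr)
  if (sum(ok) < 2) stop("not estimable: need >= 2 levels with finite S/N")
  d <- series[ok, ]
  d <- utils::head(d[order(d$concentration), ], min(n_levels, nrow(d)))
  if (length(unique(d$concentration)) < 2) {
    stop("not estimable: S/N known at fewer than 2 distinct concentrations")
  }
  fit <- stats::lm(snr ~ concentration, data = d)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 1e-12) {
    if (all(d$snr < snr_target)) {
      stop("not estimable: S/N below target and non-increasing")
    }
    stop("not estimable: S/N does not increase with concentration")
  }
  mlod <- (snr_target - unname(stats::coef(fit)[1])) / slope
  max(mlod, .Machine$double.eps)
}

#' Screening error rates
#'
#' False-positive rate over the non-spiked panel members,
#' `100 * fp / (fp + tn)`; false-negative rate over the spiked members,
#' `100 * fn / (fn + tp)`. A rate with an empty denominator is `NaN`.
#'
#' @param truth Character vector of spiked compounds.
#' @param predicted Character vector of screening hits (must be within the
#'   panel).
#' @param panel All library compounds under evaluation.
#' @return List: `fp_pct`, `fn_pct`, and `counts` (tp, fp, fn, tn).
#' @export
confusion_rates <- function(truth, predicted, panel) {
  if (length(panel) == 0) stop("empty panel")
  if (length(setdiff(predicted, panel)) > 0) {
    stop("predicted compounds outside the panel: ",
         paste(setdiff(predicted, panel), collapse = ", "))
  }
  truth <- intersect(panel, truth)
  tp <- length(intersect(truth, predicted))
  fn <- length(setdiff(truth, predicted))
  fp <- length(setdiff(predicted, truth))
  tn <- length(panel) - tp - fn - fp
  list(
    fp_pct = 100 * fp / (fp + tn),
    fn_pct = 100 * fn / (fn + tp),
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn)
  )
}
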