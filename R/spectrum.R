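# Spectrum data model and the preprocessing chain applied identically at
# library-build and query time: restrict to the acquisition range, bin to
# nominal (integer) m/z, normalize to the base peak, cut at the relative
# intensity threshold.

#' Centroided spectrum
#'
#' @param mz Numeric m/z values (Da, >= 0).
#' @param intensity Numeric intensities (counts, >= 0), same length.
#' @param cone_voltage Integer cone voltage of the acquisition channel (V).
#' @param scan_range Length-2 numeric, the acquired m/z window; default the
#'   instrument's full-scan window 50-600 Da.
#' @param mode `"full_scan"` or `"sir"`.
#' @param metadata Free-form named list.
#' @return An `ms_spectrum`: a list with a `peaks` data frame (`mz`,
#'   `intensity`, sorted by m/z) plus acquisition metadata.
#' @export
ms_spectrum <- function(mz, intensity, cone_voltage = NA_integer_,
                        scan_range = c(50, 600), mode = "full_scan",
                        metadata = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stop("m/z and intensity must be finite")
  }
  if (any(mz < 0) || any(intensity < 0)) {
    stop("m/z and intensity must be non-negative")
  }
  mode <- match.arg(mode, c("full_scan", "sir"))
  ord <- order(mz)
  structure(
    list(
      peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
      cone_voltage = as.integer(cone_voltage),
      scan_range = as.numeric(scan_range),
      mode = mode,
      metadata = metadata
    ),
    class = "ms_spectrum"
  )
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms_spectrum> %d peaks, cone %s V, m/z %g-%g, %s\n",
    nrow(x$peaks), x$cone_voltage, x$scan_range[1], x$scan_range[2], x$mode
  ))
  if (nrow(x$peaks) > 0) {
    top <- x$peaks[order(-x$peaks$intensity), , drop = FALSE]
    top <- utils::head(top, 8)
    cat("  top peaks:",
        paste(sprintf("%g (%.4g)", top$mz, top$intensity), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
plot.ms_spectrum <- function(x, ...) {
  p <- x$peaks
  plot(NA, xlim = x$scan_range, ylim = c(0, max(p$intensity, 1)),
       xlab = "m/z", ylab = "intensity",
       main = sprintf("cone %s V", x$cone_voltage), ...)
  segments(p$mz, 0, p$mz, p$intensity)
  invisible(x)
}

spectrum_replace_peaks <- function(s, mz, intensity) {
  s$peaks <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity))
  s
}

#' Four-channel acquisition
#'
#' Bundles one full-scan spectrum per configured cone voltage. The method's
#' acquisition scheme records all channels in one run; exactly the configured
#' voltages must be present and are kept in ascending order.
#'
#' @param channels Named list of [ms_spectrum()]; names are voltages.
#' @param voltages Required voltages, default `c(12, 20, 30, 40)`.
#' @return An `ms_multichannel` (named list of spectra, ascending voltage).
#' @export
ms_multichannel <- function(channels, voltages = c(12L, 20L, 30L, 40L)) {
  got <- as.integer(names(channels))
  missing <- setdiff(voltages, got)
  if (length(missing) > 0) {
    stop("missing channel ", paste(missing, collapse = ", "), " V")
  }
  extra <- setdiff(got, voltages)
  if (length(extra) > 0) {
    stop("unexpected channel ", paste(extra, collapse = ", "), " V")
  }
  channels <- channels[order(got)]
  for (v in names(channels)) {
    channels[[v]]$cone_voltage <- as.integer(v)
  }
  structure(channels, class = "ms_multichannel")
}

#' @export
print.ms_multichannel <- function(x, ...) {
  cat(sprintf("<ms_multichannel> %d channels (%s V)\n", length(x),
              paste(names(x), collapse = ", ")))
  for (s in x) print(s)
  invisible(x)
}

channel_voltages <- function(x) as.integer(names(x))

#' Preprocessing parameters
#'
#' @param scan_low,scan_high Retained m/z window (Da), default 50-600.
#' @param threshold_pct Relative-intensity cut in percent of the base peak,
#'   default 5. The comparison is inclusive (`>=`) so a peak at exactly the
#'   threshold survives; set `inclusive = FALSE` for strict `>`.
#' @param inclusive Logical, see above.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(scan_low = 50, scan_high = 600,
                              threshold_pct = 5, inclusive = TRUE) {
  if (scan_low >= scan_high) stop("scan_low must be below scan_high")
  if (threshold_pct <= 0 || threshold_pct > 100) {
    stop("threshold_pct must be in (0, 100]")
  }
  structure(
    list(scan_low = as.numeric(scan_low), scan_high = as.numeric(scan_high),
         threshold_pct = as.numeric(threshold_pct),
         inclusive = isTRUE(inclusive)),
    class = "preprocess_params"
  )
}

params_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b)))
}

#' Scale a spectrum to relative intensities
#'
#' Base peak at 100; ratios preserved. Relative intensities are rounded to
#' 4 decimals so that normalized spectra have an exact, serializable decimal
#' representation.
#'
#' @param s An [ms_spectrum()].
#' @return The spectrum with intensities on the 0-100 relative scale.
#' @export
normalize_relative <- function(s) {
  p <- s$peaks
  if (nrow(p) == 0 || max(p$intensity) <= 0) {
    stop("cannot normalize an empty or all-zero spectrum")
  }
  spectrum_replace_peaks(s, p$mz, round(100 * p$intensity / max(p$intensity), 4))
}

#' Apply the relative-intensity threshold
#'
#' Retains peaks at or above `threshold_pct` percent of the base peak
#' (strictly above when `inclusive = FALSE`). Applied identically when
#' building the library and when screening queries; no background
#' subtraction is performed anywhere in the chain.
#'
#' @param s A normalized [ms_spectrum()].
#' @param threshold_pct Cut in percent, default 5.
#' @param inclusive Logical, default `TRUE` (`>=` semantics).
#' @return The thresholded spectrum.
#' @export
apply_threshold <- function(s, threshold_pct = 5, inclusive = TRUE) {
  if (threshold_pct <= 0 || threshold_pct > 100) {
    stop("threshold_pct must be in (0, 100]")
  }
  p <- s$peaks
  keep <- if (inclusive) p$intensity >= threshold_pct else p$intensity > threshold_pct
  spectrum_replace_peaks(s, p$mz[keep], p$intensity[keep])
}

#' Bin a spectrum to nominal (integer) m/z
#'
#' Each centroid's m/z is rounded to the nearest integer (round-half-to-even,
#' the IEC 60559 rule R's `round()` implements); intensities falling in the
#' same integer bin are summed, conserving total intensity.
#'
#' @param s An [ms_spectrum()].
#' @return The binned spectrum (integer m/z, re-sorted).
#' @export
bin_nominal <- function(s) {
  p <- s$peaks
  if (nrow(p) == 0) return(s)
  bins <- round(p$mz)
  agg <- tapply(p$intensity, bins, sum)
  spectrum_replace_peaks(s, as.numeric(names(agg)), as.numeric(agg))
}

#' Restrict a spectrum to the acquisition window
#'
#' @param s An [ms_spectrum()].
#' @param low,high Inclusive m/z bounds, default the full-scan window 50-600.
#' @return The restricted spectrum; `scan_range` updated.
#' @export
restrict_range <- function(s, low = 50, high = 600) {
  if (low >= high) stop("low must be below high")
  p <- s$peaks
  keep <- p$mz >= low & p$mz <= high
  s <- spectrum_replace_peaks(s, p$mz[keep], p$intensity[keep])
  s$scan_range <- c(low, high)
  s
}

#' Full preprocessing chain
#'
#' `restrict_range` then `bin_nominal` then `normalize_relative` then
#' `apply_threshold`, in that order, so the percent cut applies to binned
#' relative intensities. Idempotent: preprocessing a preprocessed spectrum
#' changes nothing.
#'
#' @param s An [ms_spectrum()].
#' @param params A [preprocess_params()].
#' @return The preprocessed spectrum.
#' @export
preprocess <- function(s, params = preprocess_params()) {
  s <- restrict_range(s, params$scan_low, params$scan_high)
  s <- bin_nominal(s)
  s <- normalize_relative(s)
  apply_threshold(s, params$threshold_pct, params$inclusive)
}

preprocess_multichannel <- function(x, params = preprocess_params()) {
  out <- lapply(x, preprocess, params = params)
  class(out) <- "ms_multichannel"
  out
}

# ---- scan-table CSV dialect ------------------------------------------------

#' Read a full-scan table CSV into a four-channel acquisition
#'
#' The scan-table dialect has columns `channel_voltage,scan_time_s,mz,
#' intensity`, one row per centroid. Centroids recorded at different scan
#' times within a channel are intensity-summed per m/z (the desorption event
#' is integrated over the run).
#'
#' @param path CSV file path.
#' @param voltages Required channel voltages, default `c(12, 20, 30, 40)`.
#' @return An [ms_multichannel()].
#' @export
read_scan_table <- function(path, voltages = c(12L, 20L, 30L, 40L)) {
  tab <- utils::read.csv(path)
  need <- c("channel_voltage", "scan_time_s", "mz", "intensity")
  if (!all(need %in% names(tab))) {
    stop("scan table must have columns ", paste(need, collapse = ", "))
  }
  channels <- lapply(split(tab, tab$channel_voltage), function(d) {
    agg <- tapply(d$intensity, d$mz, sum)
    ms_spectrum(as.numeric(names(agg)), as.numeric(agg),
                cone_voltage = d$channel_voltage[1])
  })
  ms_multichannel(channels, voltages = voltages)
}

#' Write a four-channel acquisition as a scan-table CSV
#'
#' @param x An [ms_multichannel()].
#' @param path Output CSV path.
#' @param scan_time_s Scan time stamp written on every row, default 0.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(x, path, scan_time_s = 0) {
  rows <- do.call(rbind, lapply(x, function(s) {
    if (nrow(s$peaks) == 0) return(NULL)
    data.frame(channel_voltage = s$cone_voltage, scan_time_s = scan_time_s,
               mz = s$peaks$mz, intensity = s$peaks$intensity)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
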