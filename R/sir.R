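# Selected-ion-recording (SIR) chronograms and the confirmation step that
# cross-checks library hits: a hit is confirmed when the 12 V chronogram at
# the compound's monitored m/z shows a peak with peak-to-peak S/N at or above
# the detection cut (default 3).

#' SIR chronogram
#'
#' Time-intensity trace for one monitored m/z. The desorption event produces
#' a single peak about 2 s wide; at the method's 10 Hz scan rate that is
#' roughly 12 data points over the peak.
#'
#' @param times Seconds, strictly increasing (nominally 10 Hz spacing).
#' @param intensities Counts, >= 0, same length (>= 2 points).
#' @param mz Monitored nominal m/z.
#' @param cone_voltage Acquisition voltage, 12 V for confirmation traces.
#' @return A `chronogram` list.
#' @export
chronogram <- function(times, intensities, mz = NA_integer_,
                       cone_voltage = 12L) {
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities)) stop("vector lengths differ")
  if (length(times) < 2) stop("chronogram needs at least 2 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(intensities < 0) || any(!is.finite(intensities))) {
    stop("intensities must be finite and non-negative")
  }
  structure(
    list(mz = as.integer(mz), times = times, intensities = intensities,
         cone_voltage = as.integer(cone_voltage)),
    class = "chronogram"
  )
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf(
    "<chronogram> m/z %s, %d points over %.2f s, max %.4g counts, cone %d V\n",
    x$mz, length(x$times), diff(range(x$times)), max(x$intensities),
    x$cone_voltage
  ))
  invisible(x)
}

#' @export
plot.chronogram <- function(x, ...) {
  plot(x$times, x$intensities, type = "l", xlab = "time (s)",
       ylab = "intensity", main = sprintf("SIR m/z %s", x$mz), ...)
  invisible(x)
}

#' Integrate the chronogram peak
#'
#' Apex is the global maximum (earliest time on ties); the peak region is
#' the contiguous run of points at or above 5% of the apex height that
#' contains the apex — the same 5% convention as the spectral threshold.
#' Area by the trapezoid rule over that region.
#'
#' @param c A [chronogram()].
#' @param region_frac Fraction of apex height bounding the peak region,
#'   default 0.05.
#' @return A `peak_measure` list: `apex_time`, `height`, `area`
#'   (counts * s), `n_points` (points in the region).
#' @export
integrate_peak <- function(c, region_frac = 0.05) {
  y <- c$intensities
  if (max(y) <= min(y)) stop("no peak: flat trace")
  apex <- which.max(y)  # which.max returns the first (earliest) maximum
  cut <- region_frac * y[apex]
  above <- y >= cut
  lo <- apex
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- apex
  while (hi < length(y) && above[hi + 1]) hi <- hi + 1
  idx <- lo:hi
  area <- if (length(idx) > 1) {
    sum(diff(c$times[idx]) * (utils::head(y[idx], -1) + utils::tail(y[idx], -1)) / 2)
  } else 0
  structure(
    list(apex_time = c$times[apex], height = y[apex], area = area,
         n_points = length(idx)),
    class = "peak_measure"
  )
}

#' Peak-to-peak signal-to-noise of a chronogram
#'
#' S/N = (apex height - median of the noise window) / (max - min of the
#' noise window). The noise window is a time interval that must exclude the
#' peak region; a noiseless window (zero amplitude) yields `Inf`.
#'
#' @param c A [chronogram()].
#' @param noise_window Length-2 numeric time interval (s); default the first
#'   fifth of the trace, which precedes the desorption event in this
#'   method's acquisitions.
#' @return S/N as a double (possibly `Inf`).
#' @export
snr_peak_to_peak <- function(c, noise_window = NULL) {
  if (is.null(noise_window)) {
    noise_window <- c(c$times[1],
                      c$times[1] + 0.2 * diff(range(c$times)))
  }
  in_win <- c$times >= noise_window[1] & c$times <= noise_window[2]
  if (sum(in_win) < 2) stop("noise window contains fewer than 2 points")
  noise <- c$intensities[in_win]
  amplitude <- max(noise) - min(noise)
  signal <- max(c$intensities) - stats::median(noise)
  if (amplitude <= 0) return(Inf)
  signal / amplitude
}

#' Confirm library hits against SIR chronograms
#'
#' Adds `sir_confirmed` (and `sir_snr`) to a screening report: a hit is
#' confirmed when the chronogram at the compound's monitored m/z reaches
#' S/N >= `snr_min`. Hits with no chronogram or a flat/absent trace are
#' marked unconfirmed with a warning, never promoted; non-hits are never
#' confirmed, so confirmation can only remove detections.
#'
#' @param report A `screening_report` from [screen()].
#' @param chronograms Named list, m/z (as character) -> [chronogram()].
#' @param registry A `compound_registry` supplying each compound's
#'   monitored m/z.
#' @param snr_min Confirmation cut on peak-to-peak S/N, default 3.
#' @param noise_window Passed to [snr_peak_to_peak()].
#' @return The report with `sir_snr` and `sir_confirmed` columns.
#' @export
confirm_hits <- function(report, chronograms, registry = default_registry(),
                         snr_min = 3.0, noise_window = NULL) {
  snr <- rep(NA_real_, nrow(report))
  confirmed <- rep(FALSE, nrow(report))
  for (i in seq_len(nrow(report))) {
    if (!report$hit[i]) next
    abbr <- report$compound[i]
    mz <- as.character(registry[[abbr]]$sir_mz)
    tr <- chronograms[[mz]]
    if (is.null(tr)) {
      warning("no SIR chronogram at m/z ", mz, " for hit ", abbr,
              "; marked unconfirmed")
      next
    }
    snr[i] <- tryCatch(snr_peak_to_peak(tr, noise_window),
                       error = function(e) NA_real_)
    confirmed[i] <- is.finite(snr[i]) && snr[i] >= snr_min ||
      identical(snr[i], Inf)
  }
  report$sir_snr <- snr
  report$sir_confirmed <- confirmed
  report
}

#' Read SIR traces from a scan-table CSV
#'
#' Dialect: columns `mz,scan_time_s,intensity,cone_voltage`, one row per
#' time point.
#'
#' @param path CSV path.
#' @return Named list m/z -> [chronogram()].
#' @export
read_sir_table <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("mz", "scan_time_s", "intensity", "cone_voltage")
  if (!all(need %in% names(tab))) {
    stop("SIR table must have columns ", paste(need, collapse = ", "))
  }
  out <- lapply(split(tab, tab$mz), function(d) {
    d <- d[order(d$scan_time_s), ]
    chronogram(d$scan_time_s, d$intensity, mz = d$mz[1],
               cone_voltage = d$cone_voltage[1])
  })
  out
}

#' Write SIR traces to a scan-table CSV
#'
#' @param chronograms Named list m/z -> [chronogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sir_table <- function(chronograms, path) {
  rows <- do.call(rbind, lapply(chronograms, function(tr) {
    data.frame(mz = tr$mz, scan_time_s = tr$times,
               intensity = tr$intensities, cone_voltage = tr$cone_voltage)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
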