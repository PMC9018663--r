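# Voltage-resolved reference library built from acquisitions of individual
# standards. Library spectra are stored post-threshold (thresholding happens
# at build time, exactly as at query time) and quantized to the integer
# 0-999 intensity scale used by the MSP serialization, so that a library
# survives an MSP round trip bit-identically and screening scores against
# the original and the round-tripped library are equal (the cosine score is
# scale-invariant).

LIB_INTENSITY_SCALE <- 999

quantize_library_channel <- function(s) {
  p <- s$peaks
  spectrum_replace_peaks(s, p$mz, round(p$intensity / 100 * LIB_INTENSITY_SCALE))
}

#' Build one library entry from a four-channel acquisition
#'
#' Each channel is preprocessed (range-restricted, nominally binned,
#' normalized, thresholded) with the same parameters later applied to
#' queries. When several acquisitions of the same standard are supplied,
#' their binned relative-intensity channels are averaged peak-wise before
#' thresholding, which reduces acquisition-to-acquisition variance.
#'
#' @param compound A `compound_record` from the registry.
#' @param acquisition An [ms_multichannel()], or a list of them (replicates).
#' @param params [preprocess_params()] shared by the whole library.
#' @return A `library_entry`: compound plus thresholded channels on the
#'   0-999 library intensity scale.
#' @export
build_entry <- function(compound, acquisition, params = preprocess_params()) {
  is_single <- inherits(acquisition, "ms_multichannel") ||
    (is.list(acquisition) &&
       all(vapply(acquisition, inherits, logical(1), "ms_spectrum")))
  reps <- if (is_single) list(acquisition) else acquisition
  pre <- lapply(reps, function(a) {
    a <- ms_multichannel(a)  # validates channel set
    lapply(a, function(s) {
      s <- restrict_range(s, params$scan_low, params$scan_high)
      normalize_relative(bin_nominal(s))
    })
  })
  voltages <- names(pre[[1]])
  channels <- lapply(voltages, function(v) {
    merged <- average_peaklists(lapply(pre, function(a) a[[v]]$peaks))
    s <- pre[[1]][[v]]
    s <- spectrum_replace_peaks(s, merged$mz, merged$intensity)
    s <- normalize_relative(s)
    s <- apply_threshold(s, params$threshold_pct, params$inclusive)
    quantize_library_channel(s)
  })
  names(channels) <- voltages
  class(channels) <- "ms_multichannel"
  structure(list(compound = compound, channels = channels),
            class = "library_entry")
}

# peak-wise mean across replicate peak lists (absent m/z counts as 0)
average_peaklists <- function(plists) {
  if (length(plists) == 1) return(plists[[1]])
  allmz <- sort(unique(unlist(lapply(plists, `[[`, "mz"))))
  mat <- vapply(plists, function(p) {
    v <- numeric(length(allmz))
    v[match(p$mz, allmz)] <- p$intensity
    v
  }, numeric(length(allmz)))
  data.frame(mz = allmz, intensity = rowMeans(mat))
}

#' Build a reference library from standard acquisitions
#'
#' @param acquisitions Named list (abbreviation -> [ms_multichannel()] or
#'   list of replicates).
#' @param registry A `compound_registry`; every abbreviation must resolve.
#' @param params [preprocess_params()] recorded as the library's
#'   `build_params` and enforced at query time.
#' @return An `ms_library`: entries keyed by abbreviation plus build_params.
#' @export
build_library <- function(acquisitions, registry = default_registry(),
                          params = preprocess_params()) {
  if (length(acquisitions) == 0) stop("no acquisitions supplied")
  abbrs <- names(acquisitions)
  unknown <- setdiff(abbrs, names(registry))
  if (length(unknown) > 0) {
    stop("unknown compound abbreviation(s): ", paste(unknown, collapse = ", "))
  }
  entries <- lapply(abbrs, function(a) {
    build_entry(registry[[a]], acquisitions[[a]], params)
  })
  names(entries) <- abbrs
  entries <- entries[order(abbrs)]
  structure(list(entries = entries, build_params = params),
            class = "ms_library")
}

#' @export
print.ms_library <- function(x, ...) {
  cat(sprintf(
    "<ms_library> %d compounds x %d channels, threshold %g%%, m/z %g-%g\n",
    length(x$entries), length(x$entries[[1]]$channels),
    x$build_params$threshold_pct, x$build_params$scan_low,
    x$build_params$scan_high
  ))
  cat("  compounds:", paste(names(x$entries), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a library to MSP
#'
#' One entry per (compound, voltage), named `"<abbr>@<V>V"`, with Comment
#' fields carrying the compound abbreviation, the cone voltage and the
#' build parameters, so the library reconstructs losslessly from its own
#' serialization.
#'
#' @param library An `ms_library`.
#' @param path Output path, or `NULL` for the document text.
#' @param eol Line separator.
#' @return See [write_msp()].
#' @export
library_to_msp <- function(library, path = NULL, eol = "\n") {
  bp <- library$build_params
  entries <- list()
  for (abbr in names(library$entries)) {
    for (v in names(library$entries[[abbr]]$channels)) {
      s <- library$entries[[abbr]]$channels[[v]]
      entries[[length(entries) + 1]] <- msp_entry(
        name = sprintf("%s@%sV", abbr, v),
        comment_fields = c(
          Compound = abbr, ConeVoltage = paste0(v, "V"),
          ThresholdPct = format(bp$threshold_pct),
          ThresholdInclusive = if (bp$inclusive) "true" else "false",
          ScanLow = format(bp$scan_low), ScanHigh = format(bp$scan_high)
        ),
        mz = s$peaks$mz, intensity = s$peaks$intensity
      )
    }
  }
  write_msp(entries, path, eol)
}

#' Reconstruct a library from its MSP serialization
#'
#' @param path MSP file path (or document text with `text = TRUE`).
#' @param registry A `compound_registry` for compound resolution.
#' @param text Logical; treat `path` as document text.
#' @return An `ms_library`.
#' @export
library_from_msp <- function(path, registry = default_registry(),
                             text = FALSE) {
  msp <- read_msp(path, text = text)
  if (length(msp) == 0) stop("no entries in MSP source")
  first <- msp[[1]]$comment_fields
  params <- preprocess_params(
    scan_low = as.numeric(first[["ScanLow"]]),
    scan_high = as.numeric(first[["ScanHigh"]]),
    threshold_pct = as.numeric(first[["ThresholdPct"]]),
    inclusive = identical(first[["ThresholdInclusive"]], "true")
  )
  abbrs <- vapply(msp, function(e) e$comment_fields[["Compound"]], character(1))
  unknown <- setdiff(unique(abbrs), names(registry))
  if (length(unknown) > 0) {
    stop("unknown compound abbreviation(s): ", paste(unknown, collapse = ", "))
  }
  entries <- lapply(split(msp, abbrs), function(es) {
    channels <- lapply(es, function(e) {
      ms_spectrum(e$peaks$mz, e$peaks$intensity,
                  cone_voltage = entry_voltage(e),
                  scan_range = c(params$scan_low, params$scan_high))
    })
    names(channels) <- vapply(es, entry_voltage, integer(1))
    channels <- ms_multichannel(channels)
    structure(list(compound = registry[[es[[1]]$comment_fields[["Compound"]]]],
                   channels = channels),
              class = "library_entry")
  })
  entries <- entries[order(names(entries))]
  structure(list(entries = entries, build_params = params),
            class = "ms_library")
}
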