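# Seeded generator of synthetic acquisitions with the statistical structure
# the screening workflow assumes: protonated molecule as 12 V base peak,
# fragment richness growing with cone voltage, additive mixture spectra (no
# chromatographic separation), oil-matrix interference biased to low m/z,
# multiplicative lognormal intensity noise, detector saturation, and ~2 s
# Gaussian SIR chronogram peaks sampled at 10 Hz.
#
# Relative fragment abundances at each voltage are free parameters of a
# parametric decay model (no tabulated values exist to emulate); generated
# spectra are structurally, not quantitatively, faithful.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + salt) %% 2147483587 + 1)
}

#' Voltage-dependent fragmentation profiles
#'
#' One relative-intensity fingerprint per compound and cone voltage, built
#' from each registry record's annotated fragment list. At 12 V the
#' monitored precursor ion is the base peak (100) with fragments at most
#' `fragment_levels[1]` (default 7, below the visibility of all but the
#' first fragment at the 5% cut); as voltage rises the fragment envelope
#' grows (`fragment_levels` per voltage) while the precursor decays
#' (`precursor_levels`), so the count of peaks at or above 5% of the base
#' peak never decreases from 12 to 40 V. Fragments within a record decay
#' geometrically (`fragment_decay`) in their listed order, so shared
#' fragments of family members (e.g. the two estradiol esters that share
#' 279/255/159/135/109) appear with the same prominence ranking.
#'
#' @param registry A `compound_registry`.
#' @param precursor_levels Named (by voltage) precursor relative
#'   intensities, default `c(100, 100, 60, 30)` for 12/20/30/40 V.
#' @param fragment_levels Leading-fragment relative intensities per voltage,
#'   default `c(7, 35, 70, 100)`.
#' @param fragment_decay Geometric decay between successive fragments,
#'   default 0.7.
#' @return Named list: abbreviation -> list(voltage -> named numeric vector
#'   of relative intensities keyed by nominal m/z).
#' @export
default_profiles <- function(registry = default_registry(),
                             precursor_levels = c(`12` = 100, `20` = 100,
                                                  `30` = 60, `40` = 30),
                             fragment_levels = c(`12` = 7, `20` = 35,
                                                 `30` = 70, `40` = 100),
                             fragment_decay = 0.7) {
  voltages <- names(precursor_levels)
  lapply(registry, function(rec) {
    frag_mz <- vapply(rec$fragments, `[[`, integer(1), "nominal_mz")
    prof <- lapply(voltages, function(v) {
      vals <- precursor_levels[[v]]
      mzs <- rec$sir_mz
      if (length(frag_mz) > 0) {
        fr <- fragment_levels[[v]] * fragment_decay^(seq_along(frag_mz) - 1)
        keep <- frag_mz != rec$sir_mz
        vals <- c(vals, fr[keep])
        mzs <- c(mzs, frag_mz[keep])
      }
      agg <- tapply(vals, mzs, sum)
      out <- as.numeric(agg)
      names(out) <- names(agg)
      out
    })
    names(prof) <- voltages
    prof
  })
}

#' Sample definition
#'
#' @param constituents Named numeric vector, abbreviation -> concentration
#'   in mg/L (> 0); empty for a blank.
#' @param matrix `"none"` (solvent) or `"oil"`.
#' @param dilution_factor Dilution before analysis, default 100-fold.
#' @param seed Integer seed making the whole simulated acquisition
#'   reproducible.
#' @return A `sample_definition` list.
#' @export
sample_definition <- function(constituents = numeric(0),
                              matrix = c("none", "oil"),
                              dilution_factor = 100, seed = 1L) {
  matrix <- match.arg(matrix)
  if (length(constituents) > 0) {
    if (is.null(names(constituents)) || any(!nzchar(names(constituents)))) {
      stop("constituents must be named by abbreviation")
    }
    if (any(constituents <= 0)) stop("concentrations must be positive")
  }
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  structure(
    list(constituents = constituents, matrix = matrix,
         dilution_factor = as.numeric(dilution_factor),
         seed = as.integer(seed)),
    class = "sample_definition"
  )
}

#' Simulation tuning parameters
#'
#' @param base_response Detector counts per mg/L at the probe for a
#'   precursor at relative intensity 100; default 2e5, which puts a
#'   100 mg/L constituent diluted 100-fold well above the matrix background
#'   but below saturation.
#' @param noise_sdlog Multiplicative lognormal intensity noise (sdlog),
#'   default 0.1; 0 disables noise.
#' @param saturation_cap Detector ceiling in counts, default 1e6; peak
#'   intensities are clipped here, emulating the saturated scans seen with
#'   undiluted oily samples.
#' @param n_matrix_peaks,matrix_mz_range,matrix_mz_scale,matrix_intensity
#'   Oil-matrix interference: number of seeded interference ions, their m/z
#'   range, the exponential low-mass bias scale (Da), and their mean
#'   intensity (counts).
#' @param sir_duration_s,sir_rate_hz,sir_sigma_s SIR chronogram geometry:
#'   trace length, sampling rate (10 Hz default) and Gaussian peak width
#'   (sigma 0.25 s, giving the ~1.2 s span above 5% of apex, i.e. 12-13
#'   points at 10 Hz).
#' @param sir_baseline,sir_baseline_sd Additive chronogram baseline level
#'   and noise (counts).
#' @return A `sim_params` list.
#' @export
sim_params <- function(base_response = 2e5, noise_sdlog = 0.1,
                       saturation_cap = 1e6, n_matrix_peaks = 150,
                       matrix_mz_range = c(100, 600), matrix_mz_scale = 120,
                       matrix_intensity = 2000, sir_duration_s = 5,
                       sir_rate_hz = 10, sir_sigma_s = 0.25,
                       sir_baseline = 50, sir_baseline_sd = 10) {
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate one full-scan channel
#'
#' The channel spectrum is the linear combination of the constituents'
#' fragmentation profiles scaled by their at-probe concentration
#' (concentration / dilution_factor), because without chromatographic
#' separation every desorbing species contributes to the same scan. Oil
#' matrix adds dense, low-mass-biased interference ions; multiplicative
#' lognormal noise perturbs every peak; intensities are clipped at the
#' saturation cap.
#'
#' @param sample A [sample_definition()].
#' @param voltage Cone voltage (one of 12/20/30/40).
#' @param profiles From [default_profiles()].
#' @param params A [sim_params()].
#' @return An [ms_spectrum()].
#' @export
simulate_channel <- function(sample, voltage, profiles = default_profiles(),
                             params = sim_params()) {
  unknown <- setdiff(names(sample$constituents), names(profiles))
  if (length(unknown) > 0) {
    stop("no fragmentation profile for: ", paste(unknown, collapse = ", "))
  }
  with_seed(derive_seed(sample$seed, as.integer(voltage)), {
    mz <- numeric(0); intensity <- numeric(0)
    for (abbr in names(sample$constituents)) {
      prof <- profiles[[abbr]][[as.character(voltage)]]
      scale <- params$base_response *
        sample$constituents[[abbr]] / sample$dilution_factor
      mz <- c(mz, as.numeric(names(prof)))
      intensity <- c(intensity, prof / 100 * scale)
    }
    if (sample$matrix == "oil") {
      lo <- params$matrix_mz_range[1]; hi <- params$matrix_mz_range[2]
      cand <- lo:hi
      w <- exp(-(cand - lo) / params$matrix_mz_scale)
      m_mz <- sample(cand, params$n_matrix_peaks, replace = TRUE,
                     prob = w / sum(w))
      m_int <- stats::rexp(params$n_matrix_peaks,
                           rate = 1 / params$matrix_intensity)
      mz <- c(mz, m_mz); intensity <- c(intensity, m_int)
    }
    if (length(mz) > 0) {
      agg <- tapply(intensity, mz, sum)
      mz <- as.numeric(names(agg)); intensity <- as.numeric(agg)
      if (params$noise_sdlog > 0) {
        intensity <- intensity *
          stats::rlnorm(length(intensity), 0, params$noise_sdlog)
      }
      intensity <- pmin(intensity, params$saturation_cap)
    }
    ms_spectrum(mz, intensity, cone_voltage = as.integer(voltage))
  })
}

#' Simulate a single SIR chronogram
#'
#' A Gaussian desorption peak (width `sir_sigma_s`, apex at `apex_frac` of
#' the trace) on a noisy additive baseline, sampled at `sir_rate_hz`.
#' `apex_height = 0` gives a baseline-only (blank) trace.
#'
#' @param apex_height Peak height in counts above baseline.
#' @param mz Monitored nominal m/z.
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @param apex_frac Apex position as a fraction of the trace duration.
#' @return A [chronogram()].
#' @export
simulate_chronogram <- function(apex_height, mz, params = sim_params(),
                                seed = 1L, apex_frac = 0.5) {
  times <- seq(0, params$sir_duration_s, by = 1 / params$sir_rate_hz)
  with_seed(seed, {
    y <- rep(params$sir_baseline, length(times))
    if (params$sir_baseline_sd > 0) {
      y <- y + stats::rnorm(length(times), 0, params$sir_baseline_sd)
    }
    if (apex_height > 0) {
      t0 <- apex_frac * params$sir_duration_s
      y <- y + apex_height * exp(-(times - t0)^2 / (2 * params$sir_sigma_s^2))
    }
    chronogram(times, pmax(y, 0), mz = mz, cone_voltage = 12L)
  })
}

#' Simulate a complete acquisition
#'
#' Four full-scan channels (12/20/30/40 V) plus one 12 V SIR chronogram per
#' registry compound's monitored m/z. A chronogram carries a Gaussian
#' desorption peak (apex proportional to the constituent's 12 V precursor
#' response, sigma 0.25 s, 10 Hz sampling) when the corresponding compound
#' is present, and baseline noise only otherwise. Fully reproducible from
#' the sample's seed.
#'
#' @param sample A [sample_definition()].
#' @param registry A `compound_registry`.
#' @param profiles From [default_profiles()].
#' @param params A [sim_params()].
#' @return List with `channels` (an [ms_multichannel()]) and `chronograms`
#'   (named list, m/z -> [chronogram()]).
#' @export
simulate_acquisition <- function(sample, registry = default_registry(),
                                 profiles = default_profiles(registry),
                                 params = sim_params()) {
  voltages <- c(12L, 20L, 30L, 40L)
  channels <- lapply(voltages, function(v) {
    simulate_channel(sample, v, profiles, params)
  })
  names(channels) <- voltages
  sir_mzs <- sort(unique(vapply(registry, `[[`, integer(1), "sir_mz")))
  chronograms <- lapply(seq_along(sir_mzs), function(i) {
    mz <- sir_mzs[i]
    present <- names(registry)[vapply(registry, function(r) r$sir_mz == mz,
                                      logical(1))]
    apex <- 0
    for (abbr in intersect(present, names(sample$constituents))) {
      prof12 <- profiles[[abbr]][["12"]]
      apex <- apex + params$base_response *
        sample$constituents[[abbr]] / sample$dilution_factor *
        prof12[[as.character(mz)]] / 100
    }
    simulate_chronogram(apex, mz, params,
                        seed = derive_seed(sample$seed, 1000L + i))
  })
  names(chronograms) <- sir_mzs
  list(channels = ms_multichannel(channels), chronograms = chronograms)
}

#' Reference acquisitions for the 17 standards
#'
#' Noise-free, matrix-free single-standard acquisitions at a fixed
#' concentration, the synthetic stand-in for recording each standard once
#' at the four cone voltages when building the reference library.
#'
#' @param registry A `compound_registry`.
#' @param profiles From [default_profiles()].
#' @param concentration Standard concentration in mg/L, default 100.
#' @param params A [sim_params()]; noise defaults to 0 here.
#' @param seed Base seed.
#' @return Named list abbreviation -> [ms_multichannel()], ready for
#'   [build_library()].
#' @export
standard_acquisitions <- function(registry = default_registry(),
                                  profiles = default_profiles(registry),
                                  concentration = 100,
                                  params = sim_params(noise_sdlog = 0),
                                  seed = 1L) {
  out <- lapply(names(registry), function(abbr) {
    smp <- sample_definition(stats::setNames(concentration, abbr),
                             matrix = "none", dilution_factor = 100,
                             seed = derive_seed(seed, match(abbr, names(registry))))
    simulate_acquisition(smp, registry, profiles, params)$channels
  })
  names(out) <- names(registry)
  out
}

#' Generate a labelled validation set
#'
#' A reproducible panel of simulated samples — singles, cocktails and
#' optional blanks, with oil matrix on or off — each paired with its ground
#' truth, the end-to-end test bed for screening and error-rate estimation.
#'
#' @param panel Compound abbreviations to draw constituents from.
#' @param n_samples Number of non-blank samples (>= 1).
#' @param mixture_sizes Cycled over samples, default `c(1, 3)`.
#' @param concentration Per-constituent concentration in mg/L, default 100
#'   (the level at which the decision criteria were established).
#' @param matrix `"oil"` or `"none"`, default `"oil"`.
#' @param n_blanks Blank (matrix-only) samples appended, default 0.
#' @param registry,profiles,params As in [simulate_acquisition()].
#' @param seed Master seed.
#' @return List of records: `definition`, `truth` (character vector of
#'   spiked abbreviations), `channels`, `chronograms`.
#' @export
generate_validation_set <- function(panel = names(default_registry()),
                                    n_samples = 20,
                                    mixture_sizes = c(1, 3),
                                    concentration = 100,
                                    matrix = "oil", n_blanks = 0,
                                    registry = default_registry(),
                                    profiles = default_profiles(registry),
                                    params = sim_params(), seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  defs <- with_seed(derive_seed(seed, 0L), {
    lapply(seq_len(n_samples + n_blanks), function(i) {
      if (i > n_samples) {
        return(sample_definition(numeric(0), matrix = matrix,
                                 seed = derive_seed(seed, i)))
      }
      k <- mixture_sizes[(i - 1) %% length(mixture_sizes) + 1]
      who <- sample(panel, k)
      sample_definition(stats::setNames(rep(concentration, k), who),
                        matrix = matrix, seed = derive_seed(seed, i))
    })
  })
  lapply(defs, function(d) {
    acq <- simulate_acquisition(d, registry, profiles, params)
    list(definition = d, truth = names(d$constituents),
         channels = acq$channels, chronograms = acq$chronograms)
  })
}
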