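# Synthetic acquisition generator: profiles, channels, chronograms,
# validation sets.

test_that("profiles put the monitored ion as 12 V base peak", {
  prof <- default_profiles()
  reg <- default_registry()
  for (abbr in names(prof)) {
    p12 <- prof[[abbr]][["12"]]
    expect_identical(names(p12)[which.max(p12)],
                     as.character(reg[[abbr]]$sir_mz), label = abbr)
    expect_true(all(p12[names(p12) != as.character(reg[[abbr]]$sir_mz)] <= 10))
  }
  expect_true(all(c("271", "253") %in% names(prof[["Tr En"]][["40"]])))
  # shared estradiol fragments appear in both esters
  expect_true(all(c("279", "255", "159", "109") %in%
                    names(prof[["E2 V1"]][["30"]])))
  expect_true(all(c("279", "255", "159", "109") %in%
                    names(prof[["E2 DiPr"]][["30"]])))
})

test_that("fragment richness never decreases with voltage", {
  prof <- default_profiles()
  n_above <- function(p) sum(p >= 0.05 * max(p))
  for (abbr in names(prof)) {
    counts <- vapply(prof[[abbr]], n_above, numeric(1))
    expect_true(all(diff(counts) >= 0), label = abbr)
  }
})

test_that("a noiseless single-constituent channel is proportional to its profile", {
  quiet <- sim_params(noise_sdlog = 0)
  smp <- sample_definition(c("T Pr" = 100), seed = 1L)
  s <- simulate_channel(smp, 20, params = quiet)
  prof <- default_profiles()[["T Pr"]][["20"]]
  expect_setequal(s$peaks$mz, as.numeric(names(prof)))
  scale <- s$peaks$intensity / prof[as.character(s$peaks$mz)]
  expect_equal(max(scale) / min(scale), 1, tolerance = 1e-9)
})

test_that("pre-noise mixtures are exactly additive in constituents", {
  quiet <- sim_params(noise_sdlog = 0)
  a <- simulate_channel(sample_definition(c("T Pr" = 100), seed = 4L), 30,
                        params = quiet)
  b <- simulate_channel(sample_definition(c("B Un" = 100), seed = 4L), 30,
                        params = quiet)
  ab <- simulate_channel(sample_definition(c("T Pr" = 100, "B Un" = 100),
                                           seed = 4L), 30, params = quiet)
  expect_setequal(ab$peaks$mz, union(a$peaks$mz, b$peaks$mz))
  for (mz in ab$peaks$mz) {
    expect_equal(
      ab$peaks$intensity[ab$peaks$mz == mz],
      sum(a$peaks$intensity[a$peaks$mz == mz],
          b$peaks$intensity[b$peaks$mz == mz]),
      label = mz
    )
  }
})

test_that("intensities clip exactly at the saturation cap", {
  capped <- sim_params(noise_sdlog = 0, saturation_cap = 1e5)
  smp <- sample_definition(c("T Pr" = 1000), dilution_factor = 1, seed = 1L)
  s <- simulate_channel(smp, 12, params = capped)
  expect_equal(max(s$peaks$intensity), 1e5)
})

test_that("unknown constituents are rejected", {
  expect_error(simulate_channel(sample_definition(c(Nope = 10), seed = 1L),
                                12), "Nope")
})

test_that("acquisitions are reproducible from the sample seed", {
  smp <- sample_definition(c("E2 Bz" = 100), matrix = "oil", seed = 55L)
  a1 <- simulate_acquisition(smp)
  a2 <- simulate_acquisition(smp)
  for (v in names(a1$channels)) {
    expect_identical(a1$channels[[v]]$peaks, a2$channels[[v]]$peaks)
  }
  for (mz in names(a1$chronograms)) {
    expect_identical(a1$chronograms[[mz]]$intensities,
                     a2$chronograms[[mz]]$intensities)
  }
})

test_that("blank chronograms hold baseline only", {
  blank <- sample_definition(numeric(0), matrix = "oil", seed = 21L)
  acq <- simulate_acquisition(blank)
  for (tr in acq$chronograms) {
    expect_lt(max(tr$intensities), 200)
    expect_lt(snr_peak_to_peak(tr), 3)
  }
})

test_that("oil matrix adds low-mass-biased interference", {
  quiet <- sim_params(noise_sdlog = 0)
  blank <- sample_definition(numeric(0), matrix = "oil", seed = 9L)
  s <- simulate_channel(blank, 12, params = quiet)
  expect_gt(nrow(s$peaks), 50)
  expect_gt(mean(s$peaks$mz < 300), 0.5)
})

test_that("a present compound's chronogram has ~12 points per peak at 10 Hz", {
  smp <- sample_definition(c("T Dc" = 100), seed = 14L)
  acq <- simulate_acquisition(smp)
  pm <- integrate_peak(acq$chronograms[["443"]])
  expect_true(pm$n_points %in% 11:14)
  expect_gt(snr_peak_to_peak(acq$chronograms[["443"]]), 100)
})

test_that("validation sets are labelled, sized and reproducible", {
  expect_error(generate_validation_set(n_samples = 0), "n_samples")
  set <- generate_validation_set(n_samples = 10, mixture_sizes = 1,
                                 n_blanks = 2, seed = 3L)
  expect_length(set, 12)
  for (i in 1:10) expect_length(set[[i]]$truth, 1)
  for (i in 11:12) expect_length(set[[i]]$truth, 0)
  set2 <- generate_validation_set(n_samples = 10, mixture_sizes = 1,
                                  n_blanks = 2, seed = 3L)
  expect_identical(lapply(set, `[[`, "truth"), lapply(set2, `[[`, "truth"))
  expect_identical(set[[1]]$channels[["12"]]$peaks,
                   set2[[1]]$channels[["12"]]$peaks)
})
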