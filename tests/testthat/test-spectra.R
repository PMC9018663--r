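# Spectrum model and the preprocessing chain.

test_that("normalization scales the base peak to 100 and preserves ratios", {
  s <- normalize_relative(ms_spectrum(c(331, 271), c(2000, 500)))
  expect_equal(s$peaks$intensity[s$peaks$mz == 331], 100)
  expect_equal(s$peaks$intensity[s$peaks$mz == 271], 25)
  one <- normalize_relative(ms_spectrum(400, 7))
  expect_equal(one$peaks$intensity, 100)
  s2 <- normalize_relative(ms_spectrum(c(100, 200), c(1, 3)))
  expect_equal(s2$peaks$intensity, c(33.3333, 100), tolerance = 1e-6)
  expect_error(normalize_relative(ms_spectrum(numeric(0), numeric(0))),
               "empty")
  expect_error(normalize_relative(ms_spectrum(100, 0)), "all-zero")
})

test_that("thresholding keeps the boundary peak under inclusive semantics", {
  s <- ms_spectrum(c(109, 271, 331), c(4.99, 5.0, 100))
  kept <- apply_threshold(s, 5)
  expect_identical(kept$peaks$mz, c(271, 331))
  strict <- apply_threshold(s, 5, inclusive = FALSE)
  expect_identical(strict$peaks$mz, 331)
  expect_identical(apply_threshold(kept, 5)$peaks, kept$peaks)
  expect_error(apply_threshold(s, 0), "threshold")
  expect_error(apply_threshold(s, 101), "threshold")
})

test_that("nominal binning sums same-bin centroids and rounds half to even", {
  s <- bin_nominal(ms_spectrum(c(331.2, 331.4), c(60, 40)))
  expect_equal(s$peaks$mz, 331)
  expect_equal(s$peaks$intensity, 100)
  expect_equal(bin_nominal(ms_spectrum(270.5, 10))$peaks$mz, 270)
  expect_equal(bin_nominal(ms_spectrum(271.5, 10))$peaks$mz, 272)
  ints <- ms_spectrum(c(100, 200, 300), c(1, 2, 3))
  expect_equal(bin_nominal(ints)$peaks, ints$peaks)
})

test_that("binning conserves total intensity", {
  set.seed(11)
  for (i in 1:20) {
    s <- ms_spectrum(runif(30, 50, 600), runif(30, 0, 1e5))
    expect_equal(sum(bin_nominal(s)$peaks$intensity),
                 sum(s$peaks$intensity))
  }
})

test_that("range restriction is boundary-inclusive", {
  s <- ms_spectrum(c(45, 49, 50, 300, 600, 601), c(10, 10, 10, 50, 10, 5))
  r <- restrict_range(s)
  expect_identical(r$peaks$mz, c(50, 300, 600))
  expect_identical(restrict_range(ms_spectrum(c(45, 300, 601),
                                              c(10, 50, 5)))$peaks$mz, 300)
})

test_that("preprocess composes the four stages in order", {
  s <- ms_spectrum(c(331.1, 331.3, 49.0), c(900, 100, 50))
  out <- preprocess(s)
  expect_equal(out$peaks$mz, 331)
  expect_equal(out$peaks$intensity, 100)
  # threshold applies to binned relative intensities
  s2 <- ms_spectrum(c(331.2, 331.4, 271.1), c(30, 70, 4.9))
  out2 <- preprocess(s2)
  expect_identical(out2$peaks$mz, 331)
})

test_that("preprocess is idempotent and never removes the base peak", {
  set.seed(23)
  for (i in 1:25) {
    s <- random_spectrum(n = sample(3:40, 1))
    p1 <- preprocess(s)
    p2 <- preprocess(p1)
    expect_equal(p1$peaks, p2$peaks)
    expect_lte(nrow(p1$peaks), nrow(s$peaks))
    base <- p1$peaks$mz[which.max(p1$peaks$intensity)]
    binned <- bin_nominal(restrict_range(s))
    expect_identical(base,
                     binned$peaks$mz[which.max(binned$peaks$intensity)])
    expect_equal(max(p1$peaks$intensity), 100)
  }
})

test_that("a spectrum left empty by preprocessing is rejected", {
  expect_error(preprocess(ms_spectrum(20, 100)), "empty|all-zero")
})

test_that("multichannel acquisitions validate the channel set", {
  mk <- function() ms_spectrum(c(345, 271), c(100, 10))
  chans <- list(`12` = mk(), `20` = mk(), `30` = mk(), `40` = mk())
  x <- ms_multichannel(chans)
  expect_identical(names(x), c("12", "20", "30", "40"))
  expect_error(ms_multichannel(chans[c("12", "20", "40")]),
               "missing channel 30 V")
  expect_error(ms_multichannel(c(chans, list(`50` = mk()))), "unexpected")
})

test_that("scan-table CSV round-trips an acquisition", {
  smp <- sample_definition(c("T Pr" = 100), seed = 3L)
  acq <- simulate_acquisition(smp)$channels
  path <- withr::local_tempfile(fileext = ".csv")
  write_scan_table(acq, path)
  back <- read_scan_table(path)
  for (v in names(acq)) {
    expect_equal(back[[v]]$peaks, acq[[v]]$peaks, tolerance = 1e-8)
  }
  expect_error(read_scan_table(withr::local_tempfile(lines = "a,b\n1,2")),
               "columns")
})
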