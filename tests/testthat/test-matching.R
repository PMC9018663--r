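# Channel scores, fusion, hit criteria, screening.

test_that("channel score fixtures hold in both support modes", {
  a <- ms_spectrum(c(345, 271, 109), c(100, 40, 10))
  b <- ms_spectrum(c(400, 500), c(100, 50))
  for (mode in c("reference", "union")) {
    expect_identical(channel_score(a, a, mode = mode), 1000L)
    expect_identical(channel_score(a, b, mode = mode), 0L)
  }
  # scale invariance: library 0-999 vs relative 0-100
  a999 <- ms_spectrum(a$peaks$mz, a$peaks$intensity * 9.99)
  expect_identical(channel_score(a, a999), 1000L)
  expect_error(channel_score(ms_spectrum(numeric(0), numeric(0)), a),
               "empty")
})

test_that("the hand-computed partial-overlap score matches the oracle", {
  q <- ms_spectrum(331, 100)
  r <- ms_spectrum(c(331, 271), c(100, 100))
  for (mode in c("reference", "union")) {
    expect_identical(channel_score(q, r, mode = mode), 707L)
    expect_equal(oracle_cosine_score(331, 100, c(331, 271), c(100, 100),
                                     support = mode), 707)
  }
})

test_that("scores agree with the brute-force oracle on random spectra", {
  set.seed(41)
  for (i in 1:30) {
    q <- random_spectrum(sample(2:15, 1), c(50, 120))
    r <- random_spectrum(sample(2:15, 1), c(50, 120))
    for (mode in c("reference", "union")) {
      expect_identical(
        as.numeric(channel_score(q, r, mode = mode)),
        oracle_cosine_score(q$peaks$mz, q$peaks$intensity,
                            r$peaks$mz, r$peaks$intensity, support = mode),
        label = sprintf("iter %d mode %s", i, mode)
      )
    }
  }
})

test_that("the union-support score is symmetric and bounded", {
  set.seed(17)
  for (i in 1:25) {
    a <- random_spectrum(sample(2:20, 1), c(50, 150))
    b <- random_spectrum(sample(2:20, 1), c(50, 150))
    sab <- channel_score(a, b, mode = "union")
    expect_identical(sab, channel_score(b, a, mode = "union"))
    expect_gte(sab, 0L); expect_lte(sab, 1000L)
  }
})

test_that("score fusion is a weighted arithmetic mean", {
  expect_equal(fuse_scores(c(900, 900, 900, 900)), 900)
  expect_equal(fuse_scores(c(850, 825, 825, 825)), 831.25)
  expect_equal(fuse_scores(c(700, 0, 0, 0), c(1, 0, 0, 0)), 700)
  expect_error(fuse_scores(c(900, 900), rep(0.25, 4)), "one weight")
  expect_error(fuse_scores(c(900, 900), c(0.3, 0.3)), "sum to 1")
})

test_that("hit criteria are conjunctive with inclusive boundaries", {
  expect_true(apply_criteria(c(850, 825, 825, 825)))   # avg 831.25
  expect_false(apply_criteria(c(900, 800, 900, 900)))  # channel 2 low
  expect_false(apply_criteria(c(840, 900, 900, 900)))  # channel 1 low
  expect_false(apply_criteria(c(850, 825, 825, 825), average_score = 799))
  loose <- match_criteria(channel1_min = 0, other_channels_min = 0,
                          average_min = 800)
  expect_true(apply_criteria(c(700, 850, 850, 850), criteria = loose))
})

test_that("screening a library entry against itself scores 1000 everywhere", {
  lib <- default_test_library()
  entry <- lib$entries[["T Pr"]]
  rep <- screen(entry$channels, lib)
  top <- rep[1, ]
  expect_identical(top$compound, "T Pr")
  expect_identical(c(top$score_12v, top$score_20v, top$score_30v,
                     top$score_40v), rep(1000L, 4))
  expect_equal(top$average_score, 1000)
  expect_true(top$hit)
})

test_that("a pure synthetic standard ranks first against the full library", {
  lib <- default_test_library()
  smp <- sample_definition(c("T Pr" = 100), matrix = "none", seed = 5L)
  rep <- screen(simulate_acquisition(smp)$channels, lib)
  expect_identical(rep$compound[1], "T Pr")
  expect_true(rep$hit[1])
})

test_that("screening rejects an empty library and sorts deterministically", {
  expect_error(screen(default_test_library()$entries[["Tr"]]$channels,
                      list(entries = list(), build_params = preprocess_params())),
               "empty library")
  lib <- default_test_library()
  rep <- screen(lib$entries[["E2 V1"]]$channels, lib)
  expect_identical(order(-rep$average_score, rep$compound),
                   seq_len(nrow(rep)))
})

test_that("mixture spectra never outscore the pure compound", {
  lib <- default_test_library()
  quiet <- sim_params(noise_sdlog = 0)
  pure <- simulate_acquisition(
    sample_definition(c("T En" = 100), seed = 8L), params = quiet)$channels
  mix <- simulate_acquisition(
    sample_definition(c("T En" = 100, "B Un" = 100, "Tr Ac" = 100),
                      seed = 8L), params = quiet)$channels
  for (mode in c("reference", "union")) {
    s_pure <- screen(pure, lib, mode = mode)
    s_mix <- screen(mix, lib, mode = mode)
    expect_lte(s_mix$average_score[s_mix$compound == "T En"],
               s_pure$average_score[s_pure$compound == "T En"])
  }
  # the union-support identity search degrades strictly on mixtures
  s_mix_u <- screen(mix, lib, mode = "union")
  expect_lt(s_mix_u$average_score[s_mix_u$compound == "T En"], 700)
})

test_that("estradiol esters are mutually confusable at high voltage", {
  lib <- default_test_library()
  query <- simulate_acquisition(
    sample_definition(c("E2 V1" = 100), seed = 13L))$channels
  rep <- screen(query, lib)
  for (col in c("score_30v", "score_40v")) {
    expect_gt(rep[[col]][rep$compound == "E2 DiPr"],
              rep[[col]][rep$compound == "T Dc"])
  }
})
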