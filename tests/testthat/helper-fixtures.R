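# Shared fixtures, built in code. The default synthetic library is cached
# per test run because several files screen against it.

.fixture_env <- new.env(parent = emptyenv())

default_test_library <- function() {
  if (is.null(.fixture_env$lib)) {
    reg <- default_registry()
    acq <- standard_acquisitions(reg, seed = 7L)
    .fixture_env$lib <- build_library(acq, reg)
  }
  .fixture_env$lib
}

# The monitored m/z list, in panel order (the published acquisition list).
SIR_CAPTION <- c(
  "T Ac" = 331, "T Pr" = 345, "T Iso" = 289, "T En" = 401, "T Dc" = 443,
  "T Bz" = 393, "T PhPr" = 421, "T Cy" = 413, "N PhPr" = 407, "B Un" = 453,
  "E2 DiPr" = 385, "E2 V1" = 357, "E2 Bz" = 377, "Tr" = 271, "Tr Ac" = 313,
  "Tr En" = 383, "D En" = 417
)

# Independent brute-force oracle for the cosine score: explicit loops over
# an integer bin grid, no shared code with channel_score(). Reference
# support applies the interference cap: scaled at the reference base bin
# (highest m/z on ties), bins whose query intensity grossly exceeds the
# scaled fingerprint (> 3x) are truncated to the fingerprint proportion.
oracle_cosine_score <- function(q_mz, q_int, r_mz, r_int,
                                support = c("reference", "union")) {
  support <- match.arg(support)
  bins <- if (support == "reference") sort(unique(r_mz))
          else sort(unique(c(q_mz, r_mz)))
  qv <- rv <- numeric(length(bins))
  for (i in seq_along(bins)) {
    qv[i] <- sum(q_int[q_mz == bins[i]])
    rv[i] <- sum(r_int[r_mz == bins[i]])
  }
  if (support == "reference") {
    anchor <- max(bins[rv == max(rv)])
    s <- qv[bins == anchor] / rv[bins == anchor]
    for (i in seq_along(bins)) {
      if (qv[i] > 3 * rv[i] * s) qv[i] <- rv[i] * s
    }
  }
  num <- 0; qq <- 0; rr <- 0
  for (i in seq_along(bins)) {
    num <- num + sqrt(qv[i]) * sqrt(rv[i])
    qq <- qq + qv[i]
    rr <- rr + rv[i]
  }
  if (qq == 0 || rr == 0) return(0)
  floor(1000 * num / sqrt(qq * rr) + 0.5)
}

params_equal_for_test <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b)))
}

unclass_for_test <- function(x) {
  if (is.list(x)) x <- lapply(x, unclass_for_test)
  attr(x, "class") <- NULL
  x
}

random_spectrum <- function(n = 10, mz_range = c(50, 600)) {
  ms_spectrum(sample(seq(mz_range[1], mz_range[2]), n),
              stats::runif(n, 1, 1000))
}
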