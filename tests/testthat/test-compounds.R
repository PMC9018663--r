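# Formula arithmetic and the steroid-ester registry.

test_that("nominal mass reproduces the printed fragment-ion assignments", {
  # every printed formula/m-z pair in the fragment annotations
  fixtures <- list(
    list("C19H27O", 271), list("C7H9O", 109), list("C7H5O", 105),
    list("C19H25O", 269), list("C10H15", 135), list("C8H9O", 121),
    list("C18H23O", 255), list("C18H23O2", 271), list("C18H21O", 253)
  )
  for (fx in fixtures) {
    expect_identical(nominal_mass(fx[[1]]), as.integer(fx[[2]]),
                     label = fx[[1]])
  }
  expect_identical(nominal_mass("H"), 1L)
})

test_that("protonated nominal m/z matches the published panel values", {
  expect_identical(protonated_nominal_mz("C29H46O3"), 443L)  # T Dc
  expect_identical(protonated_nominal_mz("C26H40O3"), 401L)  # T En
  expect_identical(protonated_nominal_mz("C30H44O3"), 453L)  # B Un
  expect_identical(protonated_nominal_mz("C24H32O4"), 385L)  # E2 DiPr
  expect_identical(protonated_nominal_mz("C18H22O2"), 271L)  # Tr
})

test_that("monoisotopic masses agree with tabulated sums", {
  expect_equal(monoisotopic_mass("C"), 12.0, tolerance = 1e-9)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-5)
  expect_equal(monoisotopic_mass("C19H27O"), 271.2056, tolerance = 1e-3)
})

test_that("monoisotopic mass stays in the sanity band around nominal", {
  for (rec in default_registry()) {
    f <- rec$formula
    nom <- nominal_mass(f)
    mono <- monoisotopic_mass(f)
    expect_gte(mono, nom - 0.5 * sum(f))
    expect_lt(abs(mono - nom) / nom, 0.002)
  }
})

test_that("unknown element symbols are rejected by name", {
  expect_error(nominal_mass("C2Xx3"), "Xx")
  expect_error(chem_formula("Zr2O"), "Zr")
})

test_that("formula parsing handles brackets, charges and repeated elements", {
  expect_identical(nominal_mass("[C19H27O]+"), 271L)
  expect_identical(nominal_mass("CH3CH2OH"), nominal_mass("C2H6O"))
  expect_error(chem_formula(""), "empty")
})

test_that("registry has 17 records with consistent printed ion values", {
  reg <- default_registry()
  expect_length(reg, 17)
  expect_false(anyDuplicated(names(reg)) > 0)
  for (rec in reg) {
    expect_identical(rec$protonated_mz, nominal_mass(rec$formula) + 1L)
    if (!rec$sir_discrepancy) {
      expect_identical(rec$sir_mz, rec$protonated_mz,
                       label = rec$abbreviation)
    }
    for (fr in rec$fragments) {
      if (!is.null(fr$formula)) {
        expect_identical(nominal_mass(fr$formula), fr$nominal_mz,
                         label = sprintf("%s fragment %d", rec$abbreviation,
                                         fr$nominal_mz))
      }
    }
  }
  expect_identical(reg[["Tr"]]$protonated_mz, 271L)
  expect_identical(reg[["Tr Ac"]]$protonated_mz, 313L)
})

test_that("the monitored m/z for testosterone isocaproate is flagged, not fixed", {
  rec <- default_registry()[["T Iso"]]
  expect_identical(rec$sir_mz, 289L)
  expect_identical(rec$protonated_mz, 387L)
  expect_true(rec$sir_discrepancy)
})

test_that("family fragment sets follow the assignment scheme", {
  reg <- default_registry()
  frag_mzs <- function(a) vapply(reg[[a]]$fragments, `[[`, integer(1),
                                 "nominal_mz")
  for (a in c("T Ac", "T Pr", "T Iso", "T En", "T Dc", "T Bz", "T PhPr",
              "T Cy")) {
    expect_true(all(c(271, 109, 105) %in% frag_mzs(a)), label = a)
  }
  expect_true(all(c(269, 135, 121) %in% frag_mzs("B Un")))
  for (a in c("E2 DiPr", "E2 V1", "E2 Bz")) {
    expect_true(all(c(255, 105) %in% frag_mzs(a)), label = a)
  }
  for (a in c("E2 DiPr", "E2 V1")) {
    expect_true(all(c(279, 159, 135, 109) %in% frag_mzs(a)), label = a)
  }
  for (a in c("Tr Ac", "Tr En")) {
    expect_true(all(c(271, 253, 279) %in% frag_mzs(a)), label = a)
  }
  # the unassigned ions carry no formula
  e279 <- Filter(function(f) f$nominal_mz == 279L,
                 reg[["E2 V1"]]$fragments)[[1]]
  expect_null(e279$formula)
})

test_that("registry exports as a tab-separated table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- registry_table(file = path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_identical(nrow(back), 17L)
  expect_identical(back$abbreviation, tab$abbreviation)
  expect_identical(back$sir_mz, tab$sir_mz)
})
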