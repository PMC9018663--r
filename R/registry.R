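# Built-in registry of the 17 anabolic steroid esters the screening method
# targets, with neutral formulas, protonated-molecule m/z, the m/z actually
# monitored in SIR mode, and annotated in-source fragment ions.

fragment_ion <- function(nominal_mz, formula = NULL, annotation = "") {
  if (!is.null(formula)) {
    f <- chem_formula(formula)
    if (nominal_mass(f) != nominal_mz) {
      stop(sprintf(
        "fragment formula %s has nominal mass %d, not %d",
        format_formula(f), nominal_mass(f), nominal_mz
      ))
    }
    formula <- f
  }
  structure(
    list(nominal_mz = as.integer(nominal_mz), formula = formula,
         annotation = annotation),
    class = "fragment_ion"
  )
}

compound_record <- function(name, abbreviation, formula, sir_mz = NULL,
                            fragments = list(), sir_discrepancy = FALSE) {
  formula <- chem_formula(formula)
  pmz <- nominal_mass(formula) + 1L
  if (is.null(sir_mz)) sir_mz <- pmz
  structure(
    list(
      name = name,
      abbreviation = abbreviation,
      formula = formula,
      protonated_mz = pmz,
      sir_mz = as.integer(sir_mz),
      fragments = fragments,
      sir_discrepancy = isTRUE(sir_discrepancy)
    ),
    class = "compound_record"
  )
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf(
    "%s (%s) %s  [M+H]+ %d  SIR %d%s  fragments: %s\n",
    x$abbreviation, x$name, format_formula(x$formula),
    x$protonated_mz, x$sir_mz,
    if (x$sir_discrepancy) " (monitored m/z differs from [M+H]+; flagged)" else "",
    paste(vapply(x$fragments, `[[`, integer(1), "nominal_mz"), collapse = ", ")
  ))
  invisible(x)
}

# Shared fragment-ion constructors. Ester cleavage of the protonated molecule
# regenerates the protonated free steroid minus water for 17-hydroxyl esters.
.frag <- local({
  list(
    t271  = function() fragment_ion(271, "C19H27O", "ester cleavage of [M+H]+"),
    t109  = function() fragment_ion(109, "C7H9O", "B-ring cleavage"),
    t105  = function() fragment_ion(105, "C7H5O", "B-ring cleavage"),
    n257  = function() fragment_ion(257, "C18H25O",
                                    "ester cleavage of [M+H]+ (inferred)"),
    b269  = function() fragment_ion(269, "C19H25O", "ester cleavage of [M+H]+"),
    b135  = function() fragment_ion(135, "C10H15", "B-ring fission"),
    b121  = function() fragment_ion(121, "C8H9O", "B-ring fission"),
    e255  = function() fragment_ion(255, "C18H23O", "loss of R-COOH"),
    e105  = function() fragment_ion(105, "C7H5O", "phenylcarbonyl"),
    e279  = function() fragment_ion(279, NULL,
                                    "ring cleavage, pathway unassigned"),
    e159  = function() fragment_ion(159, NULL, "assignment unclear"),
    tr271 = function() fragment_ion(271, "C18H23O2", "ester cleavage of [M+H]+"),
    tr253 = function() fragment_ion(253, "C18H21O", "water loss from m/z 271"),
    tr279 = function() fragment_ion(279, NULL,
                                    "ring cleavage, pathway unassigned"),
    d287  = function() fragment_ion(287, "C20H31O",
                                    "ester cleavage of [M+H]+ (inferred)")
  )
})

testo_frags <- function() list(.frag$t271(), .frag$t109(), .frag$t105())

#' Registry of the 17 target steroid esters
#'
#' The built-in panel: names, abbreviations, neutral elemental formulas,
#' nominal protonated-molecule m/z, the m/z monitored in SIR confirmation,
#' and annotated in-source fragment ions. Every testosterone ester shares the
#' ester-cleavage ion m/z 271 and the B-ring ions 109/105; boldenone
#' undecylenate fragments to 269/135/121; estradiol esters lose the acyl acid
#' to m/z 255 with the phenylcarbonyl 105; estradiol valerate and dipropionate
#' additionally share 279/159/135/109 (the source of their mutual
#' confusability at 30-40 V); trenbolone esters give 271/253/279.
#'
#' One monitored m/z is deliberately inconsistent: the testosterone
#' isocaproate trace is listed at m/z 289 (protonated testosterone, the free
#' steroid) rather than its ester \[M+H\]+ 387. The registry stores both
#' values and flags the record (`sir_discrepancy = TRUE`) rather than
#' silently correcting either.
#'
#' @return A `compound_registry`: a named list of 17 `compound_record`
#'   objects keyed by abbreviation.
#' @examples
#' reg <- default_registry()
#' length(reg)
#' reg[["T Dc"]]$protonated_mz
#' @export
default_registry <- function() {
  records <- list(
    compound_record("testosterone acetate", "T Ac", "C21H30O3",
                    fragments = testo_frags()),
    compound_record("testosterone propionate", "T Pr", "C22H32O3",
                    fragments = testo_frags()),
    compound_record("testosterone isocaproate", "T Iso", "C25H38O3",
                    sir_mz = 289, sir_discrepancy = TRUE,
                    fragments = testo_frags()),
    compound_record("testosterone enanthate", "T En", "C26H40O3",
                    fragments = testo_frags()),
    compound_record("testosterone decanoate", "T Dc", "C29H46O3",
                    fragments = testo_frags()),
    compound_record("testosterone benzoate", "T Bz", "C26H32O3",
                    fragments = testo_frags()),
    compound_record("testosterone phenylpropionate", "T PhPr", "C28H36O3",
                    fragments = testo_frags()),
    compound_record("testosterone cypionate", "T Cy", "C27H40O3",
                    fragments = testo_frags()),
    compound_record("nortestosterone phenylpropionate", "N PhPr", "C27H34O3",
                    fragments = list(.frag$n257(), .frag$t109(), .frag$t105())),
    compound_record("boldenone undecylenate", "B Un", "C30H44O3",
                    fragments = list(.frag$b269(), .frag$b135(), .frag$b121())),
    compound_record("estradiol dipropionate", "E2 DiPr", "C24H32O4",
                    fragments = list(.frag$e255(), .frag$e105(), .frag$e279(),
                                     .frag$e159(), .frag$b135(), .frag$t109())),
    compound_record("estradiol valerate", "E2 V1", "C23H32O3",
                    fragments = list(.frag$e255(), .frag$e105(), .frag$e279(),
                                     .frag$e159(), .frag$b135(), .frag$t109())),
    compound_record("estradiol benzoate", "E2 Bz", "C25H28O3",
                    fragments = list(.frag$e255(), .frag$e105(), .frag$b135())),
    compound_record("trenbolone", "Tr", "C18H22O2",
                    fragments = list(.frag$tr253())),
    compound_record("trenbolone acetate", "Tr Ac", "C20H24O3",
                    fragments = list(.frag$tr271(), .frag$tr253(), .frag$tr279())),
    compound_record("trenbolone enanthate", "Tr En", "C25H34O3",
                    fragments = list(.frag$tr271(), .frag$tr253(), .frag$tr279())),
    compound_record("drostanolone enanthate", "D En", "C27H44O3",
                    fragments = list(.frag$d287()))
  )
  abbrs <- vapply(records, `[[`, character(1), "abbreviation")
  if (anyDuplicated(abbrs)) stop("duplicate abbreviations in registry")
  names(records) <- abbrs
  structure(records, class = "compound_registry")
}

#' @export
print.compound_registry <- function(x, ...) {
  cat(sprintf("Steroid ester registry: %d compounds\n", length(x)))
  for (rec in x) print(rec)
  invisible(x)
}

#' Registry as a data frame / tab-separated table
#'
#' @param registry A `compound_registry`, by default [default_registry()].
#' @param file Optional path; when given, the table is written as TSV.
#' @return A data frame with columns abbreviation, name, formula (Hill
#'   order), protonated_mz, sir_mz, sir_discrepancy and a semicolon-joined
#'   fragment list (invisibly, when writing).
#' @export
registry_table <- function(registry = default_registry(), file = NULL) {
  tab <- data.frame(
    abbreviation = vapply(registry, `[[`, character(1), "abbreviation"),
    name = vapply(registry, `[[`, character(1), "name"),
    formula = vapply(registry, function(r) format_formula(r$formula),
                     character(1)),
    protonated_mz = vapply(registry, `[[`, integer(1), "protonated_mz"),
    sir_mz = vapply(registry, `[[`, integer(1), "sir_mz"),
    sir_discrepancy = vapply(registry, `[[`, logical(1), "sir_discrepancy"),
    fragments = vapply(registry, function(r) {
      paste(vapply(r$fragments, `[[`, integer(1), "nominal_mz"),
            collapse = ";")
    }, character(1)),
    row.names = NULL
  )
  if (!is.null(file)) {
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
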