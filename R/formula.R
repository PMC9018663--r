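# Elemental-formula arithmetic at the two mass scales a single-quadrupole
# screening method needs: integer nominal masses (unit resolution) and
# monoisotopic masses (for future high-resolution adapters).

# Integer mass numbers of the most abundant isotope.
.NOMINAL_MASS <- c(C = 12L, H = 1L, N = 14L, O = 16L, S = 32L)

# IUPAC monoisotopic masses, >= 6 decimals.
.MONO_MASS <- c(
  C = 12.000000,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

#' Elemental formula
#'
#' A molecular or ionic formula restricted to the elements needed for steroid
#' esters and their fragments (C, H, N, O, S). Counts are non-negative
#' integers; the charge (default +1, the cation regime of positive-ion ASAP)
#' carries no mass consequence at nominal resolution.
#'
#' @param x A formula string such as `"C19H28O2"` (Hill-style element/count
#'   tokens; brackets and a trailing `+` are tolerated, e.g. `"[C19H27O]+"`),
#'   or a named numeric vector of element counts.
#' @param charge Integer charge state; defaults to +1.
#' @return An object of class `chem_formula`: a named integer vector of
#'   element counts with a `charge` attribute.
#' @examples
#' chem_formula("C19H28O2")
#' nominal_mass(chem_formula("[C19H27O]+"))
#' @export
chem_formula <- function(x, charge = 1L) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) {
    counts <- parse_formula_string(x)
  } else if (is.numeric(x) && !is.null(names(x))) {
    counts <- as.integer(x)
    names(counts) <- names(x)
  } else {
    stop("formula must be a string or a named count vector")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("element counts must be non-negative integers")
  }
  unknown <- setdiff(names(counts), names(.NOMINAL_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("formula must contain at least one atom")
  structure(counts, charge = as.integer(charge), class = "chem_formula")
}

# "C19H27O" / "[C19H27O]+" -> named integer vector of counts
parse_formula_string <- function(s) {
  s <- gsub("[][+]|\\s", "", s)
  if (!nzchar(s)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(s)) {
    stop("cannot parse formula string: ", s)
  }
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
  tapply(counts, syms, sum)[unique(syms)]
}

#' @export
print.chem_formula <- function(x, ...) {
  cat(format_formula(x), "charge", format(attr(x, "charge"), ...), "\n")
  invisible(x)
}

#' Format a formula in Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetical.
#'
#' @param formula A [chem_formula()] (or string coercible to one).
#' @return A single string, e.g. `"C26H40O3"`.
#' @export
format_formula <- function(formula) {
  f <- chem_formula(formula)
  syms <- names(f)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(ord, ifelse(f[ord] > 1, f[ord], ""), collapse = "")
}

#' Nominal (integer) mass of a formula
#'
#' Sum of element counts times the integer mass number of each element's most
#' abundant isotope (C = 12, H = 1, N = 14, O = 16, S = 32). At unit
#' resolution the cation charge contributes no mass change, so the same value
#' serves for neutral molecules and their even-electron cations.
#'
#' @param formula A [chem_formula()] or formula string.
#' @return Integer mass in Da.
#' @examples
#' nominal_mass("C19H27O")  # 271, the testosterone-ester cleavage ion
#' @export
nominal_mass <- function(formula) {
  f <- chem_formula(formula)
  as.integer(sum(as.integer(f) * .NOMINAL_MASS[names(f)]))
}

#' Monoisotopic mass of a formula
#'
#' Sum of IUPAC monoisotopic masses (C 12 exactly, H 1.007825, N 14.003074,
#' O 15.994915, S 31.972071). No electron-mass correction is applied; at the
#' sub-millidalton level that correction (0.00055 Da per charge) is smaller
#' than the tolerance any nominal-resolution consumer of this value needs.
#'
#' @param formula A [chem_formula()] or formula string.
#' @return Mass in Da (double).
#' @examples
#' monoisotopic_mass("H2O")  # 18.010565
#' @export
monoisotopic_mass <- function(formula) {
  f <- chem_formula(formula)
  sum(as.integer(f) * .MONO_MASS[names(f)])
}

#' Nominal m/z of the protonated molecule
#'
#' Under the open ASAP source all compounds studied here ionize as
#' \[M+H\]\eqn{^+}; at nominal resolution that is simply the neutral nominal
#' mass plus 1.
#'
#' @param formula Neutral-molecule formula ([chem_formula()] or string), or a
#'   `compound_record` whose formula is used.
#' @return Integer m/z in Da.
#' @examples
#' protonated_nominal_mz("C29H46O3")  # 443, testosterone decanoate
#' @export
protonated_nominal_mz <- function(formula) {
  if (inherits(formula, "compound_record")) formula <- formula$formula
  nominal_mass(formula) + 1L
}
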