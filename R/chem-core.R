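#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom rlang .data %||% abort
#' @importFrom stats setNames runif
#' @importFrom utils head tail
## usethis namespace: end
NULL

# Monoisotopic atomic masses (Da), IUPAC/CODATA values. These constants are
# the single source for every precursor and fragment m/z the package emits.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668
)

# Electron rest mass in Da. Included exactly once per charge in every ion
# m/z: without it head-group and adduct masses are wrong at the 4th decimal.
.ELECTRON_MASS <- 0.00054857990946

.PROTON_MASS <- .ATOMIC_MASS[["H"]] - .ELECTRON_MASS

#' Monoisotopic atomic masses used by the package
#'
#' Returns the embedded table of monoisotopic atomic masses (Da), plus the
#' electron rest mass, so that every m/z the package writes can be
#' reproduced bit-exact from documented constants.
#'
#' @return A tibble with columns `element` and `mass`. The electron appears
#'   as pseudo-element `"e-"`.
#' @export
#' @examples
#' atomic_masses()
atomic_masses <- function() {
  tibble::tibble(
    element = c(names(.ATOMIC_MASS), "e-"),
    mass = c(unname(.ATOMIC_MASS), .ELECTRON_MASS)
  )
}

#' Parse a molecular formula string
#'
#' Hill-style formulas such as `"C46H80NO8P"` are turned into named element
#' counts. Only elements with embedded monoisotopic masses are accepted.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C5H15NO4P")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (formula == "" || is.na(formula)) {
    return(setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    abort(paste0("Cannot parse formula: '", formula, "'"))
  }
  el <- sub("[0-9]*$", "", toks)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1L
  bad <- setdiff(el, names(.ATOMIC_MASS))
  if (length(bad) > 0) {
    abort(paste0("Unknown element symbol(s): ", paste(bad, collapse = ", ")))
  }
  counts <- tapply(n, el, sum)
  setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula A formula string (e.g. `"C46H80NO8P"`) or a named numeric
#'   vector of element counts as returned by [parse_formula()].
#' @return Monoisotopic mass in Da. The empty formula has mass 0.
#' @export
#' @examples
#' formula_mass("C46H80NO8P") # neutral PC(16:0/22:6)
formula_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0) return(0)
  if (is.null(names(formula)) || any(!nzchar(names(formula)))) {
    abort("Element counts must be named by element symbol")
  }
  bad <- setdiff(names(formula), names(.ATOMIC_MASS))
  if (length(bad) > 0) {
    abort(paste0("Unknown element symbol(s): ", paste(bad, collapse = ", ")))
  }
  if (any(formula < 0)) abort("Element counts must be non-negative")
  sum(.ATOMIC_MASS[names(formula)] * as.numeric(formula))
}

#' Electrospray adducts known to the package
#'
#' Each adduct carries the mass delta (Da) between the neutral molecule and
#' the singly charged ion, including the electron-mass correction
#' (0.00054858 Da per charge).
#'
#' @return A tibble with columns `adduct`, `polarity`, `charge`, `mass_delta`.
#' @export
#' @examples
#' adduct_table()
adduct_table <- function() {
  H <- .ATOMIC_MASS[["H"]]; e <- .ELECTRON_MASS
  tibble::tribble(
    ~adduct,        ~polarity,  ~charge, ~mass_delta,
    "[M+H]+",       "positive", 1L, H - e,
    "[M+NH4]+",     "positive", 1L, formula_mass("NH4") - e,
    "[M+Na]+",      "positive", 1L, .ATOMIC_MASS[["Na"]] - e,
    "[M-H]-",       "negative", 1L, -(H - e),
    "[M+HCO2]-",    "negative", 1L, formula_mass("CHO2") + e,
    "[M+CH3CO2]-",  "negative", 1L, formula_mass("C2H3O2") + e,
    "[M-CH3]-",     "negative", 1L, -formula_mass("CH3") + e
  )
}

.adduct_lookup <- function(adduct) {
  tab <- adduct_table()
  i <- match(adduct, tab$adduct)
  if (anyNA(i)) {
    abort(paste0("Unknown adduct(s): ",
                 paste(unique(adduct[is.na(i)]), collapse = ", ")))
  }
  tab[i, ]
}

#' Ion m/z of a neutral molecule under an adduct
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0). Vectorised.
#' @param adduct Adduct name, e.g. `"[M+H]+"` or `"[M+HCO2]-"`.
#' @return m/z values, electron-mass corrected.
#' @export
#' @examples
#' ion_mz(805.5622, "[M+HCO2]-") # ~850.5604, the worked PC example
ion_mz <- function(neutral_mass, adduct) {
  stopifnot(all(neutral_mass > 0))
  a <- .adduct_lookup(adduct)
  (neutral_mass + a$mass_delta) / a$charge
}

#' m/z of a fragment ion given its ion formula
#'
#' The formula describes the atoms of the ion itself; the electron mass is
#' subtracted (cations) or added (anions) once per charge.
#'
#' @param formula Ion formula string or named counts.
#' @param polarity `"positive"` or `"negative"`.
#' @param charge Positive integer charge (default 1).
#' @return m/z of the fragment ion.
#' @export
#' @examples
#' fragment_ion_mz("C5H15NO4P", "positive") # phosphocholine head group 184.0733
#' fragment_ion_mz("C16H31O2", "negative")  # palmitate carboxylate 255.2330
fragment_ion_mz <- function(formula, polarity = c("positive", "negative"),
                            charge = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(charge >= 1)
  m <- formula_mass(formula)
  sign <- if (polarity == "positive") -1 else 1
  (m + sign * charge * .ELECTRON_MASS) / charge
}

#' Signed mass error in parts per million
#'
#' @param observed,theoretical m/z values; `theoretical` must be > 0.
#' @return `1e6 * (observed - theoretical) / theoretical`, sign preserved.
#' @export
#' @examples
#' ppm_error(744.5536, 744.5538)
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}

#' Round half away from zero
#'
#' m/z values are displayed at 4 decimals with half-up rounding, matching the
#' convention used when printing theoretical masses; base `round()` rounds
#' half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
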