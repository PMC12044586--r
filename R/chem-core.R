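# Exact monoisotopic mass arithmetic on elemental compositions.
#
# All m/z values in the package flow through this file, so the isotope table
# must be precise enough that printed 6-decimal m/z values reproduce exactly.
# Masses are CODATA/AME monoisotopic values (most abundant isotope).

.ISOTOPE_MASS <- c(
  H  = 1.00782503207,
  B  = 11.0093054,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840316273,
  Na = 22.9897692809,
  Mg = 23.985041697,
  Si = 27.9769265325,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.96370668,
  Ca = 39.96259098,
  Fe = 55.93493633,
  Cu = 62.92959772,
  Zn = 63.92914201,
  Se = 79.9165218,
  Br = 78.9183376,
  I  = 126.904473,
  Li = 7.01600455
)

.ELECTRON_MASS <- 0.00054857990907

#' Monoisotopic isotope masses used by the package
#'
#' @return Named numeric vector of monoisotopic masses (Da) for the supported
#'   element symbols.
#' @export
isotope_masses <- function() .ISOTOPE_MASS

#' Electron rest mass in daltons
#'
#' @return The electron mass (Da) used for charge-state corrections.
#' @export
electron_mass <- function() .ELECTRON_MASS

#' Construct an elemental composition
#'
#' An elemental composition is the unit of all mass arithmetic: a named
#' element-count vector plus a signed integer charge.
#'
#' @param counts Named integer vector, element symbol to count (all >= 0).
#' @param charge Integer charge of the species (signed; 0 = neutral).
#' @return An object of class `elemental_composition`.
#' @examples
#' composition(c(C = 8, H = 11, N = 1, O = 2))
#' @export
composition <- function(counts = integer(), charge = 0L) {
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("element counts must be named by element symbol")
    unknown <- setdiff(names(counts), names(.ISOTOPE_MASS))
    if (length(unknown))
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    if (any(counts < 0))
      stop("element counts must be non-negative")
    counts <- counts[counts > 0]
  }
  structure(
    list(counts = as.integer(round(counts)) |> stats::setNames(names(counts)),
         charge = as.integer(charge)),
    class = "elemental_composition"
  )
}

#' Parse a Hill-style molecular formula
#'
#' Accepts strings such as `"C8H11NO2"`: element symbols (one capital letter
#' plus optional lower-case letter) each followed by an optional integer
#' multiplicity.  Repeated symbols are summed.
#'
#' @param formula Character scalar, the formula.
#' @param charge Integer charge to attach (default 0, a neutral molecule).
#' @return An `elemental_composition` with the given charge.
#' @examples
#' parse_formula("C8H11NO2")    # dopamine and its isomers
#' parse_formula("C20H15FN")    # the FMP-10 cation skeleton
#' @export
parse_formula <- function(formula, charge = 0L) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("formula must be a single character string")
  formula <- gsub("[[:space:]]", "", formula)
  if (!nzchar(formula)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("formula contains unparseable characters: ", formula)
  syms <- sub("[0-9]*$", "", tokens)
  mult <- sub("^[A-Z][a-z]?", "", tokens)
  mult <- ifelse(nzchar(mult), as.integer(mult), 1L)
  unknown <- setdiff(syms, names(.ISOTOPE_MASS))
  if (length(unknown))
    stop("unknown element symbol(s) in formula '", formula, "': ",
         paste(unique(unknown), collapse = ", "))
  counts <- tapply(mult, syms, sum)
  composition(stats::setNames(as.integer(counts), names(counts)),
              charge = charge)
}

# Hill order: C first, H second, all other elements alphabetical.
# With no carbon, everything alphabetical.
.hill_order <- function(syms) {
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    c(intersect("C", syms), intersect("H", syms), rest)
  } else sort(syms)
}

#' Canonical Hill formula string of a composition
#'
#' @param x An `elemental_composition`.
#' @param ... Unused.
#' @return Character scalar (e.g. `"C8H11NO2"`); `""` for an empty
#'   composition.
#' @export
format.elemental_composition <- function(x, ...) {
  if (!length(x$counts)) return("")
  ord <- .hill_order(names(x$counts))
  n <- x$counts[ord]
  paste0(ord, ifelse(n > 1L, n, ""), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  chg <- if (x$charge == 0L) "neutral" else sprintf("charge %+d", x$charge)
  cat(sprintf("<composition %s, %s, m/z %.6f>\n",
              if (nzchar(format(x))) format(x) else "(empty)",
              chg, monoisotopic_mz(x)))
  invisible(x)
}

# element-wise combination; negative results are an error for subtraction
.comp_combine <- function(a, b, sign) {
  syms <- union(names(a$counts), names(b$counts))
  na <- stats::setNames(integer(length(syms)), syms)
  nb <- na
  na[names(a$counts)] <- a$counts
  nb[names(b$counts)] <- b$counts
  out <- na + sign * nb
  if (any(out < 0))
    stop("composition subtraction yields negative count for: ",
         paste(syms[out < 0], collapse = ", "))
  composition(out[out > 0], charge = a$charge + sign * b$charge)
}

#' Arithmetic on elemental compositions
#'
#' `+` and `-` combine counts element-wise and add/subtract charges, so ion
#' bookkeeping (tagging reactions, neutral losses, charge-reduction losses)
#' is ordinary arithmetic on compositions.
#'
#' @param e1,e2 `elemental_composition` objects.
#' @return An `elemental_composition`.
#' @export
Ops.elemental_composition <- function(e1, e2) {
  if (!.Generic %in% c("+", "-"))
    stop("operation '", .Generic, "' not defined for compositions")
  .comp_combine(e1, e2, if (.Generic == "+") 1L else -1L)
}

#' Monoisotopic mass-to-charge ratio of a composition
#'
#' Sums monoisotopic isotope masses, applies the electron-mass correction for
#' the charge state, and divides by |charge|.  A neutral composition returns
#' its neutral monoisotopic mass.
#'
#' @param comp An `elemental_composition`.
#' @return m/z in Da per unit charge (neutral mass for charge 0).
#' @examples
#' monoisotopic_mz(parse_formula("C8H11NO2"))              # 153.07898
#' monoisotopic_mz(parse_formula("C20H14N", charge = 1L))  # 268.112076
#' @export
monoisotopic_mz <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  mass <- sum(.ISOTOPE_MASS[names(comp$counts)] * comp$counts) -
    comp$charge * .ELECTRON_MASS
  if (comp$charge == 0L) mass else mass / abs(comp$charge)
}

#' Signed parts-per-million mass error
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return Signed ppm error `(observed - theoretical) / theoretical * 1e6`.
#'   Vectorized over both arguments.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

# round half away from zero at k decimals; R's round() is round-half-even,
# but printed instrument m/z values use conventional rounding
# (286.1226406 must print as 286.122641)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
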