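# ---- Frozen physical constants -------------------------------------------
# Monoisotopic atomic masses (Da). Frozen so golden tests are bit-stable.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740,
  O = 15.9949146,
  P = 30.97376151
)

# Proton mass (Da); subtracted from the neutral monoisotopic mass to give the
# [M-H]- anion mass under the standard negative-ESI convention.
.PROTON_MASS <- 1.00727646

.ELEMENTS <- names(.ATOMIC_MASS)

#' Construct an elemental formula
#'
#' An `elemental_formula` is a named integer vector of atom counts over the
#' alphabet C, H, N, O, P, with exact monoisotopic mass given by the dot
#' product with a frozen atomic-mass table (C = 12 exactly, H = 1.0078250319,
#' N = 14.0030740, O = 15.9949146, P = 30.97376151). Addition and subtraction
#' are element-wise; subtraction that would drive any count negative is an
#' error.
#'
#' @param C,H,N,O,P Non-negative integer atom counts.
#' @return An object of class `elemental_formula`.
#' @examples
#' guanosine <- elemental_formula(C = 10, H = 13, N = 5, O = 5)
#' formula_mass(guanosine)
#' @export
elemental_formula <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  counts <- c(C = C, H = H, N = N, O = O, P = P)
  if (any(counts < 0)) stop("element counts must be non-negative")
  if (any(counts != round(counts))) stop("element counts must be integers")
  structure(as.integer(round(counts)), names = .ELEMENTS,
            class = "elemental_formula")
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  structure(unclass(e1) + unclass(e2), names = .ELEMENTS,
            class = "elemental_formula")
}

#' @export
`-.elemental_formula` <- function(e1, e2) {
  out <- unclass(e1) - unclass(e2)
  if (any(out < 0))
    stop("formula subtraction would yield a negative atom count")
  structure(out, names = .ELEMENTS, class = "elemental_formula")
}

#' @export
`*.elemental_formula` <- function(e1, e2) {
  if (is.numeric(e1)) { k <- e1; f <- e2 } else { k <- e2; f <- e1 }
  if (length(k) != 1L || k < 0 || k != round(k))
    stop("formula scaling requires a single non-negative integer")
  structure(as.integer(unclass(f) * k), names = .ELEMENTS,
            class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  nz <- x[x > 0L]
  if (length(nz) == 0L) return("(empty)")
  paste0(names(nz), ifelse(nz > 1L, nz, ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x),
      sprintf("  (monoisotopic %.6f Da)\n", formula_mass(x)), sep = "")
  invisible(x)
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula An [elemental_formula()].
#' @return Monoisotopic mass in Da.
#' @export
formula_mass <- function(formula) {
  sum(unclass(formula) * .ATOMIC_MASS)
}

# Building blocks, frozen.
.F_CH2  <- elemental_formula(C = 1, H = 2)
.F_H2O  <- elemental_formula(H = 2, O = 1)
.F_TRIPHOSPHATE <- elemental_formula(H = 5, P = 3, O = 10)  # H5P3O10 bridge

# Base ribonucleoside formulas (neutral, unmodified).
.RIBONUCLEOSIDE <- list(
  A = elemental_formula(C = 10, H = 13, N = 5, O = 4),
  C = elemental_formula(C = 9,  H = 13, N = 3, O = 5),
  G = elemental_formula(C = 10, H = 13, N = 5, O = 5),
  U = elemental_formula(C = 9,  H = 12, N = 2, O = 6)
)

# Default allowed base-methyl counts: guanosine up to trimethyl (e.g. the
# N2,N2,7-trimethylguanosine cap), adenosine up to monomethyl (N6), none on
# C and U. Only the count affects mass; position names are bookkeeping.
.BASE_METHYL_MAX <- c(A = 1L, C = 0L, G = 3L, U = 0L)

#' Mass added by one methyl group (CH2), Da
#' @export
methyl_mass <- function() formula_mass(.F_CH2)

#' Construct a (possibly methylated) ribonucleoside
#'
#' A nucleoside is one of the four ribonucleosides A, C, G, U carrying
#' `base_methyls` N-methyl groups and optionally one 2'-O-ribose methyl.
#' Each methyl adds exactly one CH2 to the elemental formula.
#'
#' @param base One of `"A"`, `"C"`, `"G"`, `"U"`.
#' @param base_methyls Number of base N-methyl groups (default 0). Allowed
#'   ranges default to G: 0-3, A: 0-1, C/U: 0.
#' @param ribose_methyl Logical; 2'-O-methylated ribose?
#' @param base_methyl_max Named integer vector of per-base maxima, for
#'   alphabets extended beyond the default.
#' @return An object of class `nucleoside`.
#' @examples
#' nucleoside("G", base_methyls = 3)            # trimethylguanosine
#' nucleoside("A", ribose_methyl = TRUE)        # Am
#' @export
nucleoside <- function(base, base_methyls = 0L, ribose_methyl = FALSE,
                       base_methyl_max = .BASE_METHYL_MAX) {
  if (!is.character(base) || length(base) != 1L ||
      !base %in% names(.RIBONUCLEOSIDE))
    stop("unknown base: must be one of A, C, G, U")
  base_methyls <- as.integer(base_methyls)
  if (is.na(base_methyls) || base_methyls < 0L ||
      base_methyls > base_methyl_max[[base]])
    stop(sprintf("base methyl count %d outside allowed range 0-%d for %s",
                 base_methyls, base_methyl_max[[base]], base))
  structure(list(base = base, base_methyls = base_methyls,
                 ribose_methyl = isTRUE(ribose_methyl)),
            class = "nucleoside")
}

#' Elemental formula of a methylated ribonucleoside
#'
#' @inheritParams nucleoside
#' @return An [elemental_formula()]. Each base or ribose methyl adds CH2
#'   (14.01565 Da) to the unmodified ribonucleoside formula.
#' @examples
#' formula_of_nucleoside("G")                   # C10H13N5O5
#' formula_of_nucleoside("A", 1, TRUE)          # mAm
#' @export
formula_of_nucleoside <- function(base, base_methyls = 0L,
                                  ribose_methyl = FALSE,
                                  base_methyl_max = .BASE_METHYL_MAX) {
  n <- nucleoside(base, base_methyls, ribose_methyl, base_methyl_max)
  nucleoside_formula(n)
}

#' @rdname formula_of_nucleoside
#' @param n A `nucleoside` object.
#' @export
nucleoside_formula <- function(n) {
  stopifnot(inherits(n, "nucleoside"))
  .RIBONUCLEOSIDE[[n$base]] +
    (n$base_methyls + as.integer(n$ribose_methyl)) * .F_CH2
}

#' Short label of a nucleoside in cap notation
#'
#' Renders the field's abbreviations: `mN`/`2mN`/`3mN` for base mono-, di-,
#' tri-methylation and a trailing `m` for 2'-O-ribose methylation, so one
#' base methyl plus a ribose methyl on adenosine is `"mAm"`.
#'
#' @param n A `nucleoside`.
#' @return Character label.
#' @export
nucleoside_label <- function(n) {
  stopifnot(inherits(n, "nucleoside"))
  prefix <- c("", "m", "2m", "3m")[n$base_methyls + 1L]
  paste0(prefix, n$base, if (n$ribose_methyl) "m" else "")
}

#' @export
print.nucleoside <- function(x, ...) {
  cat("<nucleoside> ", nucleoside_label(x), "  (",
      format(nucleoside_formula(x)), ")\n", sep = "")
  invisible(x)
}

# A side is eligible to be written as the outer cap guanosine iff it is a G
# without ribose methylation; between two eligible sides the more methylated
# is written first (mGpppG, not GpppmG). Reproduces the published row labels.
.outer_rank <- function(n) {
  eligible <- n$base == "G" && !n$ribose_methyl
  c(if (eligible) 0 else 1,
    -n$base_methyls,
    match(n$base, c("G", "A", "C", "U")),
    as.integer(n$ribose_methyl))
}

#' Construct a 5'-5' triphosphate-bridged cap dinucleotide
#'
#' A cap structure is an unordered pair of (possibly methylated)
#' ribonucleosides joined by a 5'-5' triphosphate bridge. The neutral formula
#' is formula(outer) + formula(inner) + H5P3O10 - 2 H2O, and mass is
#' invariant under swapping the two sides (mass spectrometry cannot order
#' them). For reporting, the side resembling a cap guanosine (G without
#' ribose methylation, more base methyls first) is written first.
#'
#' @param outer,inner `nucleoside` objects (order is not significant for
#'   mass; it is canonicalized for labeling).
#' @return An object of class `cap_structure`.
#' @examples
#' cap <- cap_structure(nucleoside("G", 3), nucleoside("A", ribose_methyl = TRUE))
#' cap_label(cap)     # "3mGpppAm"
#' anion_mass(cap)
#' @export
cap_structure <- function(outer, inner) {
  stopifnot(inherits(outer, "nucleoside"), inherits(inner, "nucleoside"))
  sides <- list(outer, inner)
  ranks <- lapply(sides, .outer_rank)
  if (do.call(function(a, b) {
        d <- sign(a - b); d <- d[d != 0]; length(d) > 0 && d[1] > 0
      }, ranks)) {
    sides <- sides[c(2, 1)]
  }
  structure(list(outer = sides[[1]], inner = sides[[2]]),
            class = "cap_structure")
}

#' @rdname cap_structure
#' @param cap A `cap_structure`.
#' @param both_orders Logical; render the label as `"XpppY/YpppX"`?
#' @export
cap_label <- function(cap, both_orders = FALSE) {
  stopifnot(inherits(cap, "cap_structure"))
  a <- nucleoside_label(cap$outer)
  b <- nucleoside_label(cap$inner)
  lab <- paste0(a, "ppp", b)
  if (both_orders && a != b) lab <- paste0(lab, "/", b, "ppp", a)
  lab
}

#' Neutral elemental formula of a cap dinucleotide
#'
#' formula(outer) + formula(inner) + H5P3O10 - 2 H2O; symmetric in its
#' arguments.
#'
#' @param outer,inner `nucleoside` objects.
#' @return An [elemental_formula()].
#' @examples
#' cap_neutral_formula(nucleoside("G"), nucleoside("G"))  # C20H27N10O18P3
#' @export
cap_neutral_formula <- function(outer, inner) {
  nucleoside_formula(outer) + nucleoside_formula(inner) +
    .F_TRIPHOSPHATE - 2L * .F_H2O
}

#' Monoisotopic [M-H]- anion mass of a cap dinucleotide
#'
#' Neutral monoisotopic mass minus the proton mass 1.00727646 Da (standard
#' negative-ESI deprotonation; the electron is thereby handled implicitly).
#'
#' @param cap A `cap_structure`.
#' @return Mass in Da.
#' @export
anion_mass <- function(cap) {
  stopifnot(inherits(cap, "cap_structure"))
  formula_mass(cap_neutral_formula(cap$outer, cap$inner)) - .PROTON_MASS
}

#' @export
print.cap_structure <- function(x, ...) {
  cat("<cap_structure> ", cap_label(x, both_orders = TRUE),
      sprintf("  [M-H]- %.4f Da\n", anion_mass(x)), sep = "")
  invisible(x)
}

#' Total methyl count of a cap structure
#' @param cap A `cap_structure`.
#' @return Integer: base plus ribose methyls over both nucleosides.
#' @export
cap_total_methyls <- function(cap) {
  stopifnot(inherits(cap, "cap_structure"))
  with(cap, outer$base_methyls + inner$base_methyls +
         as.integer(outer$ribose_methyl) + as.integer(inner$ribose_methyl))
}

#' Mass accuracy in parts per million
#'
#' `(observed - calculated) / calculated * 1e6`, the standard MS
#' mass-accuracy measure. Vectorized; reports conventionally round to two
#' decimals.
#'
#' @param observed,calculated Masses in Da; `calculated` must be positive.
#' @return ppm error(s).
#' @examples
#' ppm_error(827.1308, 827.1294)  # 1.69 to two decimals
#' @export
ppm_error <- function(observed, calculated) {
  if (any(calculated <= 0)) stop("calculated mass must be positive")
  (observed - calculated) / calculated * 1e6
}

#' Frozen physical constants used by the mass calculator
#'
#' @return A data frame (constant, value, units) with the atomic monoisotopic
#'   masses, proton mass, and the CH2/H2O/H5P3O10 group masses.
#' @export
capchem_constants <- function() {
  data.frame(
    constant = c(paste0("atomic_mass_", .ELEMENTS), "proton_mass",
                 "methyl_CH2", "water_H2O", "triphosphate_H5P3O10"),
    value = c(unname(.ATOMIC_MASS), .PROTON_MASS, formula_mass(.F_CH2),
              formula_mass(.F_H2O), formula_mass(.F_TRIPHOSPHATE)),
    units = "Da",
    stringsAsFactors = FALSE
  )
}
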