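# Physical constants and residue tables used throughout the package.
# Monoisotopic atomic masses (CODATA/NIST); the proton mass is used for
# all m/z <-> neutral-mass conversions.

.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Fe = 55.93493750
)

#' Mass constants
#'
#' Frequently needed monoisotopic mass constants: the proton mass used for
#' charging, the water and ammonia neutral-loss masses, the averaged
#' C12/C13 isotopologue spacing, and the hexose-unit mass used for
#' pseudo-glycan elemental simulation.
#'
#' @format Named numeric vector of masses in daltons.
#' @export
massConstants <- c(
  proton   = 1.007276467,
  hydrogen = 1.00782503207,
  water    = 2 * 1.00782503207 + 15.9949146196,
  ammonia  = 3 * 1.00782503207 + 14.0030740048,
  neutron  = 1.0033548378,   # C13 - C12; isotopologue spacing
  hpo3     = 1.00782503207 + 30.97376163 + 3 * 15.9949146196
)

# Natural isotope abundances per element, nominal mass offsets 0,1,2,...
# relative to the principal isotope.  Fe-54 (lighter than the principal
# Fe-56) is dropped and the remainder renormalised; iron-containing
# species are not a target of this package.
.ISOTOPE_ABUNDANCE <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  S  = c(0.9499, 0.0075, 0.0425, 0.0, 0.0001),
  P  = 1.0,
  Fe = c(0.91754, 0.02119, 0.00282) / (0.91754 + 0.02119 + 0.00282)
)

# Amino-acid residue elemental compositions (canonical 20; I/L identical).
.AA_ELEMENTS <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

# Monosaccharide residue elemental compositions.  Registry is extensible
# at run time via registerMonosaccharide().
.MONO_ELEMENTS_BUILTIN <- list(
  Hex    = c(C = 6,  H = 10, O = 5),
  HexNAc = c(C = 8,  H = 13, N = 1, O = 5),
  Fuc    = c(C = 6,  H = 10, O = 4),
  NeuAc  = c(C = 11, H = 17, N = 1, O = 8),
  NeuGc  = c(C = 11, H = 17, N = 1, O = 9)
)

.pkgenv <- new.env(parent = emptyenv())
.pkgenv$mono <- .MONO_ELEMENTS_BUILTIN

#' Register a monosaccharide residue
#'
#' Extends the monosaccharide registry with a new residue, given its
#' elemental composition.  Registered residues participate in glycan mass
#' arithmetic, Y-ion stepping gaps and composition parsing.
#'
#' @param name Residue name (e.g. `"Pent"`).
#' @param elements Named numeric vector of element counts over
#'   C, H, N, O, S, P, Fe.
#' @return Invisibly, the residue monoisotopic mass in daltons.
#' @examples
#' registerMonosaccharide("Pent", c(C = 5, H = 8, O = 4))
#' monosaccharideMasses()[["Pent"]]
#' @export
registerMonosaccharide <- function(name, elements) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  elements <- elementalComposition(elements)
  .pkgenv$mono[[name]] <- elements
  invisible(elementMass(elements))
}

#' Monosaccharide residue masses
#'
#' @return Named numeric vector of monoisotopic residue masses (Da) for
#'   every registered monosaccharide (built-ins: Hex, HexNAc, Fuc, NeuAc,
#'   NeuGc).
#' @examples
#' monosaccharideMasses()["HexNAc"]
#' @export
monosaccharideMasses <- function() {
  vapply(.pkgenv$mono, elementMass, numeric(1))
}

.monoElements <- function(name) {
  el <- .pkgenv$mono[[name]]
  if (is.null(el))
    stop("unknown monosaccharide residue: ", name, call. = FALSE)
  el
}

# Residue monoisotopic masses for the 20 amino acids.
.aaMasses <- function() vapply(.AA_ELEMENTS, elementMass, numeric(1))

# Common modification masses.
.MOD_MASS <- c(
  carbamidomethyl = 57.02146372,   # +C2H3NO on Cys
  oxidation       = 15.9949146196  # +O on Met
)
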