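# Exact monoisotopic mass arithmetic: elemental compositions, glycan and
# peptide masses, aggregated isotope patterns, and the pseudo-glycan
# elemental simulation used for precursor envelope modelling.

#' Build an elemental composition
#'
#' An elemental composition is a named numeric vector of element counts
#' over the supported elements (C, H, N, O, S, P, Fe).  Counts are
#' normally non-negative integers; fractional counts are permitted only
#' for isotope simulation of pseudo-glycans (see
#' [pseudoGlycanElements()]).
#'
#' @param x Named numeric vector of element counts, or a list coercible
#'   to one.  Duplicate element names are summed.
#' @return Named numeric vector over the supported element alphabet.
#' @examples
#' water <- elementalComposition(c(H = 2, O = 1))
#' elementMass(water)
#' @export
elementalComposition <- function(x) {
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("elemental composition must be a named vector", call. = FALSE)
  bad <- setdiff(names(x), names(.ATOMIC_MASS))
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- tapply(as.numeric(x), names(x), sum)
  out <- out[names(out)]          # drop tapply attributes
  structure(as.numeric(out), names = names(out))
}

#' @rdname elementalComposition
#' @param ... Elemental compositions to sum element-wise.
#' @export
ecSum <- function(...) {
  parts <- list(...)
  all <- unlist(parts)
  elementalComposition(all)
}

#' @rdname elementalComposition
#' @param ec Elemental composition.
#' @param k Scalar multiplier (may be fractional or negative for
#'   transient arithmetic).
#' @export
ecScale <- function(ec, k) {
  structure(as.numeric(ec) * k, names = names(ec))
}

#' @rdname elementalComposition
#' @export
elementMass <- function(ec) {
  sum(as.numeric(ec) * .ATOMIC_MASS[names(ec)])
}

#' Monoisotopic mass of a glycan composition
#'
#' Sums registered monosaccharide residue masses weighted by their counts
#' and adds any moiety mass (a non-monosaccharide mass addition such as
#' phosphate or an ammonium adduct).
#'
#' @param comp A [GlycanComposition-class] object, a named numeric vector
#'   of residue counts, or a composition string such as
#'   `"Hex(5)HexNAc(2)"` or `"Hex(6)HexNAc(2)+17.0265"`.
#' @return Monoisotopic mass in daltons.
#' @examples
#' glycanMass("Hex(3)HexNAc(2)")   # the N-glycan pentasaccharide core, ~892.32
#' @export
glycanMass <- function(comp) {
  comp <- as.glycanComposition(comp)
  counts <- comp@counts
  if (any(counts < 0)) stop("negative residue count", call. = FALSE)
  m <- monosaccharideMasses()
  unknown <- setdiff(names(counts), names(m))
  if (length(unknown))
    stop("unknown residue name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sum(counts * m[names(counts)]) + comp@moietyMass
}

#' Elemental composition of a glycan
#'
#' @param comp As for [glycanMass()]; the moiety mass must be zero
#'   (moieties have no assigned elemental composition).
#' @return Elemental composition vector.
#' @export
glycanElements <- function(comp) {
  comp <- as.glycanComposition(comp)
  if (comp@moietyMass != 0)
    stop("glycan with non-zero moiety mass has no exact elemental ",
         "composition; use pseudoGlycanElements()", call. = FALSE)
  counts <- comp@counts
  parts <- lapply(names(counts), function(r) ecScale(.monoElements(r),
                                                     counts[[r]]))
  elementalComposition(unlist(parts))
}

#' Monoisotopic mass of a peptide
#'
#' @param sequence Character string over the 20 canonical amino acids.
#' @param modMass Numeric vector of modification masses in daltons (one
#'   entry per modification; positions do not affect the total mass).
#' @return Neutral monoisotopic mass in daltons (residues + water + mods).
#' @examples
#' peptideMass("PEPTIDE")
#' @export
peptideMass <- function(sequence, modMass = numeric(0)) {
  sum(residueMasses(sequence)) + massConstants[["water"]] + sum(modMass)
}

#' Per-residue masses of a peptide, optionally with positioned mods
#'
#' @param sequence Peptide string.
#' @param modPos Integer positions (1-based) of modifications.
#' @param modMass Masses added at `modPos`.
#' @return Numeric vector of residue masses, modifications folded in at
#'   their positions.
#' @export
residueMasses <- function(sequence, modPos = integer(0),
                          modMass = numeric(0)) {
  if (!nzchar(sequence)) stop("empty peptide sequence", call. = FALSE)
  aa <- strsplit(sequence, "")[[1]]
  m <- .aaMasses()
  bad <- setdiff(aa, names(m))
  if (length(bad))
    stop("non-canonical residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  r <- unname(m[aa])
  if (length(modPos)) {
    stopifnot(length(modPos) == length(modMass),
              all(modPos >= 1L), all(modPos <= length(aa)))
    for (i in seq_along(modPos)) r[modPos[i]] <- r[modPos[i]] + modMass[i]
  }
  r
}

#' Elemental composition of a peptide
#'
#' Modification masses are mapped to elements for the two standard
#' modifications (carbamidomethyl-C, +57.02146 = C2H3NO; oxidation-M,
#' +15.99491 = O); other masses are rejected.
#'
#' @inheritParams peptideMass
#' @return Elemental composition including the terminal water.
#' @export
peptideElements <- function(sequence, modMass = numeric(0)) {
  aa <- strsplit(sequence, "")[[1]]
  parts <- .AA_ELEMENTS[aa]
  if (any(vapply(parts, is.null, logical(1))))
    stop("non-canonical residue in ", sequence, call. = FALSE)
  ec <- elementalComposition(unlist(unname(parts)))
  ec <- ecSum(ec, c(H = 2, O = 1))
  for (mm in modMass) {
    if (abs(mm - .MOD_MASS[["carbamidomethyl"]]) < 1e-3)
      ec <- ecSum(ec, c(C = 2, H = 3, N = 1, O = 1))
    else if (abs(mm - .MOD_MASS[["oxidation"]]) < 1e-3)
      ec <- ecSum(ec, c(O = 1))
    else
      stop("no elemental composition known for modification mass ", mm,
           call. = FALSE)
  }
  ec
}

# Convolve two truncated abundance vectors (offsets 0..len-1).
.convTrunc <- function(a, b, nKeep) {
  n <- min(nKeep, length(a) + length(b) - 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1L)
    if (jmax >= 1L) {
      idx <- i:(i + jmax - 1L)
      out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
    }
  }
  out
}

# Isotopologue distribution of n atoms of one element, by repeated
# squaring of the element's natural-abundance polynomial.
.elementPattern <- function(element, n, nKeep) {
  v <- .ISOTOPE_ABUNDANCE[[element]]
  if (is.null(v)) stop("no isotope data for element ", element, call. = FALSE)
  acc <- 1.0
  base <- v
  while (n > 0L) {
    if (n %% 2L == 1L) acc <- .convTrunc(acc, base, nKeep)
    n <- n %/% 2L
    if (n > 0L) base <- .convTrunc(base, base, nKeep)
  }
  acc
}

.integerPattern <- function(counts, nKeep) {
  acc <- 1.0
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n > 0L) acc <- .convTrunc(acc, .elementPattern(el, n, nKeep), nKeep)
  }
  length(acc) <- nKeep
  acc[is.na(acc)] <- 0
  acc
}

#' Aggregated isotope pattern of an elemental composition
#'
#' Convolves natural isotope abundances element-wise to obtain the
#' aggregated (nominal-offset) isotopologue distribution, truncated to
#' `nPeaks` and renormalised so the most abundant peak is 1.
#'
#' Fractional element counts (pseudo-glycan simulation) are handled by
#' linear interpolation between the integer-hexose convolutions when the
#' composition carries a `hexUnits` attribute, and by per-element
#' interpolation otherwise.
#'
#' @param ec Elemental composition (see [elementalComposition()]).
#' @param nPeaks Number of isotopologue peaks to return (>= 1).
#' @return `data.frame` with columns `offset` (0-based nominal offset)
#'   and `abundance` (max = 1).
#' @examples
#' isotopePattern(c(C = 100), nPeaks = 4)
#' @export
isotopePattern <- function(ec, nPeaks = 6L) {
  stopifnot(nPeaks >= 1L)
  counts <- as.numeric(ec)
  names(counts) <- names(ec)
  hexUnits <- attr(ec, "hexUnits")
  frac <- counts - floor(counts)
  if (!is.null(hexUnits) && any(frac > 1e-12)) {
    # interpolate between whole-composition convolutions at floor/ceil Hex
    k <- floor(hexUnits); f <- hexUnits - k
    hexEl <- c(C = 6, H = 10, O = 5)
    base <- counts - hexUnits * c(C = 6, H = 10, N = 0, O = 5, S = 0,
                                  P = 0, Fe = 0)[names(counts)]
    lo <- round(base + k * c(C = 6, H = 10, N = 0, O = 5, S = 0, P = 0,
                             Fe = 0)[names(counts)])
    hi <- lo + c(C = 6, H = 10, N = 0, O = 5, S = 0, P = 0,
                 Fe = 0)[names(counts)]
    if (any(lo < 0) || any(hi < 0))
      stop("pseudo-glycan element count below zero", call. = FALSE)
    p <- (1 - f) * .integerPattern(lo, nPeaks) +
      f * .integerPattern(hi, nPeaks)
  } else if (any(frac > 1e-12)) {
    # per-element interpolation for general fractional counts
    p <- 1.0
    for (el in names(counts)) {
      n <- counts[[el]]
      if (n < 0) stop("negative element count", call. = FALSE)
      k <- floor(n); f <- n - k
      ep <- .elementPattern(el, k, nPeaks)
      if (f > 1e-12)
        ep <- (1 - f) * ep + f * .elementPattern(el, k + 1L, nPeaks)
      p <- .convTrunc(p, ep, nPeaks)
    }
    length(p) <- nPeaks
    p[is.na(p)] <- 0
  } else {
    if (any(counts < 0)) stop("negative element count", call. = FALSE)
    p <- .integerPattern(round(counts), nPeaks)
  }
  data.frame(offset = seq_len(nPeaks) - 1L, abundance = p / max(p))
}

#' Pseudo-glycan elemental composition for a glycan mass
#'
#' The precursor isotope envelope of a glycopeptide is simulated from the
#' peptide's exact elements plus a pseudo-glycan: the elements of the
#' N-glycan pentasaccharide core Hex(3)HexNAc(2) (892.3172 Da) plus the
#' residual mass expressed as a (possibly fractional, possibly negative)
#' number of hexose units (C6H10O5).  This sidesteps the need to know the
#' true composition when only the glycan mass is available.
#'
#' @param glycanMass Neutral glycan mass in daltons (> 0).
#' @return Elemental composition (fractional counts allowed) carrying a
#'   `hexUnits` attribute; `elementMass()` of the result reproduces
#'   `glycanMass` exactly.
#' @examples
#' ec <- pseudoGlycanElements(1216.4229)  # core + 2 hexose units
#' elementMass(ec)
#' @export
pseudoGlycanElements <- function(glycanMass) {
  stopifnot(glycanMass > 0)
  coreEl <- glycanElements(c(Hex = 3, HexNAc = 2))
  coreMass <- elementMass(coreEl)
  hexMass <- monosaccharideMasses()[["Hex"]]
  r <- (glycanMass - coreMass) / hexMass
  full <- c(C = 0, H = 0, N = 0, O = 0)
  full[names(coreEl)] <- coreEl
  ec <- full + r * c(C = 6, H = 10, N = 0, O = 5)
  if (any(ec < -1e-9))
    stop("glycan mass ", glycanMass,
         " Da too small for pseudo-glycan simulation", call. = FALSE)
  ec[ec < 0] <- 0
  attr(ec, "hexUnits") <- r
  ec
}
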