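# S4 containers: glycan compositions, MS2 spectra, the MS1 map and
# peptide fragmentation patterns.

#' GlycanComposition: a monosaccharide count vector
#'
#' Counts per registered monosaccharide residue plus an optional moiety
#' mass, non-zero only for modified glycans (e.g. phosphorylated or
#' ammonium-adducted glycans discovered by monosaccharide stepping).
#'
#' @slot counts Named numeric vector of non-negative residue counts.
#' @slot moietyMass Single numeric, daltons; 0 for unmodified glycans.
#' @aliases GlycanComposition
#' @exportClass GlycanComposition
setClass("GlycanComposition",
  representation(counts = "numeric", moietyMass = "numeric"),
  prototype(counts = numeric(0), moietyMass = 0),
  validity = function(object) {
    if (length(object@moietyMass) != 1L) return("moietyMass must be scalar")
    if (any(object@counts < 0)) return("residue counts must be >= 0")
    if (length(object@counts) && is.null(names(object@counts)))
      return("counts must be named by residue")
    TRUE
  })

#' Construct a glycan composition
#'
#' @param ... Residue counts as named arguments (e.g. `Hex = 5,
#'   HexNAc = 2`) or a single named vector.
#' @param moietyMass Extra non-monosaccharide mass in daltons.
#' @return A [GlycanComposition-class] object.
#' @examples
#' glycanComposition(Hex = 5, HexNAc = 2)
#' parseGlycanComposition("Hex(6)HexNAc(2)+17.0265")
#' @export
glycanComposition <- function(..., moietyMass = 0) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]])))
    counts <- args[[1]]
  else
    counts <- unlist(args)
  counts <- counts[counts != 0]
  if (length(counts)) {
    reg <- names(.pkgenv$mono)
    unknown <- setdiff(names(counts), reg)
    if (length(unknown))
      stop("unknown residue name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    counts <- counts[order(match(names(counts), reg))]
  }
  new("GlycanComposition",
      counts = stats::setNames(as.numeric(counts), names(counts)),
      moietyMass = moietyMass)
}

#' @rdname glycanComposition
#' @param x Composition string, named count vector, or
#'   `GlycanComposition`.
#' @export
as.glycanComposition <- function(x) {
  if (methods::is(x, "GlycanComposition")) return(x)
  if (is.character(x)) return(parseGlycanComposition(x))
  if (is.numeric(x) && !is.null(names(x)))
    return(glycanComposition(x, moietyMass = 0))
  stop("cannot interpret as a glycan composition", call. = FALSE)
}

#' @rdname glycanComposition
#' @param string Canonical composition string, residues as
#'   `Name(count)` runs with an optional trailing `+mass` or `-mass`
#'   moiety term.
#' @export
parseGlycanComposition <- function(string) {
  s <- gsub("\\s", "", string)
  moiety <- 0
  m <- regmatches(s, regexec("([+-]\\d+\\.?\\d*)$", s))[[1]]
  if (length(m)) {
    moiety <- as.numeric(m[2])
    s <- sub("([+-]\\d+\\.?\\d*)$", "", s)
  }
  if (nzchar(s)) {
    pieces <- regmatches(s, gregexpr("[A-Za-z]+\\(\\d+\\)", s))[[1]]
    if (!length(pieces) || sum(nchar(pieces)) != nchar(s))
      stop("cannot parse glycan composition string: ", string, call. = FALSE)
    nm <- sub("\\(.*", "", pieces)
    ct <- as.numeric(sub(".*\\((\\d+)\\)", "\\1", pieces))
    counts <- stats::setNames(ct, nm)
  } else counts <- numeric(0)
  glycanComposition(counts, moietyMass = moiety)
}

#' Canonical label of a glycan composition
#'
#' Residues in registry order with non-zero counts, followed by the
#' moiety mass with sign when present, e.g. `"Hex(6)HexNAc(2)+17.0265"`.
#'
#' @param comp A [GlycanComposition-class] (or coercible).
#' @return Character scalar.
#' @export
glycanLabel <- function(comp) {
  comp <- as.glycanComposition(comp)
  counts <- comp@counts[comp@counts > 0]
  s <- paste0(names(counts), "(", format(counts, trim = TRUE), ")",
              collapse = "")
  if (comp@moietyMass != 0)
    s <- paste0(s, ifelse(comp@moietyMass > 0, "+", "-"),
                format(round(abs(comp@moietyMass), 4), nsmall = 4))
  s
}

#' @describeIn glycanComposition Residue counts accessor.
#' @param comp A `GlycanComposition`.
#' @export
glycanCounts <- function(comp) comp@counts

#' @describeIn glycanComposition Moiety mass accessor.
#' @export
moietyMass <- function(comp) comp@moietyMass

setMethod("show", "GlycanComposition", function(object) {
  cat("GlycanComposition:", glycanLabel(object),
      sprintf("(%.4f Da)\n", glycanMass(object)))
})

#' Ms2Spectrum: one centroided MS2 scan
#'
#' @slot scanId Scan identifier string.
#' @slot precursorMz Precursor m/z (Th).
#' @slot precursorCharge Precursor charge (>= 1).
#' @slot rt Retention time in seconds.
#' @slot mz Peak m/z values, strictly ascending.
#' @slot intensity Peak intensities (>= 0), parallel to `mz`.
#' @aliases Ms2Spectrum
#' @exportClass Ms2Spectrum
setClass("Ms2Spectrum",
  representation(scanId = "character", precursorMz = "numeric",
                 precursorCharge = "integer", rt = "numeric",
                 mz = "numeric", intensity = "numeric"),
  validity = function(object) {
    if (length(object@mz) != length(object@intensity))
      return("mz and intensity must be parallel")
    if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
      return("mz must be strictly ascending")
    if (any(object@intensity < 0)) return("intensities must be >= 0")
    if (object@precursorCharge < 1L) return("precursor charge must be >= 1")
    TRUE
  })

#' Construct an MS2 spectrum
#'
#' Peaks are sorted by m/z on construction; exact-duplicate m/z values
#' are merged by intensity summation.
#'
#' @param scanId Scan identifier.
#' @param precursorMz Precursor m/z in Th.
#' @param precursorCharge Integer charge >= 1.
#' @param rt Retention time, seconds.
#' @param mz,intensity Parallel peak arrays.
#' @return An [Ms2Spectrum-class] object.
#' @export
ms2Spectrum <- function(scanId, precursorMz, precursorCharge, rt,
                        mz, intensity) {
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (length(mz) > 1L) {
    dup <- c(FALSE, diff(mz) == 0)
    if (any(dup)) {
      grp <- cumsum(!dup)
      intensity <- as.numeric(tapply(intensity, grp, sum))
      mz <- mz[!dup]
    }
  }
  new("Ms2Spectrum", scanId = as.character(scanId),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      rt = as.numeric(rt), mz = as.numeric(mz),
      intensity = as.numeric(intensity))
}

#' @describeIn ms2Spectrum Number of peaks.
#' @param s An `Ms2Spectrum`.
#' @export
peakCount <- function(s) length(s@mz)

#' @describeIn ms2Spectrum Scan identifier accessor.
#' @export
scanId <- function(s) s@scanId

#' @describeIn ms2Spectrum Neutral precursor mass
#'   (`mz * z - z * proton`).
#' @export
precursorMass <- function(s) {
  s@precursorMz * s@precursorCharge -
    s@precursorCharge * massConstants[["proton"]]
}

setMethod("show", "Ms2Spectrum", function(object) {
  cat(sprintf(
    "Ms2Spectrum %s: %d peaks, precursor %.4f (%d+), RT %.1f s\n",
    object@scanId, length(object@mz), object@precursorMz,
    object@precursorCharge, object@rt))
})

#' Ms1Map: retention-time ordered MS1 frames
#'
#' Holds the MS1 dimension of a run and answers m/z-window by RT-window
#' extracted-ion-chromatogram queries.
#'
#' @slot rt Frame retention times, seconds, ascending.
#' @slot frames List of per-frame peak lists, each `list(mz=, intensity=)`.
#' @aliases Ms1Map
#' @exportClass Ms1Map
setClass("Ms1Map",
  representation(rt = "numeric", frames = "list"),
  validity = function(object) {
    if (length(object@rt) != length(object@frames))
      return("rt and frames must be parallel")
    if (length(object@rt) > 1L && any(diff(object@rt) <= 0))
      return("frames must be RT-ascending")
    TRUE
  })

#' Construct an MS1 map
#'
#' @param rt Frame retention times (seconds), ascending.
#' @param frames List of `list(mz =, intensity =)` per frame (m/z
#'   ascending within a frame).
#' @return An [Ms1Map-class] object.
#' @export
ms1Map <- function(rt, frames) {
  o <- order(rt)
  new("Ms1Map", rt = as.numeric(rt[o]), frames = frames[o])
}

#' Extracted ion chromatogram from an MS1 map
#'
#' Sums, per frame, the intensity of all MS1 peaks within a ppm window
#' around a target m/z, restricted to an RT window.
#'
#' @param map An [Ms1Map-class].
#' @param mz Target m/z (Th).
#' @param tolPpm Half-window in ppm.
#' @param rtRange Length-2 numeric RT window in seconds (default: all).
#' @return `data.frame` with columns `rt` and `intensity`.
#' @export
extractXic <- function(map, mz, tolPpm = 20, rtRange = NULL) {
  keep <- if (is.null(rtRange)) seq_along(map@rt) else
    which(map@rt >= rtRange[1] & map@rt <= rtRange[2])
  dm <- mz * tolPpm * 1e-6
  inten <- vapply(keep, function(i) {
    fr <- map@frames[[i]]
    lo <- findInterval(mz - dm, fr$mz)
    hi <- findInterval(mz + dm, fr$mz)
    if (hi > lo) sum(fr$intensity[(lo + 1L):hi]) else 0
  }, numeric(1))
  data.frame(rt = map@rt[keep], intensity = inten)
}

setMethod("show", "Ms1Map", function(object) {
  cat(sprintf("Ms1Map: %d frames, RT %.1f-%.1f s\n", length(object@rt),
              if (length(object@rt)) min(object@rt) else NA,
              if (length(object@rt)) max(object@rt) else NA))
})

#' FragmentationPattern: an ion-type intensity signature
#'
#' Normalised intensities per peptide fragment ion type (series b/y,
#' index, neutral-loss tag), charge states pre-summed.  The maximum value
#' is 1 when the pattern is non-empty.
#'
#' @slot values Named numeric vector in `[0, 1]`, names like `"b2"`,
#'   `"y5-NH3"`.
#' @slot support Number of PSMs contributing (for averaged patterns).
#' @slot meanRt Mean retention time of the contributing PSMs, seconds.
#' @aliases FragmentationPattern
#' @exportClass FragmentationPattern
setClass("FragmentationPattern",
  representation(values = "numeric", support = "integer",
                 meanRt = "numeric"),
  prototype(values = numeric(0), support = 0L, meanRt = NA_real_),
  validity = function(object) {
    if (length(object@values)) {
      if (is.null(names(object@values))) return("values must be named")
      if (abs(max(object@values) - 1) > 1e-9)
        return("non-empty pattern must have max value 1")
      if (any(object@values < 0)) return("values must be >= 0")
    }
    TRUE
  })

#' @describeIn extractPattern Pattern values accessor.
#' @param p A `FragmentationPattern`.
#' @export
patternValues <- function(p) p@values

#' @describeIn extractPattern Support (contributing PSM count) accessor.
#' @export
patternSupport <- function(p) p@support

setMethod("show", "FragmentationPattern", function(object) {
  cat(sprintf(
    "FragmentationPattern: %d ion types, support %d, mean RT %.1f s\n",
    length(object@values), object@support, object@meanRt))
})
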