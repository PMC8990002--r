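# MS1 elution-profile quantification of intact glycopeptides and
# site-level glycan abundance distributions.

#' Quantify a glycopeptide from MS1 elution profiles
#'
#' Computes the theoretical isotopologue m/z list from the glycopeptide
#' elemental composition (peptide elements plus the pseudo-glycan
#' simulation of the glycan mass, so modified glycans are covered),
#' extracts and sums the isotopologue XICs per charge state, integrates
#' the summed trace by the trapezoidal rule between the apex and the
#' points where intensity falls below 1% of the apex or a local valley,
#' and sums areas over charge states (shared apex).
#'
#' @param pepElements Peptide elemental composition.
#' @param glycanMass Glycan mass (moiety included), Da.
#' @param charges Charge states to extract.
#' @param rt Triggering retention time, seconds (apex search center).
#' @param ms1 [Ms1Map-class].
#' @param tolPpm MS1 tolerance, ppm.
#' @param nIso Isotopologues summed.
#' @param rtHalfWindow XIC extraction half-window, seconds.
#' @return List with `area` (intensity-seconds), `traces` (per-charge
#'   `data.frame(rt, intensity)`), `bounds` (RT integration bounds) and
#'   `flag` (`"ok"` or `"no-ms1-signal"`).
#' @export
quantifyGlycopeptide <- function(pepElements, glycanMass, charges, rt,
                                 ms1, tolPpm = 20, nIso = 4L,
                                 rtHalfWindow = 60) {
  prot <- massConstants[["proton"]]
  neutron <- massConstants[["neutron"]]
  mass <- elementMass(pepElements) + glycanMass
  rtRange <- c(rt - rtHalfWindow, rt + rtHalfWindow)
  traces <- list()
  total <- NULL
  for (z in charges) {
    mono <- (mass + z * prot) / z
    tr <- NULL
    for (j in 0:(nIso - 1L)) {
      x <- extractXic(ms1, mono + j * neutron / z, tolPpm, rtRange)
      tr <- if (is.null(tr)) x else
        data.frame(rt = tr$rt, intensity = tr$intensity + x$intensity)
    }
    traces[[as.character(z)]] <- tr
    total <- if (is.null(total)) tr else
      data.frame(rt = total$rt, intensity = total$intensity +
                   tr$intensity)
  }
  if (is.null(total) || !nrow(total) || max(total$intensity) <= 0)
    return(list(area = 0, traces = traces,
                bounds = c(NA_real_, NA_real_), flag = "no-ms1-signal"))
  apex <- which.max(total$intensity)
  bounds <- .integrationBounds(total$intensity, apex)
  area <- 0
  for (tr in traces) {
    seg <- seq(bounds[1], bounds[2])
    if (length(seg) > 1L)
      area <- area + sum(diff(tr$rt[seg]) *
                           (utils::head(tr$intensity[seg], -1) +
                              utils::tail(tr$intensity[seg], -1)) / 2)
  }
  list(area = area, traces = traces,
       bounds = total$rt[bounds], flag = "ok")
}

# Indices bounding the apex: descend until < 1% of apex or a valley.
.integrationBounds <- function(y, apex) {
  thr <- 0.01 * y[apex]
  lo <- apex
  while (lo > 1L && y[lo - 1L] >= thr && y[lo - 1L] <= y[lo]) lo <- lo - 1L
  hi <- apex
  n <- length(y)
  while (hi < n && y[hi + 1L] >= thr && y[hi + 1L] <= y[hi]) hi <- hi + 1L
  c(lo, hi)
}

#' Site-specific glycan abundance distribution
#'
#' Aggregates quantified glycoforms by protein glycosite and normalises
#' elution areas to relative abundance fractions per site.
#'
#' @param quantTable `data.frame` with columns `protein`, `site`
#'   (1-based residue index), `glycan` (composition label) and `area`.
#' @return `data.frame(protein, site, glycan, area, fraction)`;
#'   fractions sum to 1 within each site.  Sites whose areas are all
#'   zero are dropped with a warning.
#' @export
siteDistribution <- function(quantTable) {
  need <- c("protein", "site", "glycan", "area")
  miss <- setdiff(need, names(quantTable))
  if (length(miss))
    stop("quant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  agg <- stats::aggregate(area ~ protein + site + glycan,
                          data = quantTable, FUN = sum)
  out <- list()
  for (key in split(agg, interaction(agg$protein, agg$site,
                                     drop = TRUE))) {
    tot <- sum(key$area)
    if (tot <= 0) {
      warning("site ", key$protein[1], ":", key$site[1],
              " has zero total area and was dropped")
      next
    }
    key$fraction <- key$area / tot
    out[[length(out) + 1L]] <- key
  }
  if (!length(out))
    return(data.frame(protein = character(0), site = integer(0),
                      glycan = character(0), area = numeric(0),
                      fraction = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
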