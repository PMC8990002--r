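# Glycan and moiety mass profiling: rough 1-Da histograms, precise
# sliding-window mass bins, smoothed moiety profiles and post-hoc mass
# harmonisation.

#' Rough glycan-mass histogram
#'
#' 1-Da bins centred at integer values over 0-6000 Da.
#'
#' @param masses Glycan masses, Da.
#' @return `data.frame(center, count)` for non-empty bins.
#' @export
roughMassHistogram <- function(masses) {
  masses <- masses[masses >= -0.5 & masses < 6000.5]
  if (!length(masses))
    return(data.frame(center = numeric(0), count = integer(0)))
  center <- round(masses)
  tab <- table(center)
  data.frame(center = as.numeric(names(tab)),
             count = as.integer(tab))
}

#' Precise mass-bin center by sliding windows
#'
#' Slides a window of `width` Da (quarter-width steps) across the mass
#' range and refines the most populated window once with `refineWidth`;
#' the final bin center (center of the maximum-count window) is the
#' observation mass value.
#'
#' @param masses Masses in one rough cluster, Da.
#' @param width First-pass window width, Da.
#' @param refineWidth Refinement window width, Da.
#' @return List with `center` and `count`.
#' @export
preciseMassBin <- function(masses, width = 0.002,
                           refineWidth = 0.001) {
  if (!length(masses)) stop("no masses", call. = FALSE)
  pass <- function(m, w) {
    lo <- min(m); hi <- max(m)
    if (hi - lo < w / 2) return(list(center = stats::median(m),
                                     count = length(m)))
    starts <- seq(lo - w, hi, by = w / 4)
    counts <- vapply(starts, function(s0)
      sum(m >= s0 & m < s0 + w), integer(1))
    i <- which.max(counts)
    list(center = starts[i] + w / 2, count = counts[i])
  }
  p1 <- pass(masses, width)
  sel <- masses[abs(masses - p1$center) <= width]
  p2 <- pass(sel, refineWidth)
  list(center = p2$center, count = p2$count)
}

#' Build glycan-mass profiles from GPSMs
#'
#' Rough 1-Da histogram of the glycan masses plus, for every populated
#' rough bin, the precise sliding-window mass bin.
#'
#' @param glycanMasses Glycan masses of the GPSMs, Da.
#' @return List with `rough` (the 1-Da histogram) and `precise`
#'   (`data.frame(roughCenter, center, count)`).
#' @export
buildMassProfiles <- function(glycanMasses) {
  rough <- roughMassHistogram(glycanMasses)
  if (!nrow(rough))
    return(list(rough = rough,
                precise = data.frame(roughCenter = numeric(0),
                                     center = numeric(0),
                                     count = integer(0))))
  precise <- do.call(rbind, lapply(rough$center, function(ctr) {
    sel <- glycanMasses[round(glycanMasses) == ctr]
    p <- preciseMassBin(sel)
    data.frame(roughCenter = ctr, center = p$center, count = p$count)
  }))
  list(rough = rough, precise = precise)
}

#' Smoothed moiety-mass profile
#'
#' Histogram of moiety masses at 0.001-Da bin width, smoothed by a
#' centred moving average (width 5 bins) to obtain a monotonic peak
#' shape; the center of the maximum bin is the moiety observation mass.
#'
#' @param moieties Moiety masses, Da.
#' @param binWidth Bin width, Da.
#' @param smoothWidth Moving-average width, bins (odd).
#' @return List with `profile` (`data.frame(center, count, smoothed)`)
#'   and `observation` (the peak-bin center).
#' @export
moietyProfile <- function(moieties, binWidth = 0.001,
                          smoothWidth = 5L) {
  if (!length(moieties)) stop("no moiety masses", call. = FALSE)
  lo <- floor(min(moieties) / binWidth) - 5L
  hi <- ceiling(max(moieties) / binWidth) + 5L
  centers <- (lo:hi) * binWidth
  counts <- vapply(centers, function(ctr)
    sum(abs(moieties - ctr) <= binWidth / 2), integer(1))
  k <- rep(1 / smoothWidth, smoothWidth)
  sm <- as.numeric(stats::filter(counts, k, sides = 2))
  sm[is.na(sm)] <- 0
  list(profile = data.frame(center = centers, count = counts,
                            smoothed = sm),
       observation = centers[which.max(sm)])
}

#' Harmonise glycan masses across GPSMs
#'
#' GPSMs whose glycan masses fall within the tolerance of the same
#' precise mass-bin center are assigned that center as their common
#' glycan mass, so the same glycan observed in different spectra gets a
#' single composition downstream.
#'
#' @param glycanMasses Glycan masses, Da.
#' @param tolDa Assignment tolerance, Da.
#' @return Numeric vector of harmonised masses (unchanged where no
#'   precise bin is within tolerance).
#' @export
harmonizeGlycanMasses <- function(glycanMasses, tolDa = 0.05) {
  prof <- buildMassProfiles(glycanMasses)
  if (!nrow(prof$precise)) return(glycanMasses)
  vapply(glycanMasses, function(m) {
    d <- abs(prof$precise$center - m)
    i <- which.min(d)
    if (d[i] <= tolDa) prof$precise$center[i] else m
  }, numeric(1))
}
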