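# Reading and writing MS runs: mzML through mzR, MGF natively.

#' Read an LC-MS/MS run
#'
#' Reads a centroided run from mzML (MS1 + MS2) or MGF (MS2 only).
#' Retention times are converted to seconds and peak arrays sorted by
#' m/z.
#'
#' @param path File path.
#' @param format `"mzML"` or `"MGF"`; default inferred from the file
#'   extension.
#' @return `list(ms1 = Ms1Map or NULL, ms2 = list of Ms2Spectrum)`.
#' @examples
#' \dontrun{run <- readRun("run.mzML")}
#' @export
readRun <- function(path, format = c("auto", "mzML", "MGF")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mgf") "MGF" else "mzML"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "MGF") list(ms1 = NULL, ms2 = .readMgf(path))
  else .readMzml(path)
}

.readMzml <- function(path) {
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  if (any(!is.na(hd$centroided) & !hd$centroided))
    warning("profile-mode scans present; peak picking is not performed ",
            "and these scans are used as-is")
  ms1idx <- which(hd$msLevel == 1L)
  ms2idx <- which(hd$msLevel == 2L)
  ms1 <- NULL
  if (length(ms1idx)) {
    frames <- lapply(ms1idx, function(i) {
      m <- pk[[i]]
      o <- order(m[, 1])
      list(mz = m[o, 1], intensity = m[o, 2])
    })
    ms1 <- ms1Map(hd$retentionTime[ms1idx], frames)
  }
  ms2 <- lapply(ms2idx, function(i) {
    m <- pk[[i]]
    z <- hd$precursorCharge[i]
    ms2Spectrum(
      scanId = if (!is.na(hd$spectrumId[i]) && nzchar(hd$spectrumId[i]))
        hd$spectrumId[i] else as.character(hd$acquisitionNum[i]),
      precursorMz = hd$precursorMZ[i],
      precursorCharge = if (is.na(z) || z < 1L) 1L else z,
      rt = hd$retentionTime[i],
      mz = m[, 1], intensity = m[, 2])
  })
  list(ms1 = ms1, ms2 = ms2)
}

.readMgf <- function(path) {
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS in ", path,
         call. = FALSE)
  lapply(seq_along(begins), function(k) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    hdr <- grep("=", block, fixed = TRUE, value = TRUE)
    keys <- sub("=.*", "", hdr)
    vals <- sub("^[^=]+=", "", hdr)
    names(vals) <- toupper(keys)
    pkLines <- block[!grepl("=", block, fixed = TRUE) & nzchar(block)]
    if (length(pkLines)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pkLines), "[ \t]+"),
                                 function(x) as.numeric(x[1:2])))
      if (anyNA(m))
        stop("malformed MGF peak line in scan block ", k, " of ", path,
             call. = FALSE)
    } else m <- matrix(numeric(0), ncol = 2)
    pepmass <- as.numeric(strsplit(vals[["PEPMASS"]], "[ \t]+")[[1]][1])
    charge <- if ("CHARGE" %in% names(vals))
      as.integer(sub("\\+$", "", vals[["CHARGE"]])) else 1L
    rt <- if ("RTINSECONDS" %in% names(vals))
      as.numeric(vals[["RTINSECONDS"]]) else NA_real_
    title <- if ("TITLE" %in% names(vals)) vals[["TITLE"]]
      else paste0("index=", k)
    ms2Spectrum(title, pepmass, charge, rt, m[, 1], m[, 2])
  })
}

#' Write MS2 spectra to an MGF file
#'
#' Writes `BEGIN IONS`/`END IONS` blocks with `TITLE` (the source scan
#' id), `PEPMASS`, `CHARGE` (canonical `N+` form) and `RTINSECONDS`.
#' Reading the file back reproduces peaks and precursor descriptors.
#'
#' @param spectra Non-empty list of [Ms2Spectrum-class] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMgf <- function(spectra, path) {
  if (!length(spectra)) stop("no spectra to write", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s@scanId),
      sprintf("PEPMASS=%.6f", s@precursorMz),
      sprintf("CHARGE=%d+", s@precursorCharge),
      if (!is.na(s@rt)) sprintf("RTINSECONDS=%.3f", s@rt),
      if (length(s@mz)) sprintf("%.6f %.6f", s@mz, s@intensity),
      "END IONS"), con)
  }
  invisible(path)
}

#' Write a run to mzML
#'
#' Serialises an MS1 map plus MS2 spectra to mzML (via the proteowizard
#' backend), interleaving frames and scans in retention-time order so
#' that each MS2 scan follows its nearest preceding MS1 frame.
#'
#' @param ms2 List of [Ms2Spectrum-class].
#' @param path Output path (`.mzML`).
#' @param ms1 Optional [Ms1Map-class].
#' @return Invisibly, `path`.
#' @export
writeMzml <- function(ms2, path, ms1 = NULL) {
  ents <- list()
  if (!is.null(ms1))
    for (i in seq_along(ms1@rt))
      ents[[length(ents) + 1L]] <- list(level = 1L, rt = ms1@rt[i],
                                        frame = i)
  for (i in seq_along(ms2))
    ents[[length(ents) + 1L]] <- list(level = 2L, rt = ms2[[i]]@rt,
                                      scan = i)
  if (!length(ents)) stop("nothing to write", call. = FALSE)
  o <- order(vapply(ents, `[[`, numeric(1), "rt"),
             vapply(ents, `[[`, integer(1), "level"))
  ents <- ents[o]
  n <- length(ents)
  pks <- vector("list", n)
  lastMs1 <- NA_integer_
  hd <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = integer(n), polarity = 1L, peaksCount = 0L,
    totIonCurrent = 0, retentionTime = 0, basePeakMZ = 0,
    basePeakIntensity = 0, collisionEnergy = NA_real_,
    ionisationEnergy = 0, lowMZ = 0, highMZ = 0,
    precursorScanNum = NA_integer_, precursorMZ = NA_real_,
    precursorCharge = NA_integer_, precursorIntensity = NA_real_,
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_,
    mergedResultEndScanNum = NA_integer_, injectionTime = 0,
    filterString = NA_character_, spectrumId = "", centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    e <- ents[[i]]
    if (e$level == 1L) {
      fr <- ms1@frames[[e$frame]]
      m <- cbind(mz = fr$mz, intensity = fr$intensity)
      lastMs1 <- i
      hd$spectrumId[i] <- sprintf("scan=%d", i)
    } else {
      s <- ms2[[e$scan]]
      m <- cbind(mz = s@mz, intensity = s@intensity)
      hd$precursorScanNum[i] <- lastMs1
      hd$precursorMZ[i] <- s@precursorMz
      hd$precursorCharge[i] <- s@precursorCharge
      hd$precursorIntensity[i] <- 0
      hd$collisionEnergy[i] <- 30
      hd$isolationWindowTargetMZ[i] <- s@precursorMz
      hd$isolationWindowLowerOffset[i] <- 1
      hd$isolationWindowUpperOffset[i] <- 1
      hd$spectrumId[i] <- s@scanId
    }
    if (!nrow(m)) m <- matrix(numeric(0), ncol = 2,
                              dimnames = list(NULL, c("mz", "intensity")))
    pks[[i]] <- m
    hd$msLevel[i] <- e$level
    hd$peaksCount[i] <- nrow(m)
    hd$retentionTime[i] <- e$rt
    hd$totIonCurrent[i] <- sum(m[, 2])
    hd$basePeakMZ[i] <- if (nrow(m)) m[which.max(m[, 2]), 1] else 0
    hd$basePeakIntensity[i] <- if (nrow(m)) max(m[, 2]) else 0
    hd$lowMZ[i] <- if (nrow(m)) min(m[, 1]) else 0
    hd$highMZ[i] <- if (nrow(m)) max(m[, 1]) else 0
  }
  mzR::writeMSData(pks, file = path, header = hd)
  invisible(path)
}
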