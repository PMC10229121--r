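#' Write / read a run in the internal JSON format
#'
#' The internal JSON run format is the package's primary exchange and
#' fixture format: exact (full-precision m/z and intensities), small, and
#' diffable. mzML export/import is available through [write_mzml()] /
#' [read_mzml()].
#'
#' @param run an `ms_run`.
#' @param path output file path.
#' @return `write_run_json` returns `path` invisibly; `read_run_json`
#'   returns an `ms_run`.
#' @export
write_run_json <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  x <- list(
    format = "h3tailquant-run",
    version = 1L,
    metadata = run$metadata,
    ground_truth = if (!is.null(run$ground_truth)) list(
      abundance = unname(run$ground_truth$abundance),
      pi = apply(unname(run$ground_truth$pi), 1, as.numeric,
                 simplify = FALSE)) else NULL,
    scans = lapply(run$scans, function(s) list(
      level = s$level, rt = s$rt, precursor_mz = s$precursor_mz,
      scan_range = s$scan_range, mz = s$mz, intensity = s$intensity)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_run_json
#' @export
read_run_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (!identical(x$format, "h3tailquant-run"))
    stop("not an internal run JSON file: ", path, call. = FALSE)
  gt <- NULL
  if (!is.null(x$ground_truth))
    gt <- mixture_spec(x$ground_truth$abundance,
                       do.call(rbind, x$ground_truth$pi))
  scans <- lapply(x$scans, function(s) list(
    level = as.integer(s$level), rt = as.numeric(s$rt),
    precursor_mz = if (is.null(s$precursor_mz)) NA_real_
                   else as.numeric(s$precursor_mz),
    scan_range = as.numeric(s$scan_range), mz = as.numeric(s$mz),
    intensity = as.numeric(s$intensity)))
  structure(list(scans = scans, metadata = x$metadata, ground_truth = gt),
            class = "ms_run")
}

#' Write / read a ground-truth sidecar
#'
#' YAML sidecar holding the mixture a synthetic run was generated from, for
#' benchmarking recovered stoichiometries against truth.
#'
#' @param mix a [mixture_spec].
#' @param path output file path.
#' @export
write_ground_truth <- function(mix, path) {
  stopifnot(inherits(mix, "mixture_spec"))
  yaml::write_yaml(list(abundance = as.numeric(mix$abundance),
                        pi = apply(unname(mix$pi), 1, as.numeric,
                                   simplify = FALSE)),
                   path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- yaml::read_yaml(path)
  mixture_spec(x$abundance, do.call(rbind, lapply(x$pi, as.numeric)))
}

#' Write a stoichiometry table as tidy CSV
#'
#' Columns: condition, time_min, acetyl_degree, me_state, mean_pct, sem, n.
#'
#' @param st a `stoich_table` (from [aggregate_replicates()]).
#' @param path output file path.
#' @export
write_stoich_csv <- function(st, path) {
  stopifnot(inherits(st, "stoich_table"))
  utils::write.csv(st$table, path, row.names = FALSE)
  invisible(path)
}

#' Export / import a run as mzML
#'
#' Centroided spectra via the mzR backend. Retention times are stored in
#' seconds in mzML and converted back to minutes on import.
#'
#' @param run an `ms_run`.
#' @param path mzML file path.
#' @export
write_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("the mzR package is required for mzML export", call. = FALSE)
  stopifnot(inherits(run, "ms_run"))
  n <- length(run$scans)
  pk <- lapply(run$scans, function(s) cbind(mz = s$mz,
                                            intensity = s$intensity))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(run$scans, `[[`, 0L, "level"),
    polarity = 1L,
    peaksCount = vapply(pk, nrow, 0L),
    totIonCurrent = vapply(run$scans, function(s) sum(s$intensity), 0),
    retentionTime = vapply(run$scans, `[[`, 0, "rt") * 60,
    basePeakMZ = vapply(run$scans, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, 0),
    basePeakIntensity = vapply(run$scans, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, 0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$scans, function(s) s$scan_range[1], 0),
    highMZ = vapply(run$scans, function(s) s$scan_range[2], 0),
    precursorScanNum = 0L,
    precursorMZ = vapply(run$scans, function(s)
      ifelse(is.na(s$precursor_mz), 0, s$precursor_mz), 0),
    precursorCharge = ifelse(
      vapply(run$scans, `[[`, 0L, "level") == 2L, 9L, 0L),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = vapply(run$scans, function(s)
      ifelse(is.na(s$precursor_mz), NA_real_, s$precursor_mz), 0),
    isolationWindowLowerOffset = 1.5, isolationWindowUpperOffset = 1.5,
    scanWindowLowerLimit = vapply(run$scans, function(s) s$scan_range[1], 0),
    scanWindowUpperLimit = vapply(run$scans, function(s) s$scan_range[2], 0)
  )
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' @rdname write_mzml
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("the mzR package is required for mzML import", call. = FALSE)
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- lapply(seq_len(nrow(h)), function(i) {
    lvl <- as.integer(h$msLevel[i])
    list(level = lvl, rt = h$retentionTime[i] / 60,
         precursor_mz = if (lvl == 2L && h$precursorMZ[i] > 0)
           h$precursorMZ[i] else NA_real_,
         scan_range = c(h$scanWindowLowerLimit[i],
                        h$scanWindowUpperLimit[i]),
         mz = pk[[i]][, 1], intensity = pk[[i]][, 2])
  })
  structure(list(scans = scans, metadata = list(source = path),
                 ground_truth = NULL), class = "ms_run")
}
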