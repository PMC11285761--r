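## On-disk formats: multi-page 32-bit TIFF rasters with a JSON sidecar
## (geometry / positions / angles / ground truth), YAML for geometry
## and run configuration, CSV for metric tables.
##
## TIFF pages hold codes (v + 1) / denom in [0, 1] at 32-bit depth,
## with denom = max(v) + 1 recorded in the sidecar; the masked-pixel
## sentinel -1 maps to code 0. Integer count data round-trip exactly
## (the reader re-rounds when the sidecar flags integer data); float
## data round-trip to ~1e-10 relative.

TIFF_SENTINEL <- -1

encodePage <- function(m) {
    v <- m
    v[!is.finite(v)] <- TIFF_SENTINEL
    vmax <- max(v, 0)
    denom <- vmax + 1
    list(code = (v + 1) / denom, denom = denom,
         integer_data = all(v == round(v)))
}

decodePage <- function(code, denom, integer_data) {
    x <- code * denom - 1
    if (isTRUE(integer_data)) x <- round(x)
    x[x <= -0.5] <- NA_real_
    x
}

writePages <- function(pages, path) {
    pages <- lapply(pages, function(p) {
        storage.mode(p) <- "double"
        p
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    compression = "deflate", reduce = FALSE)
}

readPages <- function(path) {
    pg <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pg)) pg <- list(pg)
    pg
}

geometryToList <- function(geometry) {
    list(sample_detector_distance_mm = geometry@sampleDetectorDistance,
         wavelength_nm = geometry@wavelength,
         pixel_pitch_um = geometry@pixelPitch,
         beam_center_xy = geometry@beamCenter,
         detector_shape = geometry@detectorShape,
         beamstop_radius_px = geometry@beamstopRadius)
}

geometryFromList <- function(x) {
    need <- c("sample_detector_distance_mm", "wavelength_nm",
              "pixel_pitch_um", "beam_center_xy", "detector_shape",
              "beamstop_radius_px")
    miss <- setdiff(need, names(x))
    if (length(miss))
        stop("geometry block is missing fields: ",
             paste(miss, collapse = ", "))
    detectorGeometry(
        sampleDetectorDistance = x$sample_detector_distance_mm,
        wavelength = x$wavelength_nm,
        pixelPitch = x$pixel_pitch_um,
        detectorShape = unlist(x$detector_shape),
        beamCenter = unlist(x$beam_center_xy),
        beamstopRadius = x$beamstop_radius_px)
}

#' Read or write a detector geometry as YAML
#'
#' @param geometry a [DetectorGeometry-class].
#' @param path file path.
#' @return `readGeometry` returns a [DetectorGeometry-class];
#'   `writeGeometry` returns `path` invisibly.
#' @export
writeGeometry <- function(geometry, path) {
    stopifnot(is(geometry, "DetectorGeometry"))
    yaml::write_yaml(geometryToList(geometry), path)
    invisible(path)
}

#' @rdname writeGeometry
#' @export
readGeometry <- function(path) {
    geometryFromList(yaml::read_yaml(path))
}

#' Write a scatter map as multi-page TIFF plus JSON sidecar
#'
#' @param map a [ScatterMap-class].
#' @param path TIFF path; the sidecar defaults to the same path with a
#'   `.json` extension.
#' @param sidecar JSON sidecar path.
#' @param groundTruth optional named list (e.g. per-region scene
#'   parameters) embedded verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
writeScatterMap <- function(map, path,
                            sidecar = sidecarPath(path),
                            groundTruth = NULL) {
    stopifnot(is(map, "ScatterMap"))
    enc <- lapply(map@patterns, encodePage)
    writePages(lapply(enc, `[[`, "code"), path)
    meta <- list(
        format = "collagenHier scatter_map v1",
        masked_sentinel = TIFF_SENTINEL,
        geometry = geometryToList(map@geometry),
        positions = map@positions,
        page_denominators = vapply(enc, `[[`, numeric(1), "denom"),
        page_integer_data = vapply(enc, `[[`, logical(1),
                                   "integer_data"))
    if (!is.null(groundTruth)) meta$ground_truth <- groundTruth
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    invisible(path)
}

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path),
                                     ".json")

#' Read a scatter map written by [writeScatterMap()]
#'
#' @param path TIFF path.
#' @param sidecar JSON sidecar path.
#' @return A [ScatterMap-class].
#' @export
readScatterMap <- function(path, sidecar = sidecarPath(path)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pg <- readPages(path)
    np <- length(pg)
    if (np != length(meta$page_denominators))
        stop(sprintf("TIFF has %d pages but the sidecar describes %d",
                     np, length(meta$page_denominators)))
    pats <- lapply(seq_len(np), function(i)
        decodePage(pg[[i]], meta$page_denominators[i],
                   meta$page_integer_data[i]))
    pos <- as.data.frame(meta$positions)
    methods::new("ScatterMap", patterns = pats, positions = pos,
                 geometry = geometryFromList(meta$geometry))
}

#' Write a pSHG stack as multi-page TIFF plus JSON sidecar
#'
#' @param stack a [PSHGStack-class].
#' @param path TIFF path.
#' @param sidecar JSON sidecar path.
#' @param groundTruth optional named list embedded in the sidecar.
#' @return `path`, invisibly.
#' @export
writePSHGStack <- function(stack, path, sidecar = sidecarPath(path),
                           groundTruth = NULL) {
    stopifnot(is(stack, "PSHGStack"))
    d <- dim(stack@intensities)
    enc <- lapply(seq_len(d[3]), function(k)
        encodePage(stack@intensities[, , k]))
    writePages(lapply(enc, `[[`, "code"), path)
    meta <- list(
        format = "collagenHier pshg_stack v1",
        masked_sentinel = TIFF_SENTINEL,
        polarization_angles_deg = stack@angles,
        pixel_size_um = stack@pixelSize,
        page_denominators = vapply(enc, `[[`, numeric(1), "denom"),
        page_integer_data = vapply(enc, `[[`, logical(1),
                                   "integer_data"))
    if (!is.null(groundTruth)) meta$ground_truth <- groundTruth
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a pSHG stack written by [writePSHGStack()]
#'
#' @param path TIFF path.
#' @param sidecar JSON sidecar path.
#' @return A [PSHGStack-class].
#' @export
readPSHGStack <- function(path, sidecar = sidecarPath(path)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    ang <- as.numeric(meta$polarization_angles_deg)
    pg <- readPages(path)
    if (length(pg) != length(ang))
        stop(sprintf("stack has %d pages but the sidecar lists %d angles",
                     length(pg), length(ang)))
    d <- dim(pg[[1]])
    arr <- array(NA_real_, c(d[1], d[2], length(pg)))
    for (k in seq_along(pg))
        arr[, , k] <- decodePage(pg[[k]], meta$page_denominators[k],
                                 meta$page_integer_data[k])
    methods::new("PSHGStack", intensities = arr, angles = ang,
                 pixelSize = meta$pixel_size_um %||% DEFAULT_PSHG_PIXEL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metrics table as CSV
#'
#' @param metrics a DataFrame/data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeMetricsCSV <- function(metrics, path) {
    utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
    invisible(path)
}
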