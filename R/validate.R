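.REQUIRED_TAGS <- c("SubjectID", "MeasurementDate", "MeasurementTime",
                    "LengthUnit", "TimeUnit", "FrequencyUnit")

.KNOWN_DATA_TYPES <- c(1L, 99999L)  # raw CW amplitude; processed (labelled)

.finding <- function(code, severity, location, message, specRef) {
    new("Finding", code = code, severity = severity, location = location,
        message = message, specRef = specRef)
}

#' The registry of validation finding codes
#'
#' Closed registry of every code a [validateSnirf()] report can carry, with
#' the severity it is issued at and the section of the format specification
#' it enforces. Severity grading: violations of the specification are
#' `ERROR`; interoperability risks (such as a data-type code outside the
#' registry, which the format reserves room for) are `WARNING`; preserved
#' unrecognised content is `INFO`; only an unreadable container is `FATAL`.
#'
#' @return A data frame with columns `code`, `severity`, `specRef`,
#'   `description`.
#' @export
findingCodes <- function() {
    read.table(text = '
NOT_HDF5                FATAL   hdf5            "target is not a readable HDF5 container"
VERSION_MISSING         ERROR   formatversion   "root dataset formatVersion is absent or empty"
VERSION_UNPARSEABLE     ERROR   formatversion   "formatVersion is not a MAJOR.MINOR[.PATCH] semantic version"
NIRS_MISSING            ERROR   required-data   "file contains no nirs recording element"
DATA_MISSING            ERROR   required-data   "recording element has no data block"
PROBE_MISSING           ERROR   required-data   "recording element has no probe description"
NO_CHANNELS             ERROR   required-data   "data block holds no channels"
METADATA_MISSING        ERROR   metadata-tags   "a required metadata tag is missing or empty"
LIST_LENGTH_MISMATCH    ERROR   measurement-list "measurement-list length differs from the channel count"
INDEX_OUT_OF_RANGE      ERROR   measurement-list "a measurement-list index exceeds the probe arrays"
DATA_TYPE_LABEL_MISSING ERROR   measurement-list "dataType 99999 (processed) lacks dataTypeLabel"
UNKNOWN_DATA_TYPE       WARNING measurement-list "dataType code outside the registry known here"
TIME_LENGTH_MISMATCH    ERROR   data            "explicit time axis length differs from the sample count"
TIME_NOT_INCREASING     ERROR   data            "time axis is not strictly increasing"
NONCONTIGUOUS_INDEX     ERROR   indexed-groups  "indexed collection is not numbered 1..N without gaps"
BAD_INDEX_NAME          ERROR   indexed-groups  "zero-padded index or bare/indexed naming collision"
PROBE_DIM_MISMATCH      ERROR   probe           "a probe position array has the wrong shape"
POSITIONS_MISSING       ERROR   probe           "probe lacks source or detector positions entirely"
WAVELENGTHS_INVALID     ERROR   probe           "probe wavelengths are absent or not strictly positive"
UNRECOGNIZED_CONTENT    INFO    general         "content not defined by the format (preserved)"
', col.names = c("code", "severity", "specRef", "description"),
        stringsAsFactors = FALSE)
}

.validateProbe <- function(pr, p) {
    fnd <- list()
    add <- function(code, loc, msg, ref)
        fnd[[length(fnd) + 1L]] <<- .finding(code, "ERROR", loc, msg, ref)
    if (!length(pr@wavelengths) || any(!is.finite(pr@wavelengths)) ||
        any(pr@wavelengths <= 0))
        add("WAVELENGTHS_INVALID", .joinPath(p, "probe/wavelengths"),
            "wavelengths must be a non-empty, strictly positive array (nm)",
            "probe")
    if (is.na(.nSources(pr)))
        add("POSITIONS_MISSING", .joinPath(p, "probe"),
            "neither sourcePos2D nor sourcePos3D is present", "probe")
    if (is.na(.nDetectors(pr)))
        add("POSITIONS_MISSING", .joinPath(p, "probe"),
            "neither detectorPos2D nor detectorPos3D is present", "probe")
    dims <- c(sourcePos2D = 2L, sourcePos3D = 3L,
              detectorPos2D = 2L, detectorPos3D = 3L)
    for (nm in names(dims)) {
        m <- slot(pr, nm)
        if (!is.null(m) && ncol(m) != dims[[nm]])
            add("PROBE_DIM_MISMATCH", .joinPath(p, paste0("probe/", nm)),
                sprintf("%s has %d column(s); expected %d", nm, ncol(m), dims[[nm]]),
                "probe")
    }
    if (!is.null(pr@sourcePos2D) && !is.null(pr@sourcePos3D) &&
        nrow(pr@sourcePos2D) != nrow(pr@sourcePos3D))
        add("PROBE_DIM_MISMATCH", .joinPath(p, "probe"),
            sprintf("sourcePos2D (%d rows) and sourcePos3D (%d rows) disagree on the number of sources",
                    nrow(pr@sourcePos2D), nrow(pr@sourcePos3D)), "probe")
    if (!is.null(pr@detectorPos2D) && !is.null(pr@detectorPos3D) &&
        nrow(pr@detectorPos2D) != nrow(pr@detectorPos3D))
        add("PROBE_DIM_MISMATCH", .joinPath(p, "probe"),
            sprintf("detectorPos2D (%d rows) and detectorPos3D (%d rows) disagree on the number of detectors",
                    nrow(pr@detectorPos2D), nrow(pr@detectorPos3D)), "probe")
    fnd
}

.validateTimeAxis <- function(time, nRows, loc) {
    tl <- length(time)
    if (tl == nRows) {
        if (nRows > 1L && any(diff(time) <= 0))
            return(list(.finding("TIME_NOT_INCREASING", "ERROR", loc,
                                 "explicit time axis must be strictly increasing",
                                 "data")))
        return(list())
    }
    if (tl == 2L) {
        if (time[2L] <= 0)
            return(list(.finding("TIME_NOT_INCREASING", "ERROR", loc,
                                 "implicit [start, increment] axis requires a positive increment",
                                 "data")))
        return(list())
    }
    list(.finding("TIME_LENGTH_MISMATCH", "ERROR", loc,
                  sprintf("time axis has length %d; expected %d (explicit) or 2 (implicit)",
                          tl, nRows), "data"))
}

.validateBlock <- function(block, pr, q) {
    fnd <- list()
    nc <- ncol(block@dataTimeSeries)
    nml <- length(block@measurementList)
    if (nc == 0L && nml == 0L)
        fnd[[length(fnd) + 1L]] <- .finding(
            "NO_CHANNELS", "ERROR", q,
            "data block holds no channels; a file must contain at least one series of raw data",
            "required-data")
    else if (nc != nml)
        fnd[[length(fnd) + 1L]] <- .finding(
            "LIST_LENGTH_MISMATCH", "ERROR", q,
            sprintf("dataTimeSeries has %d column(s) but measurementList has %d element(s)",
                    nc, nml), "measurement-list")
    fnd <- c(fnd, .validateTimeAxis(block@time, nrow(block@dataTimeSeries),
                                    .joinPath(q, "time")))
    nS <- if (is.null(pr)) NA_integer_ else .nSources(pr)
    nD <- if (is.null(pr)) NA_integer_ else .nDetectors(pr)
    nW <- if (is.null(pr)) NA_integer_ else length(pr@wavelengths)
    for (k in seq_along(block@measurementList)) {
        ml <- block@measurementList[[k]]
        r <- .joinPath(q, renderIndexedName("measurementList", k))
        chk <- function(idx, n, field) {
            if (!is.na(n) && !is.na(idx) && (idx < 1L || idx > n))
                fnd[[length(fnd) + 1L]] <<- .finding(
                    "INDEX_OUT_OF_RANGE", "ERROR", .joinPath(r, field),
                    sprintf("%s = %d is outside 1..%d", field, idx, n),
                    "measurement-list")
        }
        chk(ml@sourceIndex, nS, "sourceIndex")
        chk(ml@detectorIndex, nD, "detectorIndex")
        chk(ml@wavelengthIndex, nW, "wavelengthIndex")
        if (!is.na(ml@dataType) && !(ml@dataType %in% .KNOWN_DATA_TYPES))
            fnd[[length(fnd) + 1L]] <- .finding(
                "UNKNOWN_DATA_TYPE", "WARNING", .joinPath(r, "dataType"),
                sprintf("dataType %d is not in the registry known here; accepted but not interpretable",
                        ml@dataType), "measurement-list")
        if (!is.na(ml@dataType) && ml@dataType == 99999L &&
            is.null(ml@dataTypeLabel))
            fnd[[length(fnd) + 1L]] <- .finding(
                "DATA_TYPE_LABEL_MISSING", "ERROR",
                .joinPath(r, "dataTypeLabel"),
                "dataType 99999 (processed) requires a dataTypeLabel",
                "measurement-list")
    }
    fnd
}

.validateModel <- function(model, nirsNames = NULL) {
    fnd <- list()
    fv <- model@formatVersion
    if (!length(fv) || is.na(fv) || !nzchar(fv))
        fnd[[length(fnd) + 1L]] <- .finding(
            "VERSION_MISSING", "ERROR", "/formatVersion",
            "formatVersion is absent or empty", "formatversion")
    else if (!grepl("^[0-9]+\\.[0-9]+(\\.[0-9]+)?$", fv))
        fnd[[length(fnd) + 1L]] <- .finding(
            "VERSION_UNPARSEABLE", "ERROR", "/formatVersion",
            sprintf("'%s' is not a MAJOR.MINOR[.PATCH] semantic version", fv),
            "formatversion")
    if (!length(model@nirs))
        fnd[[length(fnd) + 1L]] <- .finding(
            "NIRS_MISSING", "ERROR", "/",
            "file contains no nirs recording element", "required-data")
    if (is.null(nirsNames))
        nirsNames <- vapply(seq_along(model@nirs), function(i)
            renderIndexedName("nirs", i), character(1))
    for (i in seq_along(model@nirs)) {
        el <- model@nirs[[i]]
        p <- paste0("/", nirsNames[i])
        for (tag in .REQUIRED_TAGS) {
            v <- el@metadata@tags[[tag]]
            if (is.null(v) || !length(v) || is.na(v[1L]) || !nzchar(as.character(v[1L])))
                fnd[[length(fnd) + 1L]] <- .finding(
                    "METADATA_MISSING", "ERROR", .joinPath(p, "metaDataTags"),
                    sprintf("required metadata tag '%s' is missing or empty", tag),
                    "metadata-tags")
        }
        if (is.null(el@probe))
            fnd[[length(fnd) + 1L]] <- .finding(
                "PROBE_MISSING", "ERROR", .joinPath(p, "probe"),
                "recording element has no probe description", "required-data")
        else
            fnd <- c(fnd, .validateProbe(el@probe, p))
        if (!length(el@data))
            fnd[[length(fnd) + 1L]] <- .finding(
                "DATA_MISSING", "ERROR", p,
                "recording element has no data block; at least one series of raw data is required",
                "required-data")
        for (j in seq_along(el@data))
            fnd <- c(fnd, .validateBlock(el@data[[j]], el@probe,
                                         .joinPath(p, renderIndexedName("data", j))))
        for (j in seq_along(el@aux)) {
            ax <- el@aux[[j]]
            fnd <- c(fnd, .validateTimeAxis(
                ax@time, nrow(ax@dataTimeSeries),
                .joinPath(p, paste0(renderIndexedName("aux", j), "/time"))))
        }
    }
    fnd
}

.orderFindings <- function(fnd) {
    if (!length(fnd)) return(fnd)
    loc <- vapply(fnd, function(f) f@location, character(1))
    code <- vapply(fnd, function(f) f@code, character(1))
    fnd[order(loc, code, method = "radix")]
}

#' Validate a SNIRF file or model against the format rules
#'
#' Runs the full rule battery: minimum content (at least one recording
#' element with a data block and a probe), required metadata tags,
#' measurement-list length versus channel count, probe index bounds,
#' time-axis length and monotonicity, probe array shapes, indexed-group
#' contiguity and naming, formatVersion parseability, and data-type registry
#' membership. Findings are ordered deterministically by location then code,
#' so identical input always yields an identical report.
#'
#' When `target` is a path, the file is read permissively: structural damage
#' becomes findings rather than errors, and an unreadable container yields a
#' single `FATAL` finding. Naming and contiguity rules can only be checked on
#' files, since in-memory collections are contiguous by construction.
#'
#' @param target A file path or a [SnirfFile-class] model.
#' @return A [ValidationReport-class]; see [findings()] and
#'   [isValidReport()].
#' @examples
#' validateSnirf(makeWorkedExample())
#' @export
validateSnirf <- function(target) {
    if (is(target, "SnirfFile")) {
        fnd <- .validateModel(target)
    } else if (is.character(target) && length(target) == 1L) {
        res <- .readSnirfPermissive(target)
        fnd <- res$findings
        if (!is.null(res$model)) {
            nm <- res$nirsNames
            if (length(nm) != length(res$model@nirs))
                nm <- NULL
            fnd <- c(fnd, .validateModel(res$model, nirsNames = nm))
        }
        # reader and model rules both flag a missing formatVersion; keep one
        isVM <- vapply(fnd, function(f) f@code == "VERSION_MISSING", logical(1))
        if (sum(isVM) > 1L) fnd <- fnd[!(isVM & cumsum(isVM) > 1L)]
    } else {
        stop("target must be a file path or a SnirfFile", call. = FALSE)
    }
    # deduplicate findings that both the reader and the model rules raise
    key <- vapply(fnd, function(f) paste(f@code, f@location, f@message,
                                         sep = "\r"), character(1))
    fnd <- fnd[!duplicated(key)]
    new("ValidationReport", findings = .orderFindings(fnd))
}
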