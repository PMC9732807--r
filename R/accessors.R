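#' Accessors for SNIRF model objects
#'
#' Small accessor family in place of direct slot access: `formatVersion()`,
#' `nirsElements()`, `metaDataTags()`, `probe()`, `dataBlocks()`,
#' `stimElements()`, `auxElements()`, `dataTimeSeries()`, `timeAxis()`,
#' `measurementList()` and `wavelengths()`.
#'
#' @param x A model object.
#' @param value Replacement value.
#' @return The stored component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("formatVersion", "SnirfFile", function(x) x@formatVersion)

#' @rdname accessors
setMethod("formatVersion<-", "SnirfFile", function(x, value) {
    x@formatVersion <- as.character(value)
    validObject(x)
    x
})

#' @rdname accessors
setMethod("nirsElements", "SnirfFile", function(x) x@nirs)

#' @rdname accessors
setMethod("metaDataTags", "NirsElement", function(x) x@metadata@tags)

#' @rdname accessors
setMethod("probe", "NirsElement", function(x) x@probe)

#' @rdname accessors
setMethod("dataBlocks", "NirsElement", function(x) x@data)

#' @rdname accessors
setMethod("stimElements", "NirsElement", function(x) x@stim)

#' @rdname accessors
setMethod("auxElements", "NirsElement", function(x) x@aux)

#' @rdname accessors
setMethod("dataTimeSeries", "DataBlock", function(x) x@dataTimeSeries)

#' @rdname accessors
setMethod("dataTimeSeries", "AuxElement", function(x) x@dataTimeSeries)

#' @rdname accessors
setMethod("timeAxis", "DataBlock", function(x) x@time)

#' @rdname accessors
setMethod("timeAxis", "AuxElement", function(x) x@time)

#' @rdname accessors
setMethod("measurementList", "DataBlock", function(x) x@measurementList)

#' @rdname accessors
setMethod("wavelengths", "Probe", function(x) x@wavelengths)

#' @rdname accessors
setMethod("wavelengths", "NirsElement", function(x) {
    if (is.null(x@probe)) numeric(0) else x@probe@wavelengths
})

# number of sources/detectors implied by whichever position arrays exist
.nSources <- function(probe) {
    if (!is.null(probe@sourcePos3D)) nrow(probe@sourcePos3D)
    else if (!is.null(probe@sourcePos2D)) nrow(probe@sourcePos2D)
    else NA_integer_
}

.nDetectors <- function(probe) {
    if (!is.null(probe@detectorPos3D)) nrow(probe@detectorPos3D)
    else if (!is.null(probe@detectorPos2D)) nrow(probe@detectorPos2D)
    else NA_integer_
}

#' Report accessors
#'
#' `findings()` returns the findings of a [ValidationReport-class] as a
#' data frame (columns `code`, `severity`, `location`, `message`, `specRef`);
#' `isValidReport()` is `TRUE` iff no finding has severity `FATAL` or `ERROR`.
#'
#' @param x A [ValidationReport-class].
#' @return A data frame, or a logical scalar.
#' @name findings
NULL

#' @rdname findings
setMethod("findings", "ValidationReport", function(x) {
    if (!length(x@findings))
        return(data.frame(code = character(0), severity = character(0),
                          location = character(0), message = character(0),
                          specRef = character(0), stringsAsFactors = FALSE))
    do.call(rbind, lapply(x@findings, function(f)
        data.frame(code = f@code, severity = f@severity, location = f@location,
                   message = f@message, specRef = f@specRef,
                   stringsAsFactors = FALSE)))
})

#' @rdname findings
setMethod("isValidReport", "ValidationReport", function(x) {
    !any(vapply(x@findings, function(f)
        f@severity %in% c("FATAL", "ERROR"), logical(1)))
})

setMethod("show", "SnirfFile", function(object) {
    cat(sprintf("SnirfFile (formatVersion %s) with %d recording element(s)\n",
                object@formatVersion, length(object@nirs)))
    for (i in seq_along(object@nirs)) {
        el <- object@nirs[[i]]
        subj <- el@metadata@tags[["SubjectID"]]
        cat(sprintf("  nirs%d: subject %s, %d data block(s), %d stim, %d aux\n",
                    i, if (is.null(subj)) "<unset>" else subj,
                    length(el@data), length(el@stim), length(el@aux)))
    }
    invisible(object)
})

setMethod("show", "NirsElement", function(object) {
    cat(sprintf("NirsElement: %d data block(s), %d stim, %d aux, probe %s\n",
                length(object@data), length(object@stim), length(object@aux),
                if (is.null(object@probe)) "absent" else "present"))
    invisible(object)
})

setMethod("show", "DataBlock", function(object) {
    cat(sprintf("DataBlock: %d time points x %d channels, %s time axis\n",
                nrow(object@dataTimeSeries), ncol(object@dataTimeSeries),
                if (length(object@time) == nrow(object@dataTimeSeries))
                    "explicit" else "implicit [start, increment]"))
    invisible(object)
})

setMethod("show", "Probe", function(object) {
    cat(sprintf("Probe: %s source(s), %s detector(s), wavelengths [%s] nm\n",
                .nSources(object), .nDetectors(object),
                paste(object@wavelengths, collapse = ", ")))
    invisible(object)
})

setMethod("show", "ChannelDescription", function(object) {
    cat(sprintf(
        "Channel %d: source [%s] -> detector [%s], %g nm, dataType %d\n",
        object@columnIndex,
        paste(object@sourcePosition, collapse = ", "),
        paste(object@detectorPosition, collapse = ", "),
        object@wavelength, object@dataType))
    invisible(object)
})

setMethod("show", "ValidationReport", function(object) {
    df <- findings(object)
    cat(sprintf("ValidationReport: %s (%d finding(s))\n",
                if (isValidReport(object)) "VALID" else "INVALID", nrow(df)))
    if (nrow(df))
        for (i in seq_len(nrow(df)))
            cat(sprintf("  [%s] %s at %s: %s\n", df$severity[i], df$code[i],
                        df$location[i], df$message[i]))
    invisible(object)
})

setMethod("show", "SnirfGenSpec", function(object) {
    cat(sprintf(paste0("SnirfGenSpec: %d source(s) x %d detector(s), ",
                       "%d wavelength(s), %d block(s) @ [%s] Hz, ",
                       "%g s, %d stim, %d aux, seed %d\n"),
                object@nSources, object@nDetectors, length(object@wavelengths),
                object@nBlocks, paste(object@samplingRateHz, collapse = ", "),
                object@durationS, object@nStim, object@nAux, object@seed))
    invisible(object)
})
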