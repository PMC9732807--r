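#' Expand a SNIRF time axis to explicit sample times
#'
#' SNIRF stores a block's time axis either explicitly (one value per sample)
#' or implicitly as `c(start, increment)`, the compact encoding for uniformly
#' sampled signals. This helper normalises both forms to an explicit vector.
#' A length-2 axis is taken as explicit when the block has exactly two rows
#' (the length matches), implicit otherwise.
#'
#' @param time Numeric vector: explicit sample times or `c(start, increment)`.
#' @param nRows Number of samples (rows of `dataTimeSeries`).
#' @return Numeric vector of `nRows` strictly increasing sample times.
#' @examples
#' expandTime(c(0, 0.1), 5)        # 0.0 0.1 0.2 0.3 0.4
#' expandTime(c(0, 0.05, 0.2), 3)  # returned unchanged
#' @export
expandTime <- function(time, nRows) {
    time <- as.numeric(time)
    nRows <- as.integer(nRows)
    if (length(time) == nRows) {
        if (nRows > 1L && any(diff(time) <= 0))
            stop("explicit time axis must be strictly increasing", call. = FALSE)
        return(time)
    }
    if (length(time) == 2L) {
        if (time[2L] <= 0)
            stop("implicit time axis requires a positive increment", call. = FALSE)
        return(time[1L] + (seq_len(nRows) - 1L) * time[2L])
    }
    stop(sprintf(
        "time axis has length %d; expected %d (explicit) or 2 (implicit [start, increment])",
        length(time), nRows), call. = FALSE)
}

#' Number of channels in a data block
#'
#' The channel count is the number of columns of `dataTimeSeries`; a
#' compliant block carries exactly one measurement-list element per column.
#'
#' @param block A [DataBlock-class].
#' @param strict Raise an error when the measurement-list length disagrees
#'   with the column count (the validator reports the same condition as a
#'   `LIST_LENGTH_MISMATCH` finding instead of erroring).
#' @return Integer channel count.
#' @export
channelCount <- function(block, strict = TRUE) {
    stopifnot(is(block, "DataBlock"))
    nc <- ncol(block@dataTimeSeries)
    if (strict && nc != length(block@measurementList))
        stop(sprintf(
            "dataTimeSeries has %d column(s) but measurementList has %d element(s)",
            nc, length(block@measurementList)), call. = FALSE)
    nc
}

.checkMlBounds <- function(ml, pr, where) {
    nS <- .nSources(pr); nD <- .nDetectors(pr); nW <- length(pr@wavelengths)
    if (!is.na(nS) && (ml@sourceIndex < 1L || ml@sourceIndex > nS))
        stop(sprintf("%s/sourceIndex = %d is outside the probe's %d source position(s)",
                     where, ml@sourceIndex, nS), call. = FALSE)
    if (!is.na(nD) && (ml@detectorIndex < 1L || ml@detectorIndex > nD))
        stop(sprintf("%s/detectorIndex = %d is outside the probe's %d detector position(s)",
                     where, ml@detectorIndex, nD), call. = FALSE)
    if (ml@wavelengthIndex < 1L || ml@wavelengthIndex > nW)
        stop(sprintf("%s/wavelengthIndex = %d is outside the probe's %d wavelength(s)",
                     where, ml@wavelengthIndex, nW), call. = FALSE)
    invisible(TRUE)
}

#' Resolve a channel through the probe
#'
#' Follows the measurement-list entry of one column of `dataTimeSeries`
#' through the probe arrays: the 1-based `sourceIndex`, `detectorIndex` and
#' `wavelengthIndex` stored in the entry are looked up in the probe's
#' position matrices and wavelength vector, yielding actual optode
#' coordinates and the nominal wavelength of the channel. When a probe stores
#' both 2-D and 3-D coordinates, the 3-D ones are returned.
#'
#' @param element A [NirsElement-class].
#' @param blockIndex 1-based data-block index.
#' @param channelIndex 1-based channel (column) index within the block.
#' @return A [ChannelDescription-class].
#' @examples
#' el <- nirsElements(makeWorkedExample())[[1]]
#' resolveChannel(el, 1, 2)  # source at [42, -125, 42], 830 nm
#' @export
resolveChannel <- function(element, blockIndex, channelIndex) {
    stopifnot(is(element, "NirsElement"))
    blockIndex <- as.integer(blockIndex)
    channelIndex <- as.integer(channelIndex)
    if (blockIndex < 1L || blockIndex > length(element@data))
        stop(sprintf("block index %d out of range at /nirs/data%d (file has %d block(s))",
                     blockIndex, blockIndex, length(element@data)), call. = FALSE)
    block <- element@data[[blockIndex]]
    if (channelIndex < 1L || channelIndex > length(block@measurementList))
        stop(sprintf(
            "channel index %d out of range at /nirs/data%d/measurementList%d (block has %d channel(s))",
            channelIndex, blockIndex, channelIndex,
            length(block@measurementList)), call. = FALSE)
    pr <- element@probe
    if (is.null(pr))
        stop("element has no probe; channels cannot be resolved", call. = FALSE)
    ml <- block@measurementList[[channelIndex]]
    where <- sprintf("/nirs/data%d/measurementList%d", blockIndex, channelIndex)
    .checkMlBounds(ml, pr, where)
    srcPos <- if (!is.null(pr@sourcePos3D)) pr@sourcePos3D[ml@sourceIndex, ]
              else pr@sourcePos2D[ml@sourceIndex, ]
    detPos <- if (!is.null(pr@detectorPos3D)) pr@detectorPos3D[ml@detectorIndex, ]
              else pr@detectorPos2D[ml@detectorIndex, ]
    new("ChannelDescription",
        sourcePosition   = as.numeric(srcPos),
        detectorPosition = as.numeric(detPos),
        wavelength       = pr@wavelengths[ml@wavelengthIndex],
        dataType         = ml@dataType,
        columnIndex      = channelIndex)
}

#' Test two SNIRF models for deep equality
#'
#' Recursive slot-by-slot comparison with exact numeric equality, used to
#' assert lossless round trips through the HDF5 container (including
#' preserved unknown tags and datasets).
#'
#' @param a,b Objects to compare (models or any of their components).
#' @return `TRUE` or `FALSE`.
#' @export
snirfIdentical <- function(a, b) {
    if (isVirtualClass(class(a)) || !identical(class(a)[[1L]], class(b)[[1L]]))
        return(FALSE)
    if (isS4(a)) {
        for (nm in slotNames(class(a)))
            if (!snirfIdentical(slot(a, nm), slot(b, nm))) return(FALSE)
        return(TRUE)
    }
    if (is.list(a)) {
        if (length(a) != length(b)) return(FALSE)
        # named lists are mappings (metadata tags, preservation areas):
        # compare by key, not storage order, which HDF5 does not preserve
        if (!is.null(names(a)) && all(nzchar(names(a))) &&
            !anyDuplicated(names(a))) {
            if (!setequal(names(a), names(b)) || anyDuplicated(names(b)))
                return(FALSE)
            a <- a[sort(names(a))]
            b <- b[sort(names(b))]
        } else if (!identical(names(a), names(b))) {
            return(FALSE)
        }
        for (i in seq_along(a))
            if (!snirfIdentical(a[[i]], b[[i]])) return(FALSE)
        return(TRUE)
    }
    identical(a, b)
}
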