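# Writer for the SNIRF HDF5 container.
#
# Storage conventions: floating-point datasets are 64-bit, index fields are
# native signed integers, strings are variable-length UTF-8. 2-D matrices are
# transposed before handing them to rhdf5 so that C-order tools (h5py,
# MATLAB) see the on-file dataTimeSeries as time x channels. No compression
# is applied (the reader transparently accepts chunked/compressed input).

.writeString <- function(fid, path, value) {
    rhdf5::h5write(enc2utf8(as.character(value)), fid, path,
                   variableLengthString = TRUE, encoding = "UTF-8")
}

.writeNumeric <- function(fid, path, value) {
    if (is.matrix(value)) {
        storage.mode(value) <- if (is.integer(value)) "integer" else "double"
        rhdf5::h5write(t(value), fid, path)
    } else {
        rhdf5::h5write(value, fid, path)
    }
}

.writeValue <- function(fid, path, value) {
    if (is.character(value)) .writeString(fid, path, value)
    else if (is.numeric(value)) .writeNumeric(fid, path, value)
    else if (is.logical(value)) .writeNumeric(fid, path, as.integer(value))
    else stop("cannot store value of class ", class(value)[1L],
              " at ", path, call. = FALSE)
}

# preservation area: named lists become groups, leaves become datasets
.writeNode <- function(fid, path, value) {
    if (is.list(value)) {
        rhdf5::h5createGroup(fid, path)
        for (nm in names(value))
            .writeNode(fid, .joinPath(path, nm), value[[nm]])
    } else {
        .writeValue(fid, path, value)
    }
}

.writeExtras <- function(fid, path, extra) {
    for (nm in names(extra))
        .writeNode(fid, .joinPath(path, nm), extra[[nm]])
}

.writeMeasurementListElement <- function(fid, path, ml) {
    rhdf5::h5createGroup(fid, path)
    rhdf5::h5write(ml@sourceIndex, fid, .joinPath(path, "sourceIndex"))
    rhdf5::h5write(ml@detectorIndex, fid, .joinPath(path, "detectorIndex"))
    rhdf5::h5write(ml@wavelengthIndex, fid, .joinPath(path, "wavelengthIndex"))
    rhdf5::h5write(ml@dataType, fid, .joinPath(path, "dataType"))
    if (!is.null(ml@dataTypeLabel))
        .writeString(fid, .joinPath(path, "dataTypeLabel"), ml@dataTypeLabel)
    if (!is.null(ml@dataUnit))
        .writeString(fid, .joinPath(path, "dataUnit"), ml@dataUnit)
    .writeExtras(fid, path, ml@extra)
}

.writeDataBlock <- function(fid, path, block) {
    rhdf5::h5createGroup(fid, path)
    .writeNumeric(fid, .joinPath(path, "dataTimeSeries"), block@dataTimeSeries)
    rhdf5::h5write(as.numeric(block@time), fid, .joinPath(path, "time"))
    for (k in seq_along(block@measurementList))
        .writeMeasurementListElement(
            fid, .joinPath(path, renderIndexedName("measurementList", k)),
            block@measurementList[[k]])
    .writeExtras(fid, path, block@extra)
}

.writeProbe <- function(fid, path, probe) {
    rhdf5::h5createGroup(fid, path)
    rhdf5::h5write(as.numeric(probe@wavelengths), fid,
                   .joinPath(path, "wavelengths"))
    for (nm in c("sourcePos2D", "sourcePos3D", "detectorPos2D", "detectorPos3D")) {
        m <- slot(probe, nm)
        if (!is.null(m)) .writeNumeric(fid, .joinPath(path, nm), m)
    }
    if (!is.null(probe@sourceLabels))
        .writeString(fid, .joinPath(path, "sourceLabels"), probe@sourceLabels)
    if (!is.null(probe@detectorLabels))
        .writeString(fid, .joinPath(path, "detectorLabels"), probe@detectorLabels)
    .writeExtras(fid, path, probe@extra)
}

.writeNirsElement <- function(fid, path, el) {
    rhdf5::h5createGroup(fid, path)
    rhdf5::h5createGroup(fid, .joinPath(path, "metaDataTags"))
    for (nm in names(el@metadata@tags))
        .writeValue(fid, .joinPath(path, paste0("metaDataTags/", nm)),
                    el@metadata@tags[[nm]])
    if (!is.null(el@probe))
        .writeProbe(fid, .joinPath(path, "probe"), el@probe)
    for (j in seq_along(el@data))
        .writeDataBlock(fid, .joinPath(path, renderIndexedName("data", j)),
                        el@data[[j]])
    for (j in seq_along(el@stim)) {
        sp <- .joinPath(path, renderIndexedName("stim", j))
        rhdf5::h5createGroup(fid, sp)
        .writeString(fid, .joinPath(sp, "name"), el@stim[[j]]@name)
        .writeNumeric(fid, .joinPath(sp, "data"), el@stim[[j]]@data)
        .writeExtras(fid, sp, el@stim[[j]]@extra)
    }
    for (j in seq_along(el@aux)) {
        ap <- .joinPath(path, renderIndexedName("aux", j))
        rhdf5::h5createGroup(fid, ap)
        .writeString(fid, .joinPath(ap, "name"), el@aux[[j]]@name)
        dts <- el@aux[[j]]@dataTimeSeries
        if (ncol(dts) == 1L) {
            rhdf5::h5write(as.numeric(dts[, 1L]), fid,
                           .joinPath(ap, "dataTimeSeries"))
        } else {
            .writeNumeric(fid, .joinPath(ap, "dataTimeSeries"), dts)
        }
        rhdf5::h5write(as.numeric(el@aux[[j]]@time), fid, .joinPath(ap, "time"))
        .writeExtras(fid, ap, el@aux[[j]]@extra)
    }
    .writeExtras(fid, path, el@extra)
}

#' Write a SNIRF file
#'
#' Serialises a [SnirfFile-class] model to an HDF5 container such that
#' [readSnirf()] recovers an identical model (exact numeric round-trip,
#' unknown content preserved). A single recording element is written as the
#' bare group `nirs`; multi-element collections carry 1-based suffixes
#' (`nirs1`, `nirs2`, ...). Data blocks, stimulus groups, auxiliary groups
#' and measurement-list elements always carry their index (`data1`,
#' `stim1`, ...).
#'
#' @param model A [SnirfFile-class].
#' @param path Output path (conventionally `.snirf`). An existing file is
#'   replaced.
#' @param force Write even when [validateSnirf()] reports errors (used to
#'   materialise deliberately broken fixtures; see [corruptSnirf()]).
#' @return `path`, invisibly.
#' @seealso [readSnirf()], [validateSnirf()]
#' @export
writeSnirf <- function(model, path, force = FALSE) {
    stopifnot(is(model, "SnirfFile"))
    if (!force) {
        rep <- validateSnirf(model)
        if (!isValidReport(rep)) {
            df <- findings(rep)
            df <- df[df$severity %in% c("FATAL", "ERROR"), , drop = FALSE]
            stop("model is not compliant; refusing to write (use force = TRUE):\n",
                 paste(sprintf("  [%s] %s: %s", df$code, df$location, df$message),
                       collapse = "\n"), call. = FALSE)
        }
    }
    if (file.exists(path) && !file.remove(path))
        stop("cannot replace '", path, "'", call. = FALSE)
    ok <- rhdf5::h5createFile(path)
    if (!isTRUE(ok)) stop("cannot create '", path, "'", call. = FALSE)
    fid <- rhdf5::H5Fopen(path)
    on.exit({ rhdf5::H5Fclose(fid) })
    .writeString(fid, "/formatVersion", model@formatVersion)
    n <- length(model@nirs)
    for (i in seq_len(n)) {
        nm <- if (n == 1L) "nirs" else renderIndexedName("nirs", i)
        .writeNirsElement(fid, paste0("/", nm), model@nirs[[i]])
    }
    .writeExtras(fid, "/", model@extra)
    invisible(path)
}
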