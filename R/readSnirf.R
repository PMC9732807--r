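# Reader for the SNIRF HDF5 container.
#
# rhdf5 presents dataset dimensions reversed relative to C-order tools
# (h5py/MATLAB view); every 2-D dataset is therefore transposed at this
# boundary so that an on-file time x channel matrix arrives in R as
# time x channel. Strings are decoded whether stored fixed- or
# variable-length, and numeric widths are coerced on read.

.readDataset <- function(fid, path) {
    v <- rhdf5::h5read(fid, path)
    if (is.array(v) && length(dim(v)) == 2L) return(t(v))
    if (is.array(v)) v <- as.vector(v)
    if (is.character(v) && length(v) == 1L) return(as.character(v))
    if (is.factor(v)) return(as.character(v))
    v
}

.readScalarString <- function(fid, path) {
    v <- .readDataset(fid, path)
    if (length(v) != 1L) v <- paste(v, collapse = "")
    enc2utf8(as.character(v))
}

.readScalarInt <- function(fid, path) as.integer(.readDataset(fid, path)[1L])

.readNumericMatrix <- function(fid, path) {
    v <- .readDataset(fid, path)
    if (!is.matrix(v)) v <- matrix(as.numeric(v), nrow = 1L)
    storage.mode(v) <- "double"
    v
}

# recursive fallback for unrecognised groups/datasets (preservation area)
.readNode <- function(fid, path, children) {
    isGrp <- children$otype == "H5I_GROUP"
    out <- list()
    for (i in seq_len(nrow(children))) {
        nm <- children$name[i]
        sub <- .joinPath(path, nm)
        out[[nm]] <- if (isGrp[i])
            .readNode(fid, sub, .lsChildren(fid, sub))
        else .readDataset(fid, sub)
    }
    out
}

.lsChildren <- function(fid, path) {
    loc <- fid
    if (path != "/") {
        loc <- rhdf5::H5Gopen(fid, path)
        on.exit(rhdf5::H5Gclose(loc))
    }
    ls <- rhdf5::h5ls(loc, recursive = FALSE, datasetinfo = FALSE,
                      index_type = "H5_INDEX_NAME")
    ls[, c("name", "otype"), drop = FALSE]
}

.readMeasurementListElement <- function(fid, path) {
    ch <- .lsChildren(fid, path)
    known <- c("sourceIndex", "detectorIndex", "wavelengthIndex",
               "dataType", "dataTypeLabel", "dataUnit")
    has <- function(nm) nm %in% ch$name
    extraCh <- ch[!(ch$name %in% known), , drop = FALSE]
    MeasurementListElement(
        sourceIndex     = if (has("sourceIndex")) .readScalarInt(fid, .joinPath(path, "sourceIndex")) else NA_integer_,
        detectorIndex   = if (has("detectorIndex")) .readScalarInt(fid, .joinPath(path, "detectorIndex")) else NA_integer_,
        wavelengthIndex = if (has("wavelengthIndex")) .readScalarInt(fid, .joinPath(path, "wavelengthIndex")) else NA_integer_,
        dataType        = if (has("dataType")) .readScalarInt(fid, .joinPath(path, "dataType")) else NA_integer_,
        dataTypeLabel   = if (has("dataTypeLabel")) .readScalarString(fid, .joinPath(path, "dataTypeLabel")) else NULL,
        dataUnit        = if (has("dataUnit")) .readScalarString(fid, .joinPath(path, "dataUnit")) else NULL,
        extra           = if (nrow(extraCh)) .readNode(fid, path, extraCh) else list())
}

.readDataBlock <- function(fid, path) {
    ch <- .lsChildren(fid, path)
    fnd <- list()
    mlCol <- .collectIndexed(ch$name[ch$otype == "H5I_GROUP"], "measurementList", path)
    fnd <- c(fnd, mlCol$findings)
    ml <- lapply(mlCol$members, function(nm)
        .readMeasurementListElement(fid, .joinPath(path, nm)))
    dts <- if ("dataTimeSeries" %in% ch$name) {
        v <- .readDataset(fid, .joinPath(path, "dataTimeSeries"))
        if (!is.matrix(v)) v <- matrix(as.numeric(v), ncol = 1L)
        v
    } else matrix(numeric(0), 0L, 0L)
    tm <- if ("time" %in% ch$name)
        as.numeric(.readDataset(fid, .joinPath(path, "time"))) else numeric(0)
    known <- c("dataTimeSeries", "time", mlCol$members)
    extraCh <- ch[!(ch$name %in% known), , drop = FALSE]
    # members with bad names were already reported; drop them from extras
    extraCh <- extraCh[!grepl("^measurementList", extraCh$name), , drop = FALSE]
    list(block = DataBlock(dts, tm, ml,
                           extra = if (nrow(extraCh)) .readNode(fid, path, extraCh) else list()),
         findings = fnd)
}

.readProbe <- function(fid, path) {
    ch <- .lsChildren(fid, path)
    has <- function(nm) nm %in% ch$name
    known <- c("wavelengths", "sourcePos2D", "sourcePos3D", "detectorPos2D",
               "detectorPos3D", "sourceLabels", "detectorLabels")
    extraCh <- ch[!(ch$name %in% known), , drop = FALSE]
    Probe(
        wavelengths    = if (has("wavelengths")) as.numeric(.readDataset(fid, .joinPath(path, "wavelengths"))) else numeric(0),
        sourcePos2D    = if (has("sourcePos2D")) .readNumericMatrix(fid, .joinPath(path, "sourcePos2D")) else NULL,
        sourcePos3D    = if (has("sourcePos3D")) .readNumericMatrix(fid, .joinPath(path, "sourcePos3D")) else NULL,
        detectorPos2D  = if (has("detectorPos2D")) .readNumericMatrix(fid, .joinPath(path, "detectorPos2D")) else NULL,
        detectorPos3D  = if (has("detectorPos3D")) .readNumericMatrix(fid, .joinPath(path, "detectorPos3D")) else NULL,
        sourceLabels   = if (has("sourceLabels")) as.character(.readDataset(fid, .joinPath(path, "sourceLabels"))) else NULL,
        detectorLabels = if (has("detectorLabels")) as.character(.readDataset(fid, .joinPath(path, "detectorLabels"))) else NULL,
        extra          = if (nrow(extraCh)) .readNode(fid, path, extraCh) else list())
}

.readStim <- function(fid, path) {
    ch <- .lsChildren(fid, path)
    nm <- if ("name" %in% ch$name) .readScalarString(fid, .joinPath(path, "name")) else ""
    dat <- if ("data" %in% ch$name) {
        v <- .readDataset(fid, .joinPath(path, "data"))
        if (!is.matrix(v)) v <- matrix(as.numeric(v), nrow = 1L)
        v
    } else matrix(numeric(0), 0L, 3L)
    extraCh <- ch[!(ch$name %in% c("name", "data")), , drop = FALSE]
    StimElement(nm, dat,
                extra = if (nrow(extraCh)) .readNode(fid, path, extraCh) else list())
}

.readAux <- function(fid, path) {
    ch <- .lsChildren(fid, path)
    nm <- if ("name" %in% ch$name) .readScalarString(fid, .joinPath(path, "name")) else ""
    dts <- if ("dataTimeSeries" %in% ch$name) {
        v <- .readDataset(fid, .joinPath(path, "dataTimeSeries"))
        if (!is.matrix(v)) v <- matrix(as.numeric(v), ncol = 1L)
        v
    } else matrix(numeric(0), 0L, 1L)
    tm <- if ("time" %in% ch$name)
        as.numeric(.readDataset(fid, .joinPath(path, "time"))) else numeric(0)
    extraCh <- ch[!(ch$name %in% c("name", "dataTimeSeries", "time")), , drop = FALSE]
    AuxElement(nm, dts, tm,
               extra = if (nrow(extraCh)) .readNode(fid, path, extraCh) else list())
}

.readMetaDataTags <- function(fid, path) {
    ch <- .lsChildren(fid, path)
    tags <- list()
    for (nm in ch$name[ch$otype != "H5I_GROUP"]) {
        v <- .readDataset(fid, .joinPath(path, nm))
        if (is.character(v) && length(v) == 1L) v <- enc2utf8(v)
        tags[[nm]] <- v
    }
    new("MetaDataTags", tags = tags)
}

.readNirsElement <- function(fid, path) {
    ch <- .lsChildren(fid, path)
    fnd <- list()
    groups <- ch$name[ch$otype == "H5I_GROUP"]

    md <- if ("metaDataTags" %in% groups)
        .readMetaDataTags(fid, .joinPath(path, "metaDataTags"))
    else new("MetaDataTags", tags = list())
    pr <- if ("probe" %in% groups) .readProbe(fid, .joinPath(path, "probe")) else NULL

    dataCol <- .collectIndexed(groups, "data", path)
    stimCol <- .collectIndexed(groups, "stim", path)
    auxCol  <- .collectIndexed(groups, "aux", path)
    fnd <- c(fnd, dataCol$findings, stimCol$findings, auxCol$findings)

    blocks <- list()
    for (nm in dataCol$members) {
        br <- .readDataBlock(fid, .joinPath(path, nm))
        blocks[[length(blocks) + 1L]] <- br$block
        fnd <- c(fnd, br$findings)
    }
    stim <- lapply(stimCol$members, function(nm) .readStim(fid, .joinPath(path, nm)))
    aux  <- lapply(auxCol$members, function(nm) .readAux(fid, .joinPath(path, nm)))

    known <- c("metaDataTags", "probe", dataCol$members, stimCol$members,
               auxCol$members)
    extraCh <- ch[!(ch$name %in% known), , drop = FALSE]
    extraCh <- extraCh[!grepl("^(data|stim|aux)[0-9]*$", extraCh$name), , drop = FALSE]
    if (nrow(extraCh))
        for (i in seq_len(nrow(extraCh)))
            fnd[[length(fnd) + 1L]] <- .finding(
                "UNRECOGNIZED_CONTENT", "INFO",
                .joinPath(path, extraCh$name[i]),
                "content not defined by the format; preserved on round-trip",
                "general")

    list(element = NirsElement(metadata = md, probe = pr, data = blocks,
                               stim = stim, aux = aux,
                               extra = if (nrow(extraCh)) .readNode(fid, path, extraCh) else list()),
         findings = fnd)
}

# Permissive reader: never stops on compliance problems; returns the model
# (possibly incomplete), the findings collected while scanning the tree, and
# the actual group name of each recording element (bare or indexed).
.readSnirfPermissive <- function(path) {
    if (!file.exists(path))
        return(list(model = NULL, nirsNames = character(0), findings = list(
            .finding("NOT_HDF5", "FATAL", "/",
                     sprintf("file '%s' does not exist", path), "hdf5"))))
    ok <- tryCatch(rhdf5::H5Fis_hdf5(path), error = function(e) FALSE)
    if (!isTRUE(ok))
        return(list(model = NULL, nirsNames = character(0), findings = list(
            .finding("NOT_HDF5", "FATAL", "/",
                     sprintf("file '%s' is not an HDF5 container", path), "hdf5"))))
    fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
    on.exit(rhdf5::H5Fclose(fid))

    fnd <- list()
    ch <- .lsChildren(fid, "/")
    fv <- ""
    if ("formatVersion" %in% ch$name) {
        fv <- .readScalarString(fid, "/formatVersion")
    } else {
        fnd[[length(fnd) + 1L]] <- .finding(
            "VERSION_MISSING", "ERROR", "/formatVersion",
            "root dataset 'formatVersion' is missing", "formatversion")
    }

    nirsCol <- .collectIndexed(ch$name[ch$otype == "H5I_GROUP"], "nirs", "/")
    fnd <- c(fnd, nirsCol$findings)
    elements <- list()
    for (nm in nirsCol$members) {
        er <- .readNirsElement(fid, paste0("/", nm))
        elements[[length(elements) + 1L]] <- er$element
        fnd <- c(fnd, er$findings)
    }

    known <- c("formatVersion", nirsCol$members)
    extraCh <- ch[!(ch$name %in% known), , drop = FALSE]
    extraCh <- extraCh[!grepl("^nirs[0-9]*$", extraCh$name), , drop = FALSE]
    if (nrow(extraCh))
        for (i in seq_len(nrow(extraCh)))
            fnd[[length(fnd) + 1L]] <- .finding(
                "UNRECOGNIZED_CONTENT", "INFO", paste0("/", extraCh$name[i]),
                "content not defined by the format; preserved on round-trip",
                "general")

    model <- SnirfFile(nirs = elements, formatVersion = fv,
                       extra = if (nrow(extraCh)) .readNode(fid, "/", extraCh) else list())
    list(model = model, nirsNames = nirsCol$members, findings = fnd)
}

#' Read a SNIRF file
#'
#' Reads an HDF5 SNIRF container into a [SnirfFile-class] model. Indexed
#' collections (`nirs`, `data`, `stim`, `aux`, `measurementList`) are ordered
#' by their numeric index regardless of HDF5 iteration order; a bare singleton
#' name (`"nirs"` without a digit) is accepted as index 1. Strings are decoded
#' as UTF-8 whether stored fixed- or variable-length; any numeric width is
#' accepted. Content not defined by the format is retained in the `extra`
#' preservation area of its parent and written back by [writeSnirf()].
#'
#' @param path Path to a `.snirf` file.
#' @param permissive Keep reading past structural problems (as the validator
#'   does); with `permissive = FALSE` structural findings of severity ERROR or
#'   worse raise an error.
#' @return A [SnirfFile-class] object.
#' @seealso [writeSnirf()], [validateSnirf()]
#' @export
readSnirf <- function(path, permissive = FALSE) {
    res <- .readSnirfPermissive(path)
    if (is.null(res$model))
        stop(res$findings[[1L]]@message, call. = FALSE)
    if (!permissive) {
        bad <- Filter(function(f) f@severity %in% c("FATAL", "ERROR"), res$findings)
        if (length(bad))
            stop("structural problems while reading '", path, "':\n",
                 paste(vapply(bad, function(f)
                     sprintf("  [%s] %s: %s", f@code, f@location, f@message),
                     character(1)), collapse = "\n"),
                 "\n(use permissive = TRUE or validateSnirf() to inspect)",
                 call. = FALSE)
    }
    res$model
}
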