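#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' Metadata tags of a SNIRF recording element
#'
#' A flat key--value store describing one `nirs` element. The format requires
#' six tags (`SubjectID`, `MeasurementDate`, `MeasurementTime`, `LengthUnit`,
#' `TimeUnit`, `FrequencyUnit`); any further user tags are carried along
#' unchanged so that files stay self-describing through a read/write cycle.
#'
#' @slot tags Named list of scalar values (character for all required tags;
#'   foreign numeric tags encountered in files are kept numeric).
#' @export
setClass("MetaDataTags", slots = c(tags = "list"))

setValidity("MetaDataTags", function(object) {
    tg <- object@tags
    if (length(tg) && (is.null(names(tg)) || any(!nzchar(names(tg)))))
        return("all tags must be named")
    bad <- vapply(tg, function(v)
        !(is.character(v) || is.numeric(v)) || length(v) < 1L, logical(1))
    if (any(bad))
        return(sprintf("tags must be character or numeric: %s",
                       paste(names(tg)[bad], collapse = ", ")))
    TRUE
})

#' Probe geometry of a SNIRF recording element
#'
#' Optode coordinates and nominal source wavelengths. Coordinates may be given
#' in 2-D (flattened layout, S x 2 / D x 2) and/or 3-D (digitised positions,
#' S x 3 / D x 3, in the file's `LengthUnit`). At least one source-position and
#' one detector-position array must be present for channels to be resolvable.
#'
#' @slot wavelengths Numeric vector of nominal wavelengths in nanometres.
#' @slot sourcePos2D,sourcePos3D Optional source coordinate matrices.
#' @slot detectorPos2D,detectorPos3D Optional detector coordinate matrices.
#' @slot sourceLabels,detectorLabels Optional character vectors of optode names.
#' @slot extra Named list of unrecognised datasets preserved from a file.
#' @export
setClass("Probe", slots = c(
    wavelengths    = "numeric",
    sourcePos2D    = "matrixOrNULL",
    sourcePos3D    = "matrixOrNULL",
    detectorPos2D  = "matrixOrNULL",
    detectorPos3D  = "matrixOrNULL",
    sourceLabels   = "characterOrNULL",
    detectorLabels = "characterOrNULL",
    extra          = "list"
))

setValidity("Probe", function(object) {
    for (nm in c("sourcePos2D", "sourcePos3D", "detectorPos2D", "detectorPos3D")) {
        m <- slot(object, nm)
        if (!is.null(m) && !is.numeric(m))
            return(sprintf("%s must be a numeric matrix", nm))
    }
    TRUE
})

setClassUnion("ProbeOrNULL", c("Probe", "NULL"))

#' One channel descriptor in a measurement list
#'
#' Links one column of `dataTimeSeries` to the probe: `sourceIndex`,
#' `detectorIndex` and `wavelengthIndex` are 1-based indices into the probe's
#' position and wavelength arrays. `dataType` is an integer code (1 = raw
#' continuous-wave amplitude; 99999 = processed data, which additionally
#' requires `dataTypeLabel`).
#'
#' @slot sourceIndex,detectorIndex,wavelengthIndex 1-based integer indices.
#' @slot dataType Integer data-type code.
#' @slot dataTypeLabel,dataUnit Optional strings (`NULL` when absent).
#' @slot extra Named list of unrecognised datasets preserved from a file.
#' @export
setClass("MeasurementListElement", slots = c(
    sourceIndex     = "integer",
    detectorIndex   = "integer",
    wavelengthIndex = "integer",
    dataType        = "integer",
    dataTypeLabel   = "characterOrNULL",
    dataUnit        = "characterOrNULL",
    extra           = "list"
))

setValidity("MeasurementListElement", function(object) {
    for (nm in c("sourceIndex", "detectorIndex", "wavelengthIndex", "dataType"))
        if (length(slot(object, nm)) != 1L)
            return(sprintf("%s must be a single integer", nm))
    TRUE
})

#' A block of fNIRS time-series data
#'
#' Holds the time x channel matrix `dataTimeSeries`, its time axis and the
#' measurement list describing each column. The time axis is either an
#' explicit vector of sample times (length = number of rows) or the implicit
#' two-element form `c(start, increment)` encoding a uniform axis; see
#' [expandTime()].
#'
#' @slot dataTimeSeries Numeric matrix, rows = time points, columns = channels.
#' @slot time Numeric vector: explicit sample times or `c(start, increment)`.
#' @slot measurementList List of [MeasurementListElement-class] objects, one
#'   per column.
#' @slot extra Named list of unrecognised datasets preserved from a file.
#' @export
setClass("DataBlock", slots = c(
    dataTimeSeries  = "matrix",
    time            = "numeric",
    measurementList = "list",
    extra           = "list"
))

setValidity("DataBlock", function(object) {
    if (!is.numeric(object@dataTimeSeries))
        return("dataTimeSeries must be numeric")
    ok <- vapply(object@measurementList, is, logical(1), "MeasurementListElement")
    if (!all(ok))
        return("measurementList entries must be MeasurementListElement objects")
    TRUE
})

#' An experimental stimulus descriptor
#'
#' @slot name Condition name.
#' @slot data Numeric E x 3 matrix; columns are onset, duration and amplitude
#'   (onsets/durations in the file's `TimeUnit`). The format leaves the column
#'   semantics to convention; this is the community layout.
#' @slot extra Named list of unrecognised datasets preserved from a file.
#' @export
setClass("StimElement", slots = c(
    name  = "character",
    data  = "matrix",
    extra = "list"
))

setValidity("StimElement", function(object) {
    if (length(object@name) != 1L) return("name must be a single string")
    if (!is.numeric(object@data) || ncol(object@data) != 3L)
        return("data must be a numeric E x 3 matrix [onset, duration, amplitude]")
    TRUE
})

#' An auxiliary signal (e.g. accelerometer channel)
#'
#' Auxiliary signals carry their own time axes and may be sampled at rates and
#' onsets unrelated to any data block.
#'
#' @slot name Signal name.
#' @slot dataTimeSeries Numeric matrix, rows = time points (a single-channel
#'   signal is stored as a one-column matrix).
#' @slot time Time axis, same dual convention as [DataBlock-class].
#' @slot extra Named list of unrecognised datasets preserved from a file.
#' @export
setClass("AuxElement", slots = c(
    name           = "character",
    dataTimeSeries = "matrix",
    time           = "numeric",
    extra          = "list"
))

setValidity("AuxElement", function(object) {
    if (length(object@name) != 1L) return("name must be a single string")
    if (!is.numeric(object@dataTimeSeries))
        return("dataTimeSeries must be numeric")
    TRUE
})

#' One recording element of a SNIRF file
#'
#' A `nirs` group: one subject/measurement unit holding metadata tags, the
#' probe description, and indexed collections of data blocks, stimulus
#' descriptors and auxiliary signals. Distinct blocks and auxiliary signals
#' may have different sampling rates and onsets; no shared clock is assumed.
#'
#' @slot metadata A [MetaDataTags-class] object.
#' @slot probe A [Probe-class] object (`NULL` only for damaged files held for
#'   validation).
#' @slot data List of [DataBlock-class] objects (a compliant file has >= 1).
#' @slot stim List of [StimElement-class] objects.
#' @slot aux List of [AuxElement-class] objects.
#' @slot extra Named list of unrecognised groups/datasets preserved from a file.
#' @export
setClass("NirsElement", slots = c(
    metadata = "MetaDataTags",
    probe    = "ProbeOrNULL",
    data     = "list",
    stim     = "list",
    aux      = "list",
    extra    = "list"
))

setValidity("NirsElement", function(object) {
    if (!all(vapply(object@data, is, logical(1), "DataBlock")))
        return("data entries must be DataBlock objects")
    if (!all(vapply(object@stim, is, logical(1), "StimElement")))
        return("stim entries must be StimElement objects")
    if (!all(vapply(object@aux, is, logical(1), "AuxElement")))
        return("aux entries must be AuxElement objects")
    TRUE
})

#' In-memory representation of a SNIRF file
#'
#' The root container: a semantic `formatVersion` string and an ordered,
#' 1-based collection of recording elements. Compliance (required tags, index
#' bounds, time-axis monotonicity, ...) is checked by [validateSnirf()], not by
#' the class itself, so damaged files can be represented and reported on.
#'
#' @slot formatVersion Version string, `MAJOR.MINOR[.PATCH]`.
#' @slot nirs List of [NirsElement-class] objects.
#' @slot extra Named list of unrecognised root-level content from a file.
#' @export
setClass("SnirfFile", slots = c(
    formatVersion = "character",
    nirs          = "list",
    extra         = "list"
))

setValidity("SnirfFile", function(object) {
    if (length(object@formatVersion) != 1L)
        return("formatVersion must be a single string")
    if (!all(vapply(object@nirs, is, logical(1), "NirsElement")))
        return("nirs entries must be NirsElement objects")
    TRUE
})

#' Fully resolved description of one channel
#'
#' The result of following a measurement-list entry through the probe arrays:
#' actual optode coordinates and the nominal wavelength, rather than indices.
#'
#' @slot sourcePosition,detectorPosition Numeric coordinate vectors (3-D
#'   preferred over 2-D when both are stored).
#' @slot wavelength Nominal wavelength in nanometres.
#' @slot dataType Integer data-type code of the channel.
#' @slot columnIndex 1-based column of `dataTimeSeries` this describes.
#' @export
setClass("ChannelDescription", slots = c(
    sourcePosition   = "numeric",
    detectorPosition = "numeric",
    wavelength       = "numeric",
    dataType         = "integer",
    columnIndex      = "integer"
))

#' A single validation finding
#'
#' @slot code Stable identifier from the closed registry (see [findingCodes()]).
#' @slot severity `"FATAL"`, `"ERROR"`, `"WARNING"` or `"INFO"`.
#' @slot location Absolute HDF5 path of the offending object.
#' @slot message Human-readable sentence.
#' @slot specRef Section anchor of the SNIRF format specification.
#' @export
setClass("Finding", slots = c(
    code     = "character",
    severity = "character",
    location = "character",
    message  = "character",
    specRef  = "character"
))

setValidity("Finding", function(object) {
    for (nm in slotNames(object))
        if (length(slot(object, nm)) != 1L || is.na(slot(object, nm)))
            return(sprintf("%s must be a single non-NA string", nm))
    if (!object@severity %in% c("FATAL", "ERROR", "WARNING", "INFO"))
        return("severity must be one of FATAL, ERROR, WARNING, INFO")
    TRUE
})

#' A validation report
#'
#' An ordered collection of findings (sorted by location, then code). A file
#' is valid iff the report contains no finding at `FATAL` or `ERROR` severity;
#' warnings and informational notes never invalidate a file.
#'
#' @slot findings List of [Finding-class] objects.
#' @export
setClass("ValidationReport", slots = c(findings = "list"))

setValidity("ValidationReport", function(object) {
    if (!all(vapply(object@findings, is, logical(1), "Finding")))
        return("findings must be Finding objects")
    TRUE
})

#' Parameters for the synthetic SNIRF generator
#'
#' Describes the desk-scale continuous-wave recording that [generateSnirf()]
#' emulates: a gridded probe, all source-detector-wavelength channel triples,
#' per-block sampling rates and onsets, optional stimulus and auxiliary
#' content. Source/detector counts are capped at 32 each.
#'
#' @slot nSources,nDetectors Optode counts (1..32).
#' @slot wavelengths Nominal wavelengths in nm.
#' @slot nBlocks Number of data blocks.
#' @slot durationS Recording duration per block in seconds.
#' @slot samplingRateHz Per-block sampling rates in Hz (recycled to `nBlocks`).
#' @slot nStim,nAux Number of stimulus conditions / auxiliary signals.
#' @slot seed RNG seed making the generated model fully deterministic.
#' @export
setClass("SnirfGenSpec", slots = c(
    nSources       = "integer",
    nDetectors     = "integer",
    wavelengths    = "numeric",
    nBlocks        = "integer",
    durationS      = "numeric",
    samplingRateHz = "numeric",
    nStim          = "integer",
    nAux           = "integer",
    seed           = "integer"
))

setValidity("SnirfGenSpec", function(object) {
    if (object@nSources < 1L || object@nSources > 32L)
        return("nSources must be in 1..32")
    if (object@nDetectors < 1L || object@nDetectors > 32L)
        return("nDetectors must be in 1..32")
    if (length(object@wavelengths) < 1L || any(object@wavelengths <= 0))
        return("wavelengths must be positive and non-empty")
    if (object@nBlocks < 1L) return("nBlocks must be >= 1")
    if (object@durationS <= 0) return("durationS must be positive")
    if (any(object@samplingRateHz <= 0))
        return("samplingRateHz must be positive")
    if (object@nStim < 0L || object@nAux < 0L)
        return("nStim and nAux must be >= 0")
    TRUE
})
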