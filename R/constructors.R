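# Constructors canonicalise storage modes (doubles for signals and
# coordinates, integers for indices) so that a model written to HDF5 and read
# back compares identical slot by slot.

.asMatrixOrNULL <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.vector(x) && is.numeric(x)) x <- matrix(as.numeric(x), nrow = 1L)
    if (!is.matrix(x) || !is.numeric(x))
        stop(what, " must be a numeric matrix or NULL", call. = FALSE)
    storage.mode(x) <- "double"
    dimnames(x) <- NULL
    x
}

.asScalarString <- function(x, what, optional = FALSE) {
    if (is.null(x) && optional) return(NULL)
    if (!is.character(x) || length(x) != 1L || is.na(x))
        stop(what, " must be a single string", call. = FALSE)
    x
}

#' Construct metadata tags
#'
#' @param SubjectID,MeasurementDate,MeasurementTime,LengthUnit,TimeUnit,FrequencyUnit
#'   The six tags every compliant file must carry: a subject identifier, the
#'   acquisition date (ISO 8601) and time of day, and the units used for
#'   lengths, times and frequencies throughout the file.
#' @param ... Further named scalar tags; the format allows arbitrary
#'   user-defined entries and this package preserves them verbatim.
#' @return A [MetaDataTags-class] object.
#' @examples
#' md <- MetaDataTags(SubjectID = "sub-01", MeasurementDate = "2024-05-01",
#'                    MeasurementTime = "09:30:00", Site = "lab A")
#' @export
MetaDataTags <- function(SubjectID = "subject1",
                         MeasurementDate = "2000-01-01",
                         MeasurementTime = "00:00:00",
                         LengthUnit = "mm",
                         TimeUnit = "s",
                         FrequencyUnit = "Hz",
                         ...) {
    tags <- c(list(SubjectID = SubjectID, MeasurementDate = MeasurementDate,
                   MeasurementTime = MeasurementTime, LengthUnit = LengthUnit,
                   TimeUnit = TimeUnit, FrequencyUnit = FrequencyUnit),
              list(...))
    new("MetaDataTags", tags = tags)
}

#' Construct a probe description
#'
#' @param wavelengths Numeric vector of nominal wavelengths (nm).
#' @param sourcePos2D,sourcePos3D Source coordinates, S x 2 / S x 3 (at least
#'   one required for a compliant file).
#' @param detectorPos2D,detectorPos3D Detector coordinates, D x 2 / D x 3.
#' @param sourceLabels,detectorLabels Optional optode names.
#' @param extra Named list of additional datasets to store in the probe group.
#' @return A [Probe-class] object.
#' @export
Probe <- function(wavelengths,
                  sourcePos2D = NULL, sourcePos3D = NULL,
                  detectorPos2D = NULL, detectorPos3D = NULL,
                  sourceLabels = NULL, detectorLabels = NULL,
                  extra = list()) {
    new("Probe",
        wavelengths    = as.numeric(wavelengths),
        sourcePos2D    = .asMatrixOrNULL(sourcePos2D, "sourcePos2D"),
        sourcePos3D    = .asMatrixOrNULL(sourcePos3D, "sourcePos3D"),
        detectorPos2D  = .asMatrixOrNULL(detectorPos2D, "detectorPos2D"),
        detectorPos3D  = .asMatrixOrNULL(detectorPos3D, "detectorPos3D"),
        sourceLabels   = if (is.null(sourceLabels)) NULL else as.character(sourceLabels),
        detectorLabels = if (is.null(detectorLabels)) NULL else as.character(detectorLabels),
        extra          = extra)
}

#' Construct a measurement-list element
#'
#' @param sourceIndex,detectorIndex,wavelengthIndex 1-based indices into the
#'   probe's source/detector position arrays and wavelengths vector.
#' @param dataType Integer data-type code; 1 (raw continuous-wave amplitude)
#'   by default. Code 99999 marks processed data and requires `dataTypeLabel`.
#' @param dataTypeLabel,dataUnit Optional descriptor strings.
#' @param extra Named list of additional datasets for this element.
#' @return A [MeasurementListElement-class] object.
#' @export
MeasurementListElement <- function(sourceIndex, detectorIndex, wavelengthIndex,
                                   dataType = 1L, dataTypeLabel = NULL,
                                   dataUnit = NULL, extra = list()) {
    new("MeasurementListElement",
        sourceIndex     = as.integer(sourceIndex),
        detectorIndex   = as.integer(detectorIndex),
        wavelengthIndex = as.integer(wavelengthIndex),
        dataType        = as.integer(dataType),
        dataTypeLabel   = .asScalarString(dataTypeLabel, "dataTypeLabel", TRUE),
        dataUnit        = .asScalarString(dataUnit, "dataUnit", TRUE),
        extra           = extra)
}

#' Construct a data block
#'
#' @param dataTimeSeries Numeric matrix, rows = time points, columns =
#'   channels.
#' @param time Time axis: either an explicit vector of sample times (length
#'   equal to `nrow(dataTimeSeries)`) or the implicit uniform form
#'   `c(start, increment)`.
#' @param measurementList List of [MeasurementListElement-class] objects, one
#'   per column of `dataTimeSeries`.
#' @param extra Named list of additional datasets for this block.
#' @return A [DataBlock-class] object.
#' @export
DataBlock <- function(dataTimeSeries, time, measurementList, extra = list()) {
    dataTimeSeries <- as.matrix(dataTimeSeries)
    storage.mode(dataTimeSeries) <- "double"
    dimnames(dataTimeSeries) <- NULL
    new("DataBlock",
        dataTimeSeries  = dataTimeSeries,
        time            = as.numeric(time),
        measurementList = unname(measurementList),
        extra           = extra)
}

#' Construct a stimulus descriptor
#'
#' @param name Condition name.
#' @param data Numeric E x 3 matrix with columns onset, duration, amplitude
#'   (community convention; the container format itself does not fix the
#'   column semantics).
#' @param extra Named list of additional datasets for this stimulus.
#' @return A [StimElement-class] object.
#' @export
StimElement <- function(name, data, extra = list()) {
    data <- as.matrix(data)
    storage.mode(data) <- "double"
    dimnames(data) <- NULL
    new("StimElement", name = name, data = data, extra = extra)
}

#' Construct an auxiliary signal
#'
#' @param name Signal name.
#' @param dataTimeSeries Numeric vector (single channel) or T x K matrix.
#' @param time Time axis, same convention as [DataBlock()].
#' @param extra Named list of additional datasets for this signal.
#' @return An [AuxElement-class] object.
#' @export
AuxElement <- function(name, dataTimeSeries, time, extra = list()) {
    if (!is.matrix(dataTimeSeries))
        dataTimeSeries <- matrix(as.numeric(dataTimeSeries), ncol = 1L)
    storage.mode(dataTimeSeries) <- "double"
    dimnames(dataTimeSeries) <- NULL
    new("AuxElement", name = name, dataTimeSeries = dataTimeSeries,
        time = as.numeric(time), extra = extra)
}

#' Construct a recording element
#'
#' @param metadata A [MetaDataTags-class] object.
#' @param probe A [Probe-class] object.
#' @param data List of [DataBlock-class] objects (>= 1 for a compliant file).
#' @param stim List of [StimElement-class] objects.
#' @param aux List of [AuxElement-class] objects.
#' @param extra Named list of additional content for this element.
#' @return A [NirsElement-class] object.
#' @export
NirsElement <- function(metadata = MetaDataTags(), probe = NULL,
                        data = list(), stim = list(), aux = list(),
                        extra = list()) {
    if (is(data, "DataBlock")) data <- list(data)
    if (is(stim, "StimElement")) stim <- list(stim)
    if (is(aux, "AuxElement")) aux <- list(aux)
    new("NirsElement", metadata = metadata, probe = probe,
        data = unname(data), stim = unname(stim), aux = unname(aux),
        extra = extra)
}

#' Construct a SNIRF file model
#'
#' @param nirs A [NirsElement-class] or list of them (collection is 1-based
#'   and ordered).
#' @param formatVersion Semantic version string of the format.
#' @param extra Named list of additional root-level content.
#' @return A [SnirfFile-class] object.
#' @seealso [readSnirf()], [writeSnirf()], [validateSnirf()]
#' @export
SnirfFile <- function(nirs, formatVersion = "1.0", extra = list()) {
    if (is(nirs, "NirsElement")) nirs <- list(nirs)
    new("SnirfFile", formatVersion = formatVersion, nirs = unname(nirs),
        extra = extra)
}

#' Construct a generator specification
#'
#' @param nSources,nDetectors Optode counts (1..32 each).
#' @param wavelengths Nominal wavelengths in nm; the default pair 760/850 nm
#'   brackets the isosbestic point of haemoglobin as typical continuous-wave
#'   instruments do.
#' @param nBlocks Number of data blocks.
#' @param durationS Duration of each block in seconds.
#' @param samplingRateHz Sampling rate per block in Hz (recycled to
#'   `nBlocks`); blocks may run at different rates.
#' @param nStim Number of stimulus conditions.
#' @param nAux Number of auxiliary signals.
#' @param seed Integer seed; the generated model is a pure function of the
#'   full specification including the seed.
#' @return A [SnirfGenSpec-class] object.
#' @seealso [generateSnirf()]
#' @export
genSpec <- function(nSources = 2L, nDetectors = 2L,
                    wavelengths = c(760, 850), nBlocks = 1L,
                    durationS = 10, samplingRateHz = 10,
                    nStim = 1L, nAux = 1L, seed = 1L) {
    new("SnirfGenSpec",
        nSources       = as.integer(nSources),
        nDetectors     = as.integer(nDetectors),
        wavelengths    = as.numeric(wavelengths),
        nBlocks        = as.integer(nBlocks),
        durationS      = as.numeric(durationS),
        samplingRateHz = rep_len(as.numeric(samplingRateHz), as.integer(nBlocks)),
        nStim          = as.integer(nStim),
        nAux           = as.integer(nAux),
        seed           = as.integer(seed))
}
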