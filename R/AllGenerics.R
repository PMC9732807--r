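#' @rdname accessors
#' @export
setGeneric("formatVersion", function(x) standardGeneric("formatVersion"))

#' @rdname accessors
#' @export
setGeneric("formatVersion<-", function(x, value) standardGeneric("formatVersion<-"))

#' @rdname accessors
#' @export
setGeneric("nirsElements", function(x) standardGeneric("nirsElements"))

#' @rdname accessors
#' @export
setGeneric("metaDataTags", function(x) standardGeneric("metaDataTags"))

#' @rdname accessors
#' @export
setGeneric("probe", function(x) standardGeneric("probe"))

#' @rdname accessors
#' @export
setGeneric("dataBlocks", function(x) standardGeneric("dataBlocks"))

#' @rdname accessors
#' @export
setGeneric("stimElements", function(x) standardGeneric("stimElements"))

#' @rdname accessors
#' @export
setGeneric("auxElements", function(x) standardGeneric("auxElements"))

#' @rdname accessors
#' @export
setGeneric("dataTimeSeries", function(x) standardGeneric("dataTimeSeries"))

#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname accessors
#' @export
setGeneric("measurementList", function(x) standardGeneric("measurementList"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname findings
#' @export
setGeneric("findings", function(x) standardGeneric("findings"))

#' @rdname findings
#' @export
setGeneric("isValidReport", function(x) standardGeneric("isValidReport"))
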