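.REPORT_SCHEMA <- "snirf-validation-report/1.0"

#' Serialise a validation report to JSON
#'
#' Emits the machine-readable form of a [ValidationReport-class]: a stable
#' JSON document (schema shipped at
#' `system.file("schema", "validation-report.schema.json", package = "snirfio")`)
#' with the overall verdict and every finding's code, severity, location,
#' message and specification reference. Serialisation is canonical:
#' serialise, parse and serialise again yields the identical byte sequence,
#' so reports can be diffed and archived.
#'
#' @param report A [ValidationReport-class].
#' @return A JSON string (class `json`).
#' @seealso [reportFromJson()]
#' @export
reportToJson <- function(report) {
    stopifnot(is(report, "ValidationReport"))
    doc <- list(
        schema = .REPORT_SCHEMA,
        valid = isValidReport(report),
        findings = lapply(report@findings, function(f)
            list(code = f@code, severity = f@severity, location = f@location,
                 message = f@message, spec_ref = f@specRef)))
    jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
}

#' Parse a JSON validation report
#'
#' Inverse of [reportToJson()].
#'
#' @param json JSON string, or path to a file containing one.
#' @return A [ValidationReport-class].
#' @export
reportFromJson <- function(json) {
    if (length(json) == 1L && !grepl("{", json, fixed = TRUE) &&
        file.exists(json))
        json <- paste(readLines(json, warn = FALSE), collapse = "\n")
    doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
    if (!identical(doc$schema, .REPORT_SCHEMA))
        stop("not a ", .REPORT_SCHEMA, " document", call. = FALSE)
    fnd <- lapply(doc$findings, function(f)
        .finding(f$code, f$severity, f$location, f$message, f$spec_ref))
    new("ValidationReport", findings = fnd)
}
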