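# Shared helpers for the suite. The channel-table oracle deliberately
# bypasses resolveChannel(): it materialises every channel of a block by
# direct array indexing so that the resolution logic can be checked against
# an independent path.

oracleChannelTable <- function(element, blockIndex) {
    pr <- element@probe
    srcs <- if (!is.null(pr@sourcePos3D)) pr@sourcePos3D else pr@sourcePos2D
    dets <- if (!is.null(pr@detectorPos3D)) pr@detectorPos3D else pr@detectorPos2D
    ml <- element@data[[blockIndex]]@measurementList
    lapply(seq_along(ml), function(k) {
        e <- ml[[k]]
        list(sourcePosition   = as.numeric(srcs[e@sourceIndex, ]),
             detectorPosition = as.numeric(dets[e@detectorIndex, ]),
             wavelength       = pr@wavelengths[e@wavelengthIndex],
             dataType         = e@dataType,
             columnIndex      = k)
    })
}

# a small compliant model assembled by hand (not via the generator)
handMadeModel <- function(nChannels = 2L, nT = 6L) {
    pr <- Probe(wavelengths = c(760, 850),
                sourcePos2D = matrix(c(0, 0, 30, 0), 2L, 2L, byrow = TRUE),
                detectorPos2D = matrix(c(15, 15), 1L, 2L))
    ml <- lapply(seq_len(nChannels), function(k)
        MeasurementListElement(1L + (k - 1L) %% 2L, 1L, 1L + (k - 1L) %% 2L))
    blk <- DataBlock(matrix(seq_len(nT * nChannels) / 3, nT, nChannels),
                     time = (seq_len(nT) - 1L) * 0.2,
                     measurementList = ml)
    SnirfFile(NirsElement(metadata = MetaDataTags(SubjectID = "hand"),
                          probe = pr, data = list(blk)))
}

countFindings <- function(report, code) {
    df <- findings(report)
    sum(df$code == code)
}

snirfTempFile <- function() {
    withr::local_tempfile(fileext = ".snirf", .local_envir = parent.frame())
}
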