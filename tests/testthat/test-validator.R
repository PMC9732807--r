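test_that("the minimal compliant file passes with zero errors", {
    m <- makeMinimalExample()
    rep <- validateSnirf(m)
    expect_true(isValidReport(rep))
    expect_identical(nrow(findings(rep)), 0L)
    f <- snirfTempFile()
    writeSnirf(m, f)
    expect_true(isValidReport(validateSnirf(f)))
})

test_that("a file needs at least one data block and a probe", {
    noData <- makeMinimalExample()
    noData@nirs[[1]]@data <- list()
    rep <- validateSnirf(noData)
    expect_false(isValidReport(rep))
    expect_identical(countFindings(rep, "DATA_MISSING"), 1L)

    noProbe <- makeMinimalExample()
    noProbe@nirs[[1]]@probe <- NULL
    rep <- validateSnirf(noProbe)
    expect_false(isValidReport(rep))
    expect_identical(countFindings(rep, "PROBE_MISSING"), 1L)

    empty <- new("SnirfFile", formatVersion = "1.0", nirs = list(),
                 extra = list())
    expect_identical(countFindings(validateSnirf(empty), "NIRS_MISSING"), 1L)
})

test_that("each required metadata tag is individually enforced", {
    required <- c("SubjectID", "MeasurementDate", "MeasurementTime",
                  "LengthUnit", "TimeUnit", "FrequencyUnit")
    for (tag in required) {
        m <- makeMinimalExample()
        m@nirs[[1]]@metadata@tags[[tag]] <- NULL
        rep <- validateSnirf(m)
        expect_false(isValidReport(rep))
        expect_identical(countFindings(rep, "METADATA_MISSING"), 1L)
        expect_match(findings(rep)$message, tag)
    }
    # an empty string counts as missing too
    m <- makeMinimalExample()
    m@nirs[[1]]@metadata@tags$TimeUnit <- ""
    expect_identical(countFindings(validateSnirf(m), "METADATA_MISSING"), 1L)
    # extra user tags are never findings
    m <- makeMinimalExample()
    m@nirs[[1]]@metadata@tags$MyNote <- "hello"
    expect_true(isValidReport(validateSnirf(m)))
})

test_that("a seeded dangling wavelengthIndex yields exactly one finding", {
    m <- makeWorkedExample()   # 2 wavelengths
    ml <- m@nirs[[1]]@data[[1]]@measurementList[[2]]
    ml@wavelengthIndex <- 3L
    m@nirs[[1]]@data[[1]]@measurementList[[2]] <- ml
    rep <- validateSnirf(m)
    df <- findings(rep)
    hits <- df[df$code == "INDEX_OUT_OF_RANGE", , drop = FALSE]
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$location,
                     "/nirs1/data1/measurementList2/wavelengthIndex")
})

test_that("data-type codes outside the registry warn but do not invalidate", {
    m <- makeMinimalExample()
    ml <- m@nirs[[1]]@data[[1]]@measurementList[[1]]
    ml@dataType <- 301L
    m@nirs[[1]]@data[[1]]@measurementList[[1]] <- ml
    rep <- validateSnirf(m)
    expect_identical(countFindings(rep, "UNKNOWN_DATA_TYPE"), 1L)
    expect_true(isValidReport(rep))

    ml@dataType <- 99999L
    ml@dataTypeLabel <- NULL
    m@nirs[[1]]@data[[1]]@measurementList[[1]] <- ml
    rep <- validateSnirf(m)
    expect_identical(countFindings(rep, "DATA_TYPE_LABEL_MISSING"), 1L)
    expect_false(isValidReport(rep))

    ml@dataTypeLabel <- "HbO"
    m@nirs[[1]]@data[[1]]@measurementList[[1]] <- ml
    expect_true(isValidReport(validateSnirf(m)))
})

test_that("probe shape rules: wrong column counts and row disagreements", {
    m <- makeMinimalExample()
    m@nirs[[1]]@probe@sourcePos3D <- matrix(1:4 * 1.0, 2L, 2L)  # S x 2, not S x 3
    rep <- validateSnirf(m)
    df <- findings(rep)
    expect_true(any(df$code == "PROBE_DIM_MISMATCH" &
                    df$location == "/nirs1/probe/sourcePos3D"))

    m <- makeMinimalExample()   # one source in 2-D
    m@nirs[[1]]@probe@sourcePos3D <- matrix(1:6 * 1.0, 2L, 3L)  # two in 3-D
    rep <- validateSnirf(m)
    expect_identical(countFindings(rep, "PROBE_DIM_MISMATCH"), 1L)

    m <- makeMinimalExample()
    m@nirs[[1]]@probe@wavelengths <- c(760, -850)
    expect_identical(countFindings(validateSnirf(m), "WAVELENGTHS_INVALID"), 1L)

    m <- makeMinimalExample()
    m@nirs[[1]]@probe@sourcePos2D <- NULL
    expect_identical(countFindings(validateSnirf(m), "POSITIONS_MISSING"), 1L)
})

test_that("time axes are checked for length and monotonicity, aux included", {
    m <- handMadeModel(nT = 6L)
    m@nirs[[1]]@data[[1]]@time <- c(0, 0.2, 0.4)      # 3 values for 6 rows
    rep <- validateSnirf(m)
    df <- findings(rep)
    expect_true(any(df$code == "TIME_LENGTH_MISMATCH" &
                    df$location == "/nirs1/data1/time"))

    m <- handMadeModel(nT = 6L)
    m@nirs[[1]]@data[[1]]@time <- c(0, 0.2, 0.1, 0.3, 0.4, 0.5)
    expect_identical(countFindings(validateSnirf(m), "TIME_NOT_INCREASING"), 1L)

    m <- handMadeModel()
    m@nirs[[1]]@aux <- list(AuxElement("accel", sin(1:10), (0:6) * 0.1))
    rep <- validateSnirf(m)
    df <- findings(rep)
    expect_true(any(df$code == "TIME_LENGTH_MISMATCH" &
                    df$location == "/nirs1/aux1/time"))
})

test_that("an all-empty data block violates the raw-data minimum", {
    m <- makeMinimalExample()
    m@nirs[[1]]@data[[1]] <- DataBlock(matrix(numeric(0), 5L, 0L),
                                       time = c(0, 0.1),
                                       measurementList = list())
    rep <- validateSnirf(m)
    expect_identical(countFindings(rep, "NO_CHANNELS"), 1L)
    expect_false(isValidReport(rep))
})

test_that("validation is deterministic and ordered by location then code", {
    m <- generateSnirf(genSpec(nStim = 2L, seed = 20L))
    m@nirs[[1]]@metadata@tags$SubjectID <- NULL
    m@nirs[[1]]@data[[1]]@time <- c(1, 0.5)
    f <- snirfTempFile()
    writeSnirf(m, f, force = TRUE)
    r1 <- validateSnirf(f); r2 <- validateSnirf(f)
    expect_identical(reportToJson(r1), reportToJson(r2))
    df <- findings(r1)
    expect_false(is.unsorted(df$location))
})

test_that("version strings must parse as semantic versions", {
    for (v in c("1.0", "1.1", "2.0.1", "10.23.4")) {
        m <- makeMinimalExample()
        m@formatVersion <- v
        expect_true(isValidReport(validateSnirf(m)), label = v)
    }
    for (v in c("banana", "1", "v1.0", "1.0-beta", "")) {
        m <- makeMinimalExample()
        m@formatVersion <- v
        expect_false(isValidReport(validateSnirf(m)), label = v)
    }
})

test_that("JSON reports are complete, stable and lossless", {
    emptyRep <- validateSnirf(makeMinimalExample())
    j <- reportToJson(emptyRep)
    doc <- jsonlite::fromJSON(j)
    expect_true(doc$valid)
    expect_length(doc$findings, 0L)

    m <- makeMinimalExample()
    m@nirs[[1]]@metadata@tags$SubjectID <- NULL
    rep <- validateSnirf(m)
    j <- reportToJson(rep)
    doc <- jsonlite::fromJSON(j, simplifyVector = FALSE)
    f1 <- doc$findings[[1]]
    expect_identical(f1$code, "METADATA_MISSING")
    expect_identical(f1$severity, "ERROR")
    expect_identical(f1$location, "/nirs1/metaDataTags")
    expect_true(nzchar(f1$message) && nzchar(f1$spec_ref))

    # serialize -> parse -> serialize is byte-identical
    rep2 <- reportFromJson(j)
    expect_identical(as.character(reportToJson(rep2)), as.character(j))
    expect_identical(findings(rep2), findings(rep))
})

test_that("the finding-code registry covers every defect mapping", {
    reg <- findingCodes()
    expect_true(all(defectRegistry()$findingCode %in% reg$code))
    expect_true(all(reg$severity %in% c("FATAL", "ERROR", "WARNING", "INFO")))
    expect_false(anyDuplicated(reg$code) > 0)
})
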