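test_that("implicit time axes expand to arithmetic progressions", {
    expect_equal(expandTime(c(0, 0.1), 5), c(0, 0.1, 0.2, 0.3, 0.4))
    # last sample of [2.5, 0.125] over 800 points, computed independently
    # as start + (n - 1) * increment = 2.5 + 799 * 0.125
    tt <- expandTime(c(2.5, 0.125), 800)
    expect_length(tt, 800)
    expect_equal(tt[800], 102.375)
    expect_true(all(diff(tt) > 0))
})

test_that("explicit time axes pass through unchanged and are validated", {
    expect_identical(expandTime(c(0, 0.05, 0.2), 3), c(0, 0.05, 0.2))
    # a length-2 axis matching a 2-row block is explicit, not [start, increment]
    expect_identical(expandTime(c(1.5, 1.7), 2), c(1.5, 1.7))
    expect_error(expandTime(c(0, 0.1, 0.05), 3), "strictly increasing")
    expect_error(expandTime(c(0, -0.1), 5), "positive increment")
    expect_error(expandTime(c(0, 0.1, 0.2), 5), "length 3")
})

test_that("expandTime is idempotent on its own output", {
    set.seed(21)
    for (i in 1:25) {
        n <- sample(3:50, 1)
        start <- runif(1, -5, 5)
        inc <- runif(1, 0.001, 2)
        once <- expandTime(c(start, inc), n)
        expect_identical(expandTime(once, n), once)
    }
})

test_that("channelCount returns the column count and enforces agreement", {
    m <- handMadeModel(nChannels = 7L)
    blk <- dataBlocks(nirsElements(m)[[1]])[[1]]
    expect_identical(channelCount(blk), 7L)

    empty <- DataBlock(matrix(numeric(0), 4L, 0L), time = c(0, 0.1),
                       measurementList = list())
    expect_identical(channelCount(empty), 0L)

    bad <- blk
    bad@measurementList <- bad@measurementList[-1]
    expect_error(channelCount(bad), "7 column")
    expect_identical(channelCount(bad, strict = FALSE), 7L)
})

test_that("channel 2 of the worked example resolves to the narrated optode", {
    el <- nirsElements(makeWorkedExample())[[1]]
    cd <- resolveChannel(el, 1, 2)
    expect_identical(cd@wavelength, 830)
    expect_identical(cd@sourcePosition, c(42, -125, 42))
    expect_identical(cd@columnIndex, 2L)
})

test_that("a single-channel file resolves to its sole probe entries", {
    el <- nirsElements(makeMinimalExample())[[1]]
    cd <- resolveChannel(el, 1, 1)
    expect_identical(cd@columnIndex, 1L)
    expect_identical(cd@wavelength, 760)
    expect_identical(cd@sourcePosition, c(0, 0))
    expect_identical(cd@detectorPosition, c(30, 0))
})

test_that("resolution prefers 3-D coordinates when both layouts exist", {
    pr <- Probe(wavelengths = 850,
                sourcePos2D = matrix(c(1, 2), 1L, 2L),
                sourcePos3D = matrix(c(10, 20, 30), 1L, 3L),
                detectorPos2D = matrix(c(3, 4), 1L, 2L),
                detectorPos3D = matrix(c(40, 50, 60), 1L, 3L))
    blk <- DataBlock(matrix(0, 3L, 1L), c(0, 1),
                     list(MeasurementListElement(1L, 1L, 1L)))
    el <- NirsElement(probe = pr, data = list(blk))
    cd <- resolveChannel(el, 1, 1)
    expect_identical(cd@sourcePosition, c(10, 20, 30))
    expect_identical(cd@detectorPosition, c(40, 50, 60))
})

test_that("out-of-range and dangling indices raise errors naming the path", {
    el <- nirsElements(makeWorkedExample())[[1]]
    expect_error(resolveChannel(el, 3, 1), "block index 3")
    expect_error(resolveChannel(el, 1, 9), "channel index 9")
    # dangling cross-reference: wavelengthIndex beyond the probe array
    bad <- el
    ml <- bad@data[[1]]@measurementList[[2]]
    ml@wavelengthIndex <- 5L
    bad@data[[1]]@measurementList[[2]] <- ml
    expect_error(resolveChannel(bad, 1, 2), "wavelengthIndex = 5")
})

test_that("resolution agrees with the brute-force channel table", {
    m <- generateSnirf(genSpec(nSources = 4L, nDetectors = 4L,
                               wavelengths = c(760, 850),
                               durationS = 2, seed = 31L))
    el <- nirsElements(m)[[1]]
    for (b in seq_along(dataBlocks(el))) {
        tab <- oracleChannelTable(el, b)
        for (k in seq_along(tab)) {
            cd <- resolveChannel(el, b, k)
            expect_identical(cd@sourcePosition, tab[[k]]$sourcePosition)
            expect_identical(cd@detectorPosition, tab[[k]]$detectorPosition)
            expect_identical(cd@wavelength, tab[[k]]$wavelength)
            expect_identical(cd@columnIndex, tab[[k]]$columnIndex)
        }
    }
})

test_that("operations do not mutate their inputs", {
    m <- makeWorkedExample()
    before <- m
    el <- nirsElements(m)[[1]]
    invisible(resolveChannel(el, 1, 2))
    invisible(channelCount(dataBlocks(el)[[1]]))
    invisible(validateSnirf(m))
    invisible(corruptSnirf(generateSnirf(genSpec(nStim = 2L, seed = 20L)),
                           "missing_metadata"))
    expect_true(snirfIdentical(m, before))
})

test_that("models decompose into the parts they were built from", {
    pr <- Probe(wavelengths = c(690, 830),
                sourcePos3D = matrix(1:6 * 1.0, 2L, 3L),
                detectorPos3D = matrix(7:9 * 1.0, 1L, 3L))
    md <- MetaDataTags(SubjectID = "s1", Site = "lab")
    blk <- DataBlock(matrix(1:8 * 1.0, 4L, 2L), c(0, 0.5),
                     list(MeasurementListElement(1L, 1L, 1L),
                          MeasurementListElement(2L, 1L, 2L)))
    st <- StimElement("taps", matrix(c(1, 2, 1), 1L, 3L))
    ax <- AuxElement("accel_x", sin(1:5), (0:4) * 0.1)
    m <- SnirfFile(NirsElement(metadata = md, probe = pr, data = list(blk),
                               stim = list(st), aux = list(ax)))
    el <- nirsElements(m)[[1]]
    expect_true(snirfIdentical(probe(el), pr))
    expect_true(snirfIdentical(dataBlocks(el)[[1]], blk))
    expect_true(snirfIdentical(stimElements(el)[[1]], st))
    expect_true(snirfIdentical(auxElements(el)[[1]], ax))
    expect_identical(metaDataTags(el)$Site, "lab")
    expect_identical(formatVersion(m), "1.0")
    expect_identical(wavelengths(probe(el)), c(690, 830))
})
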