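test_that("write/read round-trips a rich model exactly", {
    m <- generateSnirf(genSpec(nSources = 3L, nDetectors = 2L, nBlocks = 2L,
                               samplingRateHz = c(10, 25), durationS = 2,
                               nStim = 2L, nAux = 2L, seed = 7L))
    f <- snirfTempFile()
    writeSnirf(m, f)
    m2 <- readSnirf(f)
    expect_true(snirfIdentical(m, m2))
    # user metadata tags survive byte-exactly
    expect_identical(metaDataTags(nirsElements(m2)[[1]])$GeneratorSeed, "7")
})

test_that("unknown datasets inside recognised groups survive a round-trip", {
    m <- handMadeModel()
    el <- nirsElements(m)[[1]]
    el@probe@extra <- list(frontalLandmark = c(1.5, 2.5, 3.5),
                           montageName = "custom-cap")
    el@extra <- list(vendor = list(serial = "A-17", gains = c(1L, 2L, 4L)))
    el@metadata@tags$UnstructuredNote <- "précis ✓"
    m@nirs[[1]] <- el
    f <- snirfTempFile()
    writeSnirf(m, f)
    m2 <- readSnirf(f, permissive = TRUE)
    el2 <- nirsElements(m2)[[1]]
    expect_identical(el2@probe@extra$frontalLandmark, c(1.5, 2.5, 3.5))
    expect_identical(el2@probe@extra$montageName, "custom-cap")
    expect_identical(el2@extra$vendor$serial, "A-17")
    expect_identical(el2@extra$vendor$gains, c(1L, 2L, 4L))
    expect_identical(metaDataTags(el2)$UnstructuredNote, "précis ✓")
    expect_true(snirfIdentical(m, m2))
})

test_that("collections are ordered by index, not HDF5 iteration order", {
    f <- snirfTempFile()
    rhdf5::h5createFile(f)
    fid <- rhdf5::H5Fopen(f)
    rhdf5::h5write("1.0", fid, "formatVersion")
    # create in shuffled order: nirs2 before nirs1, stim groups reversed
    for (nm in c("nirs2", "nirs1")) {
        sub <- generateSnirf(genSpec(seed = if (nm == "nirs2") 2L else 1L,
                                     durationS = 1, nStim = 3L))
        rhdf5::H5Fclose(fid)
        # write each element under its explicit name via a scratch model file,
        # then move the group into place
        tmp <- tempfile(fileext = ".snirf")
        writeSnirf(sub, tmp)
        tfid <- rhdf5::H5Fopen(tmp)
        fid <- rhdf5::H5Fopen(f)
        rhdf5::H5Ocopy(tfid, "nirs", fid, nm)
        rhdf5::H5Fclose(tfid)
        file.remove(tmp)
    }
    rhdf5::H5Fclose(fid)
    m <- readSnirf(f)
    expect_length(nirsElements(m), 2L)
    expect_identical(metaDataTags(nirsElements(m)[[1]])$GeneratorSeed, "1")
    expect_identical(metaDataTags(nirsElements(m)[[2]])$GeneratorSeed, "2")
    # stim1..stim3 arrive in index order within each element
    expect_identical(
        vapply(stimElements(nirsElements(m)[[1]]), function(s) s@name,
               character(1)),
        c("cond1", "cond2", "cond3"))
})

test_that("bare and 1-suffixed singleton groups are both accepted", {
    m <- makeMinimalExample()
    f <- snirfTempFile()
    writeSnirf(m, f)                       # writes the bare "nirs" group
    expect_identical(rhdf5::h5ls(f)$name[1], "formatVersion")
    expect_true("nirs" %in% rhdf5::h5ls(f)$name)
    expect_length(nirsElements(readSnirf(f)), 1L)

    # same content under "nirs1"
    f2 <- snirfTempFile()
    rhdf5::h5createFile(f2)
    fid <- rhdf5::H5Fopen(f2); sfid <- rhdf5::H5Fopen(f)
    rhdf5::h5write("1.0", fid, "formatVersion")
    rhdf5::H5Ocopy(sfid, "nirs", fid, "nirs1")
    rhdf5::H5Fclose(fid); rhdf5::H5Fclose(sfid)
    m2 <- readSnirf(f2)
    expect_true(snirfIdentical(m, m2))
})

test_that("bare plus indexed names in one collection are a naming collision", {
    m <- makeMinimalExample()
    m@nirs[[1]]@stim <- list(StimElement("a", matrix(c(1, 1, 1), 1L, 3L)),
                             StimElement("b", matrix(c(2, 1, 1), 1L, 3L)))
    f <- snirfTempFile()
    writeSnirf(m, f)
    fid <- rhdf5::H5Fopen(f)
    rhdf5::H5Lmove(fid, "nirs/stim2", fid, "nirs/stim")
    rhdf5::H5Fclose(fid)
    rep <- validateSnirf(f)
    df <- findings(rep)
    expect_true(any(df$code == "BAD_INDEX_NAME" & df$location == "/nirs/stim"))
    expect_error(readSnirf(f), "BAD_INDEX_NAME")
})

test_that("non-HDF5 input is a format error, not a crash", {
    f <- snirfTempFile()
    writeLines("this is not an HDF5 container", f)
    expect_error(readSnirf(f), "not an HDF5 container")
    rep <- validateSnirf(f)
    df <- findings(rep)
    expect_identical(df$code, "NOT_HDF5")
    expect_identical(df$severity, "FATAL")
    expect_false(isValidReport(rep))
})

test_that("a file without formatVersion reads permissively but not strictly", {
    m <- makeMinimalExample()
    f <- snirfTempFile()
    writeSnirf(m, f)
    fid <- rhdf5::H5Fopen(f)
    rhdf5::H5Ldelete(fid, "formatVersion")
    rhdf5::H5Fclose(fid)
    expect_error(readSnirf(f), "VERSION_MISSING")
    m2 <- readSnirf(f, permissive = TRUE)
    expect_length(nirsElements(m2), 1L)
    expect_identical(countFindings(validateSnirf(f), "VERSION_MISSING"), 1L)
})

test_that("files are C-order faithful: h5py sees time x channels", {
    py <- Sys.which("python")
    expect_true(nzchar(py))
    m <- makeWorkedExample()     # 100 samples x 2 channels
    f <- snirfTempFile()
    writeSnirf(m, f)
    out <- system2(py, c("-c", shQuote(paste0(
        "import h5py; f = h5py.File('", f, "', 'r'); ",
        "d = f['nirs/data1/dataTimeSeries']; ",
        "print(d.shape[0], d.shape[1], round(float(d[0, 1]), 6), ",
        "f['formatVersion'][0].decode())"))), stdout = TRUE)
    # channel 2 at t = 0 is 1.2 + 0.04 * sin(0.5)
    expect_identical(out,
                     paste("100 2", round(1.2 + 0.04 * sin(0.5), 6), "1.0"))
})

test_that("files written by h5py (C-order, fixed-length strings) read back", {
    py <- Sys.which("python")
    expect_true(nzchar(py))
    f <- snirfTempFile()
    script <- paste0(
        "import h5py, numpy as np\n",
        "f = h5py.File('", f, "', 'w')\n",
        "f['formatVersion'] = '1.0'\n",
        "g = f.create_group('nirs')\n",
        "md = g.create_group('metaDataTags')\n",
        "for k, v in [('SubjectID', 'py-sub'), ('MeasurementDate', '2024-01-01'),\n",
        "             ('MeasurementTime', '08:00:00'), ('LengthUnit', 'mm'),\n",
        "             ('TimeUnit', 's'), ('FrequencyUnit', 'Hz')]:\n",
        "    md[k] = np.bytes_(v)\n",   # fixed-length byte strings
        "p = g.create_group('probe')\n",
        "p['wavelengths'] = np.array([760.0, 850.0])\n",
        "p['sourcePos3D'] = np.array([[1.0, 2.0, 3.0]])\n",
        "p['detectorPos3D'] = np.array([[4.0, 5.0, 6.0]])\n",
        "d = g.create_group('data1')\n",
        "d['dataTimeSeries'] = np.arange(8.0).reshape(4, 2)\n",
        "d['time'] = np.array([0.0, 0.5])\n",
        "for i, w in [(1, 1), (2, 2)]:\n",
        "    ml = d.create_group('measurementList%d' % i)\n",
        "    ml['sourceIndex'] = np.int32(1); ml['detectorIndex'] = np.int32(1)\n",
        "    ml['wavelengthIndex'] = np.int32(w); ml['dataType'] = np.int64(1)\n",
        "f.close()\n")
    scriptFile <- withr::local_tempfile(fileext = ".py")
    writeLines(script, scriptFile)
    expect_identical(system2(py, scriptFile), 0L)
    m <- readSnirf(f)
    expect_true(isValidReport(validateSnirf(f)))
    el <- nirsElements(m)[[1]]
    expect_identical(metaDataTags(el)$SubjectID, "py-sub")
    blk <- dataBlocks(el)[[1]]
    expect_identical(dim(dataTimeSeries(blk)), c(4L, 2L))
    # row-major 0..7 reshaped (4, 2): second column is the odd values
    expect_identical(dataTimeSeries(blk)[, 2], c(1, 3, 5, 7))
    # int32/int64 index fields coerce to R integers
    expect_identical(measurementList(blk)[[2]]@wavelengthIndex, 2L)
    cd <- resolveChannel(el, 1, 2)
    expect_identical(cd@wavelength, 850)
})
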