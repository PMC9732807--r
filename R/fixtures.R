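# Synthetic continuous-wave fixtures. The signal model is deliberately
# simple — baseline + sinusoidal physiology (cardiac and respiratory bands) +
# Gaussian noise + stimulus-locked boxcar responses — because these fixtures
# exist to exercise structure (indexed groups, cross-references, per-block
# clocks), not to emulate haemodynamics.

# evaluate f() under a fixed RNG state without disturbing the caller's stream
.withSeed <- function(seed, f) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    f()
}

#' The smallest compliant SNIRF model
#'
#' One source, one detector, one wavelength, a single two-sample data block
#' and the six required metadata tags: the minimum a file must contain (at
#' least one series of raw data plus a probe description).
#'
#' @return A [SnirfFile-class] that passes [validateSnirf()].
#' @export
makeMinimalExample <- function() {
    pr <- Probe(wavelengths = 760,
                sourcePos2D = matrix(c(0, 0), 1L, 2L),
                detectorPos2D = matrix(c(30, 0), 1L, 2L))
    ml <- list(MeasurementListElement(1L, 1L, 1L))
    blk <- DataBlock(matrix(c(1, 1.01), 2L, 1L), time = c(0, 0.1),
                     measurementList = ml)
    SnirfFile(NirsElement(metadata = MetaDataTags(SubjectID = "minimal"),
                          probe = pr, data = list(blk)))
}

#' The worked-example fixture
#'
#' A deterministic two-channel continuous-wave recording built so that
#' resolving channel 2 of block 1 through the probe reproduces the canonical
#' worked example of the format: `measurementList2` points via its
#' `sourceIndex` at the optode with 3-D coordinate `[42, -125, 42]` and via
#' its `wavelengthIndex` at the nominal wavelength 830 nm.
#'
#' @return A [SnirfFile-class] that passes [validateSnirf()].
#' @examples
#' el <- nirsElements(makeWorkedExample())[[1]]
#' resolveChannel(el, 1, 2)
#' @export
makeWorkedExample <- function() {
    pr <- Probe(
        wavelengths    = c(690, 830),
        sourcePos3D    = matrix(c(30, -120, 35,
                                  42, -125, 42), 2L, 3L, byrow = TRUE),
        detectorPos3D  = matrix(c(36, -115, 30), 1L, 3L),
        sourceLabels   = c("S1", "S2"),
        detectorLabels = "D1")
    ml <- list(
        MeasurementListElement(1L, 1L, 1L, dataUnit = "V"),
        MeasurementListElement(2L, 1L, 2L, dataUnit = "V"))
    t <- (0:99) * 0.1
    dts <- cbind(1 + 0.05 * sin(2 * pi * 0.2 * t),
                 1.2 + 0.04 * sin(2 * pi * 0.25 * t + 0.5))
    blk <- DataBlock(dts, time = c(0, 0.1), measurementList = ml)
    stim <- StimElement("tapping",
                        matrix(c(2, 2, 1,
                                 6, 2, 1), 2L, 3L, byrow = TRUE))
    SnirfFile(NirsElement(
        metadata = MetaDataTags(SubjectID = "worked-example",
                                MeasurementDate = "2022-12-09",
                                MeasurementTime = "12:00:00"),
        probe = pr, data = list(blk), stim = list(stim)))
}

.gridPositions <- function(n, x0, y0, spacing = 30) {
    g <- ceiling(sqrt(n))
    idx <- seq_len(n) - 1L
    x <- x0 + (idx %% g) * spacing
    y <- y0 + (idx %/% g) * spacing
    cbind(x, y, deparse.level = 0)
}

#' Generate a synthetic SNIRF recording
#'
#' Builds a seed-deterministic continuous-wave model from a
#' [SnirfGenSpec-class]: optodes laid out on a 30 mm grid (detectors offset
#' by half a pitch), channels enumerated over all source x detector x
#' wavelength triples in source-major order, and per-channel signals
#' composed of a baseline, cardiac (~1.1 Hz) and respiratory (~0.3 Hz)
#' sinusoids, Gaussian noise and a boxcar response locked to the onsets of
#' the first stimulus condition. Blocks run on independent clocks: each has
#' its own sampling rate and a small random onset, and blocks alternate
#' between the implicit `[start, increment]` and the explicit time-axis
#' encoding so both forms are exercised. Repeated calls with the same
#' specification (including its seed) return identical models.
#'
#' @param spec A [SnirfGenSpec-class]; see [genSpec()].
#' @return A [SnirfFile-class] that passes [validateSnirf()].
#' @examples
#' m <- generateSnirf(genSpec(nSources = 2, nDetectors = 2, seed = 7))
#' @export
generateSnirf <- function(spec) {
    stopifnot(is(spec, "SnirfGenSpec"))
    validObject(spec)
    .withSeed(spec@seed, function() {
        nS <- spec@nSources; nD <- spec@nDetectors
        wl <- spec@wavelengths; nW <- length(wl)

        src2 <- .gridPositions(nS, 0, 0)
        det2 <- .gridPositions(nD, 15, 15)
        dome <- function(p) 60 + 5 * sin(p[, 1L] / 30) + 5 * cos(p[, 2L] / 30)
        pr <- Probe(
            wavelengths = wl,
            sourcePos2D = src2,
            sourcePos3D = cbind(src2, dome(src2), deparse.level = 0),
            detectorPos2D = det2,
            detectorPos3D = cbind(det2, dome(det2), deparse.level = 0),
            sourceLabels = paste0("S", seq_len(nS)),
            detectorLabels = paste0("D", seq_len(nD)))

        # source-major, then detector, then wavelength
        mls <- list()
        for (s in seq_len(nS)) for (d in seq_len(nD)) for (w in seq_len(nW))
            mls[[length(mls) + 1L]] <- MeasurementListElement(
                s, d, w, dataType = 1L, dataUnit = "V")
        nCh <- length(mls)

        stim <- lapply(seq_len(spec@nStim), function(k) {
            nE <- max(1L, as.integer(spec@durationS %/% 4))
            onsets <- sort(round(runif(nE, 0, max(spec@durationS - 2, 0.5)), 3))
            StimElement(sprintf("cond%d", k),
                        cbind(onsets, rep(2, nE), rep(1, nE),
                              deparse.level = 0))
        })

        blocks <- lapply(seq_len(spec@nBlocks), function(j) {
            rate <- spec@samplingRateHz[j]
            start <- if (j == 1L) 0 else round(runif(1, 0, 0.5), 3)
            nT <- max(4L, as.integer(floor(spec@durationS * rate)))
            tt <- start + (seq_len(nT) - 1L) / rate
            base <- 1000 + 50 * runif(nCh)
            card <- 8 * runif(nCh); resp <- 4 * runif(nCh)
            dts <- matrix(0, nT, nCh)
            box <- numeric(nT)
            if (length(stim)) {
                s1 <- stim[[1L]]@data
                for (e in seq_len(nrow(s1)))
                    box <- box + (tt >= s1[e, 1L] & tt < s1[e, 1L] + s1[e, 2L])
            }
            for (c in seq_len(nCh))
                dts[, c] <- base[c] +
                    card[c] * sin(2 * pi * 1.1 * tt) +
                    resp[c] * sin(2 * pi * 0.3 * tt) +
                    5 * box + rnorm(nT, sd = 2)
            DataBlock(dts,
                      time = if (j %% 2L == 1L) c(start, 1 / rate) else tt,
                      measurementList = mls)
        })

        aux <- lapply(seq_len(spec@nAux), function(k) {
            rate <- 20 + 5 * k
            nT <- max(4L, as.integer(floor(spec@durationS * rate)))
            tt <- (seq_len(nT) - 1L) / rate
            AuxElement(sprintf("accel_%s", letters[(k - 1L) %% 26L + 1L]),
                       sin(2 * pi * 0.5 * tt) + rnorm(nT, sd = 0.1),
                       time = tt)
        })

        md <- MetaDataTags(
            SubjectID = sprintf("sim-%04d", spec@seed %% 10000L),
            MeasurementDate = "2024-01-15",
            MeasurementTime = "10:00:00",
            GeneratorSeed = as.character(spec@seed))
        SnirfFile(NirsElement(metadata = md, probe = pr, data = blocks,
                              stim = stim, aux = aux))
    })
}

#' The defect registry of the corruptor
#'
#' One row per defect [corruptSnirf()] can seed, the validator code expected
#' to flag it, and whether the defect is introduced in the in-memory model or
#' by tampering with a written file (naming and deletion defects cannot be
#' represented in the model, whose collections are contiguous lists by
#' construction).
#'
#' @return Data frame with columns `defect`, `findingCode`, `level`.
#' @export
defectRegistry <- function() {
    read.table(text = '
missing_metadata         METADATA_MISSING        model
index_out_of_range       INDEX_OUT_OF_RANGE      model
list_length_mismatch     LIST_LENGTH_MISMATCH    model
time_length_mismatch     TIME_LENGTH_MISMATCH    model
time_not_increasing      TIME_NOT_INCREASING     model
transposed_data          LIST_LENGTH_MISMATCH    model
bad_format_version       VERSION_UNPARSEABLE     model
missing_data_type_label  DATA_TYPE_LABEL_MISSING model
noncontiguous_index      NONCONTIGUOUS_INDEX     file
zero_padded_name         BAD_INDEX_NAME          file
missing_probe            PROBE_MISSING           file
missing_nirs             NIRS_MISSING            file
', col.names = c("defect", "findingCode", "level"), stringsAsFactors = FALSE)
}

.firstElementName <- function(model) {
    if (length(model@nirs) == 1L) "nirs" else "nirs1"
}

#' Seed exactly one defect into a valid model
#'
#' Takes a compliant model and introduces a single named defect from
#' [defectRegistry()], returning the corrupted target together with the HDF5
#' path at which [validateSnirf()] must report it and the expected finding
#' code. Model-level defects return a modified [SnirfFile-class]; naming and
#' deletion defects write the model to disk and tamper with the container
#' (via HDF5 link operations), returning the file path.
#'
#' @param model A compliant [SnirfFile-class] (for `noncontiguous_index` it
#'   must carry at least two stimulus groups, for `zero_padded_name` at least
#'   one).
#' @param defect Defect code; see [defectRegistry()].
#' @param seed Integer controlling arbitrary choices (e.g. which required
#'   tag is removed).
#' @param path Output path for file-level defects (a temporary file by
#'   default).
#' @return List with `target` (model or file path), `location` (expected
#'   report location) and `code` (expected finding code).
#' @export
corruptSnirf <- function(model, defect, seed = 1L,
                         path = tempfile(fileext = ".snirf")) {
    stopifnot(is(model, "SnirfFile"))
    reg <- defectRegistry()
    if (!defect %in% reg$defect)
        stop("unknown defect code '", defect, "'; see defectRegistry()",
             call. = FALSE)
    code <- reg$findingCode[reg$defect == defect]
    el <- model@nirs[[1L]]

    if (defect %in% c("noncontiguous_index", "zero_padded_name",
                      "missing_probe", "missing_nirs")) {
        writeSnirf(model, path)
        nm <- .firstElementName(model)
        fid <- rhdf5::H5Fopen(path)
        on.exit(rhdf5::H5Fclose(fid))
        loc <- switch(defect,
            noncontiguous_index = {
                if (length(el@stim) < 2L)
                    stop("noncontiguous_index needs a model with >= 2 stim groups",
                         call. = FALSE)
                rhdf5::H5Lmove(fid, paste0(nm, "/stim2"),
                               fid, paste0(nm, "/stim4"))
                sprintf("/%s/stim", nm)
            },
            zero_padded_name = {
                if (length(el@stim) < 1L)
                    stop("zero_padded_name needs a model with >= 1 stim group",
                         call. = FALSE)
                rhdf5::H5Lmove(fid, paste0(nm, "/stim1"),
                               fid, paste0(nm, "/stim01"))
                sprintf("/%s/stim01", nm)
            },
            missing_probe = {
                rhdf5::H5Ldelete(fid, paste0(nm, "/probe"))
                sprintf("/%s/probe", nm)
            },
            missing_nirs = {
                n <- length(model@nirs)
                for (i in seq_len(n))
                    rhdf5::H5Ldelete(fid, if (n == 1L) "nirs"
                                          else renderIndexedName("nirs", i))
                "/"
            })
        return(list(target = path, location = loc, code = code))
    }

    blk <- el@data[[1L]]
    out <- switch(defect,
        missing_metadata = {
            tag <- .REQUIRED_TAGS[1L + (as.integer(seed) %% length(.REQUIRED_TAGS))]
            el@metadata@tags[[tag]] <- NULL
            list(loc = "/nirs1/metaDataTags")
        },
        index_out_of_range = {
            k <- length(blk@measurementList)
            ml <- blk@measurementList[[k]]
            ml@wavelengthIndex <- length(el@probe@wavelengths) + 1L
            blk@measurementList[[k]] <- ml
            el@data[[1L]] <- blk
            list(loc = sprintf("/nirs1/data1/measurementList%d/wavelengthIndex", k))
        },
        list_length_mismatch = {
            blk@measurementList <- blk@measurementList[-length(blk@measurementList)]
            el@data[[1L]] <- blk
            list(loc = "/nirs1/data1")
        },
        time_length_mismatch = {
            tt <- expandTime(blk@time, nrow(blk@dataTimeSeries))
            blk@time <- tt[seq_len(length(tt) - 1L)]
            el@data[[1L]] <- blk
            list(loc = "/nirs1/data1/time")
        },
        time_not_increasing = {
            tt <- expandTime(blk@time, nrow(blk@dataTimeSeries))
            tt[c(2L, 3L)] <- tt[c(3L, 2L)]
            blk@time <- tt
            el@data[[1L]] <- blk
            list(loc = "/nirs1/data1/time")
        },
        transposed_data = {
            if (nrow(blk@dataTimeSeries) == ncol(blk@dataTimeSeries))
                stop("transposed_data needs a non-square data matrix",
                     call. = FALSE)
            blk@dataTimeSeries <- t(blk@dataTimeSeries)
            el@data[[1L]] <- blk
            list(loc = "/nirs1/data1")
        },
        bad_format_version = {
            model@formatVersion <- "not.a/version"
            list(loc = "/formatVersion")
        },
        missing_data_type_label = {
            ml <- blk@measurementList[[1L]]
            ml@dataType <- 99999L
            ml@dataTypeLabel <- NULL
            blk@measurementList[[1L]] <- ml
            el@data[[1L]] <- blk
            list(loc = "/nirs1/data1/measurementList1/dataTypeLabel")
        })
    if (defect != "bad_format_version") model@nirs[[1L]] <- el
    list(target = model, location = out$loc, code = code)
}

#' Emit a fixture corpus to a directory
#'
#' Writes one valid file plus one corrupted file per defect in
#' [defectRegistry()] under `dir/valid/` and `dir/corrupted/<defect>/`, and
#' returns the manifest. Used by the `selftest` command and handy for
#' exercising other SNIRF implementations.
#'
#' @param dir Output directory (created if needed).
#' @param spec Generator specification for the base recording; it must yield
#'   at least two stimulus groups.
#' @return Data frame with columns `defect` (`"<valid>"` for the clean
#'   file), `path`, `location`, `code`.
#' @export
writeFixtureCorpus <- function(dir, spec = genSpec(nStim = 2L, seed = 20L)) {
    model <- generateSnirf(spec)
    dir.create(file.path(dir, "valid"), recursive = TRUE, showWarnings = FALSE)
    validPath <- file.path(dir, "valid", "recording.snirf")
    writeSnirf(model, validPath)
    manifest <- data.frame(defect = "<valid>", path = validPath,
                           location = "", code = "", stringsAsFactors = FALSE)
    for (d in defectRegistry()$defect) {
        sub <- file.path(dir, "corrupted", d)
        dir.create(sub, recursive = TRUE, showWarnings = FALSE)
        p <- file.path(sub, "recording.snirf")
        cr <- corruptSnirf(model, d, path = p)
        loc <- cr$location
        if (is(cr$target, "SnirfFile")) {
            writeSnirf(cr$target, p, force = TRUE)
            # model-level locations use canonical names; a singleton element
            # is written as the bare "nirs" group
            if (length(cr$target@nirs) == 1L)
                loc <- sub("^/nirs1(/|$)", "/nirs\\1", loc)
        }
        manifest <- rbind(manifest, data.frame(
            defect = d, path = p, location = loc, code = cr$code,
            stringsAsFactors = FALSE))
    }
    manifest
}
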