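# snirfio

Read, write, validate and synthesise **SNIRF** files — the Shared
Near-Infrared Spectroscopy Format, the community HDF5 container for
functional near-infrared spectroscopy (fNIRS) recordings — from R.

fNIRS data pair time × channel intensity matrices with the probe geometry
that produced them: each channel is one source–detector–wavelength
combination, and the file's *measurement list* links every column of
`dataTimeSeries` to the probe's coordinate and wavelength arrays through
1-based indices. `snirfio` is for anyone who needs to get such files into
or out of R losslessly, check files from any acquisition system for
specification compliance, or build reproducible synthetic fixtures for
testing other SNIRF tooling. It provides:

* an S4 in-memory model (`SnirfFile`, `NirsElement`, `Probe`, `DataBlock`,
  `MeasurementListElement`, ...) with accessors and channel resolution
  (`resolveChannel()`) through the probe arrays;
* a lossless HDF5 reader/writer (`readSnirf()`, `writeSnirf()`) honouring
  the 1-based indexed-group convention (`stim1`, `stim2`, ...), exact
  numeric round trips, and byte-exact preservation of user metadata and
  unrecognised datasets;
* a rule-based compliance validator (`validateSnirf()`) with
  severity-graded findings, stable codes, HDF5 locations, and a JSON
  report schema (`reportToJson()`);
* a seed-deterministic synthetic generator (`generateSnirf()`) and a
  single-defect corruptor (`corruptSnirf()`) covering every validation
  rule with no external downloads;
* a command line: `snirf validate | info | create-example | export |
  selftest` (function `snirfCli()`, wrapper script in `inst/cli/`).

## Worked example

The format's canonical worked example: the second measurement-list entry
of a data block points, via `sourceIndex` and `wavelengthIndex`, into the
probe's `sourcePos3D` and `wavelengths` arrays — so channel 2 of the data
matrix was produced at the optode at [42, −125, 42] by an 830 nm source.

```r
library(snirfio)

m <- makeWorkedExample()
m
#> SnirfFile (formatVersion 1.0) with 1 recording element(s)
#>   nirs1: subject worked-example, 1 data block(s), 1 stim, 0 aux

writeSnirf(m, "example.snirf")
el <- nirsElements(readSnirf("example.snirf"))[[1]]

resolveChannel(el, blockIndex = 1, channelIndex = 2)
#> Channel 2: source [42, -125, 42] -> detector [36, -115, 30], 830 nm, dataType 1

validateSnirf("example.snirf")
#> ValidationReport: VALID (0 finding(s))
```

The resolved wavelength (830 nm) and source position are the probe-array
entries selected by the channel's 1-based indices; a dangling index would
instead surface as an `INDEX_OUT_OF_RANGE` finding at the offending HDF5
path. Seeding a defect shows the validator's machine-readable side:

```r
cr <- corruptSnirf(generateSnirf(genSpec(nStim = 2, seed = 20)),
                   "noncontiguous_index")
findings(validateSnirf(cr$target))
#>                  code severity   location
#> 1 NONCONTIGUOUS_INDEX    ERROR /nirs/stim
#>                                                                                   message
#> 1 'stim' collection has indices {1, 4}; indexed groups must be numbered 1..2 without gaps
#>          specRef
#> 1 indexed-groups
```

See `findingCodes()` for the full code registry and
`vignettes/snirf-io-and-validation.Rmd` for the design of the model,
validator, generator and corruptor.

## Command line

```sh
snirf validate recording.snirf --json report.json   # exit 0 valid / 1 errors / 2 unreadable
snirf info recording.snirf
snirf create-example worked example.snirf
snirf export recording.snirf channels.tsv --block 1
snirf selftest                                      # full defect-detection matrix
```

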