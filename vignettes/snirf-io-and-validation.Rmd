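---
title: "SNIRF I/O and compliance validation: the model behind snirfio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNIRF I/O and compliance validation: the model behind snirfio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snirfio)
```

## The format and the in-memory model

Functional near-infrared spectroscopy (fNIRS) measures light attenuation
between *source* and *detector* optodes on the scalp; one
source–detector–wavelength combination is a *channel*. The Shared NIRS
Format (SNIRF) stores such recordings in an HDF5 container whose root holds
a `formatVersion` string and one or more `nirs` recording elements. Each
element carries metadata tags, a probe description (optode coordinates and
nominal wavelengths), and indexed collections of data blocks, stimulus
descriptors and auxiliary signals.

`snirfio` mirrors this hierarchy with S4 classes — `SnirfFile`,
`NirsElement`, `Probe`, `DataBlock`, `MeasurementListElement`,
`StimElement`, `AuxElement` — plus `ValidationReport`/`Finding` for the
compliance layer. Two design rules shape the classes:

* **Validity methods check types and shapes only.** Whether an object is
  *compliant* (indices in bounds, tags present, monotone time) is the
  validator's job, not the class's. This separation is what lets the
  package represent damaged files, report on them, and deliberately
  construct broken fixtures for testing.
* **All indices are 1-based end to end.** Probe references
  (`sourceIndex`, `detectorIndex`, `wavelengthIndex`) are stored exactly as
  the format defines them; conversion to R's indexing happens only at the
  array-access boundary inside `resolveChannel()`.

## Indexed groups

Repeatable groups share a base name with 1-based decimal suffixes
(`stim1`, `stim2`, `stim3`); a bare base name is legal only for a
singleton. `parseIndexedName()` splits the maximal trailing digit run and
rejects zero-padded indices (`stim01`), and the reader orders collections
by numeric index regardless of HDF5 iteration order, so files created with
groups in any order load identically.

The writer emits a single recording element as the bare `nirs` group —
the layout most vendor exports use for single-subject files — while data
blocks, stimulus groups, auxiliary groups and measurement-list entries
always carry their index (`data1`, `stim1`, `measurementList1`). The
reader accepts both bare and `1`-suffixed singletons everywhere, for
interoperability with either convention.

## Channel resolution and the measurement list

A data block is a time × channel matrix; its measurement list holds one
descriptor per column with indices into the probe arrays.
`resolveChannel()` follows those indices to actual coordinates and the
nominal wavelength:

```{r}
el <- nirsElements(makeWorkedExample())[[1]]
resolveChannel(el, blockIndex = 1, channelIndex = 2)
```

When a probe stores both 2-D (flattened layout) and 3-D (digitised)
coordinates, the 3-D ones are returned: they are the physically meaningful
positions, and the canonical worked example of the format narrates the 3-D
case. The format describes the source-side lookup explicitly and notes the
detector side is analogous; `snirfio` mirrors the behaviour exactly for
`detectorIndex`.

## Time axes

Blocks and auxiliary signals in one file may run on unrelated clocks
(different rates *and* onsets), so every block carries its own axis in one
of two encodings: an explicit vector of sample times, or the implicit
uniform form `c(start, increment)`. `expandTime()` normalises both. The
two encodings collide for a block with exactly two samples; `snirfio`
resolves the ambiguity in favour of the explicit reading whenever the axis
length equals the row count, because that interpretation is the only one
consistent for every other length. Explicit axes must be strictly
increasing; the implicit increment must be positive.

## Required metadata

The format requires a subject identifier, the acquisition date and time,
and the measurement units. The concrete tag spellings enforced here —
`SubjectID`, `MeasurementDate`, `MeasurementTime`, `LengthUnit`,
`TimeUnit`, `FrequencyUnit` — follow the public format specification, fixed
in one place (`findingCodes()` documents the rule's code) so validation is
deterministic. Arbitrary further tags are allowed and survive a
read–write cycle byte-exactly, as does any unrecognised dataset inside a
recognised group (kept in the `extra` slot of its parent): a
self-describing file should never be silently thinned by a tool.

## The validator

`validateSnirf()` runs a fixed rule battery — minimum content (≥ 1
recording element with ≥ 1 data block and a probe), required tags,
measurement-list length versus column count, probe index bounds, time-axis
length and monotonicity, probe array shapes, indexed-group contiguity and
naming, `formatVersion` parseability, data-type registry membership — and
returns findings ordered by location then code, so identical input yields
a byte-identical report.

Severity grading is a design choice of this package: specification
violations are `ERROR`; interoperability risks are `WARNING`; only an
unreadable container is `FATAL`. Two judgement calls deserve note:

* **Unknown `dataType` codes are warnings, not errors.** The format
  reserves room for frequency-domain, time-domain and correlation
  modalities without an exhaustive public code registry; the registry known
  here (1 = raw continuous-wave amplitude, 99999 = processed + label)
  covers what this package can interpret, and anything else is flagged but
  tolerated.
* **A zero-channel block is an error.** The minimum-file rule demands at
  least one series of raw data; an empty matrix with an empty measurement
  list satisfies the letter of the length-match rule but not that minimum.

Contiguity and naming rules are checked on files, not in-memory models:
the model's collections are contiguous R lists by construction, so a gap
(`stim1`, `stim3`) or a zero-padded name can only exist on disk. The
validator never repairs anything; it is a pure function of the file bytes.

Reports serialise to a stable JSON schema
(`inst/schema/validation-report.schema.json`); serialise → parse →
serialise is byte-identical, so archived reports can be diffed.

## Writer conventions

Floating-point data are stored as 64-bit doubles, index fields as native
signed integers, strings as variable-length UTF-8 (the reader also accepts
fixed-length byte strings, a common vendor dialect). No compression is
applied, but chunked/compressed input is read transparently. R stores
matrices column-major while HDF5 is row-major; `snirfio` transposes 2-D
datasets at the I/O boundary so that C-order tools (h5py, MATLAB) see
`dataTimeSeries` as time × channels, byte-compatible with files produced
by the reference Python tooling — verified in the test suite by reading
`snirfio`-written files with h5py and vice versa. No auto-transposition is
attempted on read: a transposed matrix in a foreign file surfaces as a
length-mismatch finding rather than a silent guess.

`writeSnirf()` refuses non-compliant models unless `force = TRUE`; forcing
exists precisely so the corruptor can materialise broken fixtures.

## The synthetic generator and corruptor

`generateSnirf()` emulates the *structure* of a desk-scale continuous-wave
recording, not its physiology: optodes on a 30 mm grid (a typical
inter-optode pitch) with detectors offset by half a pitch; a dome-like z
coordinate for the 3-D arrays; channels enumerated over all
source × detector × wavelength triples in source-major order (a fixed
order keeps expected measurement lists reproducible; a distance cap is
deliberately not applied so channel counts stay trivially predictable);
signals composed of a ~1000-unit baseline, cardiac (1.1 Hz) and
respiratory (0.3 Hz) sinusoids, Gaussian noise (σ = 2 intensity units) and
a 5-unit boxcar locked to the first stimulus condition's onsets. The
default wavelength pair 760/850 nm brackets the haemoglobin isosbestic
point, as typical instruments do. Blocks alternate between the implicit
and explicit time encodings and carry independent rates and small random
onsets, exercising the per-block-clock guarantee.

Everything is a pure function of the `genSpec()` parameters including the
seed — repeated generation is byte-identical on disk — and the caller's
RNG stream is saved and restored around generation.

What the generator does **not** emulate: real haemodynamic response
shapes, motion artifacts, physiological drift, pruned (distance-capped)
channel sets, or vendor dialects beyond the string-encoding variants
above. Passing tests therefore demonstrate structural and numerical
fidelity of storage, resolution and validation — not that any analysis of
real recordings would behave well.

`corruptSnirf()` seeds exactly one named defect from `defectRegistry()`
(12 defects spanning every rule family) and returns the location where the
validator must report it. Defects that cannot exist in the model — gaps,
zero-padded names, deleted groups — are introduced by HDF5 link operations
on a written file. The test suite checks the full one-defect-one-detection
matrix and that the uncorrupted twin draws zero error findings.

## Problem sizes and numerical choices

The property battery runs at sizes chosen to exercise every code path
while staying desk-scale: 200 randomized generator specifications (1–2
sources and detectors, 1–2 blocks, 0.5–1.5 s at 5–20 Hz) for round-trip
identity, and exhaustive oracle comparison of channel resolution on
probes up to 16 × 16 × 3 (768 channels). Round-trip equality is *exact*
(bit-level on doubles), not tolerance-based: the container stores IEEE
doubles, so any drift would indicate a coercion bug, not rounding.
`snirfIdentical()` compares named mappings (metadata tags, preservation
areas) by key rather than storage order, since HDF5 does not preserve
insertion order.

## Known limitations

* No haemodynamic processing: conversion to optical density or
  Beer–Lambert chromophore concentrations is out of scope; the package
  stores and validates, it does not analyse.
* Frequency-domain, time-domain and correlation-spectroscopy channels are
  carried opaquely (their `dataType` codes warn) — deep validation of
  modality-specific fields is not attempted.
* Stimulus `data` column semantics (`[onset, duration, amplitude]`) follow
  community practice; the container format itself does not fix them.
* The export column convention `S{s}_D{d}_{wl}nm` is an invention of this
  tool's `export` command, not part of the format.
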