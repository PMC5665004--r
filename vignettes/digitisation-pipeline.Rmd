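---
title: "A barcode-driven digitisation pipeline for pinned-insect collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A barcode-driven digitisation pipeline for pinned-insect collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colldigi)
```

## The model

`colldigi` implements an *object-to-image-to-data* digitisation workflow
for pinned-insect collections. The physical process it mirrors: every
specimen receives a label carrying a unique identifier in both
human-readable and DataMatrix form; specimens are photographed in unit
trays with their labels placed on a raised panel at the right edge of the
frame; and every database record downstream — transcription, site and
taxon concepts, georeferences, the records ingested into the collection
management system (CMS) — is derived from those photographs. The pipeline
is deliberately modular: imaging, transcription, normalisation and
georeferencing are independent stages that can run sequentially or in
parallel, coordinated only through the relational store.

The store (`DigiStore`) is an environment of relational tables with
reference semantics, persisted as a directory of UTF-8 CSVs. Two
properties are treated as invariants everywhere:

* **Barcode uniqueness.** Codes are issued from a monotone counter that
  never rewinds; discarding a code (misplaced printed labels) makes it
  permanently unusable, so no identifier can ever be attached twice.
* **Verbatim preservation.** Transcription captures label text exactly as
  written, byte for byte, with no interpretation. All standardisation
  happens later, in the explicit variant-to-master normalisation step, so
  the original evidence is never destroyed. The published occurrence
  record carries both (`verbatimLocality` next to `locality`).

## The DataMatrix codec

No DataMatrix library is available to R, and decoding the printed symbol
is the hinge of the whole pipeline, so the package includes its own ECC200
implementation: ASCII encodation with digit-pair compaction, Reed–Solomon
error correction over GF(256) (field polynomial 0x12D, generator roots
$\alpha^1..\alpha^{n}$, Berlekamp–Massey + Chien + Forney decoding), and
the standard utah/corner bit-placement for square symbols from 10×10 to
26×26 modules — ample for barcode payloads such as `NHMUK010000001`
(ten codewords).

The image-side decoder binarises at 0.5, finds candidate symbols as large
connected dark components (the L-shaped finder makes the symbol one
component whose bounding box is exactly the symbol bounds), then samples
the module grid at every supported symbol size with *independent*
horizontal and vertical pitch. That last choice matters: the standard
label crop resamples the panel to a fixed 800×1219 geometry, stretching
symbols anisotropically, and a decoder assuming square modules would fail.
Decoding is attempted on the full-resolution crop first and once more on a
sharpened, half-scaled copy. Rotated symbols are out of scope: the imaging
rig produces upright frames.

## The synthetic collection generator

`generateCollection()` renders a ground-truthed fake collection so every
stage can be tested against a manifest. What it emulates:

* the `Drawer##/Taxonomic name/IMG_####.jpg` folder convention;
* neutral grey photographs (default 2400×1600 px) with a mock butterfly
  silhouette on the left 75% and a label card on the right 25% carrying
  rendered text (taxon, site, date, collector, human-readable code) and a
  real, decodable DataMatrix symbol;
* controlled duplication among site strings: a variant pool maps several
  verbatim spellings ("Reading", "Reading, Berks", "Redding") to one
  master site, with heavy-tailed weights so a few sites dominate, as in
  real collections — `emulateDedupProfile()` constructs pools with an
  exact prescribed variant/master structure;
* deliberate corruption: `misreadRate` overwrites a random rectangle
  covering 30% of the symbol's area with background grey, which reliably
  exceeds the Reed–Solomon correction budget; `missingBarcodeRate` omits
  the symbol; both are recorded per specimen in the manifest;
* double-sided labels: a fraction of specimens (default 0.1, a
  round number chosen in the absence of a published rate) get a second
  photograph, `*_b.jpg`, of the label versos.

Defaults describe a desk-scale British butterfly collection: a few
drawers, collecting years 1890–1960, typed-style label text. Everything is
driven by one seed; the same seed yields a byte-identical manifest.

What it does **not** emulate — and hence what passing tests do not show
about real data: handwriting (the text is a fixed bitmap font, so OCR-like
difficulties never arise; transcription here is CSV-driven by design),
specimen damage and clutter touching the label panel, camera noise,
rotation and perspective, and verbatim strings that are ambiguous to a
human. The corruption model tests the *accounting* of failures, not the
full space of real misreads (a real misread can decode to a wrong payload;
our damage model makes decoding fail outright, and wrong-payload
correction is exercised separately through `renameForBarcode`).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| label crop geometry | 800 × 1219 | px | the fixed label-crop standard; right 25% of the frame at full height |
| JPEG quality | 92 | — | "high quality JPEG" capture without a published number |
| triage threshold | 5 | specimens/site | sites at or above it are georeferenced first; heavily collected sites cover a large share of specimens |
| QA sample | 100 | sites | the double-georeferencer agreement check |
| QA agreement | max(extents), plus extent overlap | m | what "the same answer" means for two point+extent results; threshold configurable |
| PERT `b` | 90th percentile | min/specimen | worst-case estimate robust to outliers |
| timing minimum | 10 | observations/stage | below this a three-point summary is refused |

## Numerical choices

* **Rounding is half-up**, not banker's: 2 decimals for minutes, 0 for
  percentages (`roundHalfUp()`). This reproduces printed project-report
  tables (e.g. a 49.59% variant reduction prints as 50%). Stage shares are
  rounded independently and may sum to 99–101; no remainder
  redistribution is applied.
* **The total base time is the sum of unrounded stage estimates**, then
  rounded — not the three-point formula applied to the total column's own
  (min, median, max), which gives a slightly different number.
* **Percentiles** use linear interpolation between order statistics
  (`quantile(type = 7)`), checked in the tests against a hand-written
  sort-based oracle.
* **Distances** are great-circle (haversine, R = 6371 km) via geosphere.
* **Resampling** of the label crop is bilinear (EBImage's affine
  transform). Aspect ratio is deliberately not preserved and no padding is
  added: the 800×1219 contract wins.
* **Date parsing** accepts day.month.year (roman or arabic months),
  month.year, bare year, and dash ranges whose left side may be completed
  from the right ("12-14.vi.1921"). Two-digit years are refused rather
  than guessed — assuming a century is a known, silent error source — and
  the record is flagged `uncertain:date` with the verbatim string kept.
* **Degenerate inputs**: a 4-px-wide image still crops (1 column) and
  resizes; an all-background label fails decoding with a reason, never an
  error; empty discard lists and empty embargo rule sets are no-ops.

## Design decisions where the design was open

* **Barcode payload**: prefix + zero-padded 9-digit counter
  (`NHMUK010000001`), configurable; the dual human/machine-readable label
  needs a short, stable, sortable payload.
* **Persistence**: an in-memory environment of data.frames saved as a
  CSV directory, rather than a client–server database — nothing at desk
  scale requires more, and CSV is simultaneously the interchange format
  the CMS round-trip uses.
* **Idempotency by content hash**: processed photographs are remembered by
  MD5, not filename, because successful processing *renames* the file;
  hashes survive the rename, so re-running a batch creates nothing.
* **Barcode collisions** (same payload decoded twice) flag both records
  for scrutiny and never overwrite files.
* **Variant matching is exact and case-sensitive** at transcription time;
  fuzzy clustering is deliberately deferred to the expert-driven
  normalisation stage, and no automatic gazetteer lookup is attempted.
* **The CMS is emulated** (`MockCms`): sequential IRNs over a CSV
  round-trip, with the production per-entity policies — catalogue,
  collection events, sites and multimedia always created new; taxonomy
  and parties matched by exact name or created; locations (drawers)
  matched to existing records only. The implemented reference graph is
  catalogue → {taxonomy, sites, collection_events, parties, multimedia,
  locations} and collection_events → {sites, parties}.
* **Specimens-per-master statistics** use the number of masters that have
  at least one specimen as the denominator; published project tables are
  not always explicit about this choice, so reported means may differ from
  externally printed ones.

## Problem sizes

The test suite exercises unit behaviour on reduced image geometry
(1200×800) and runs one full-scale end-to-end project — 200 specimens at
the default 2400×1600 geometry with a 5% barcode-corruption rate — through
imaging, correction, transcription, normalisation, georeferencing, CMS
round-trip and publication, comparing every stage against the generator's
manifest. The codec is separately round-tripped over 500 random payloads
and the Reed–Solomon layer over injected-error trials up to its correction
bound.

## Known limitations

* No OCR, by design: transcription is human (or batch-CSV) driven.
* The decoder assumes upright symbols and a single symbol per label panel
  (a second one is detected and flagged, not resolved).
* Concurrency is last-write-wins; the store is a single-analyst handle,
  not a server.
* Georeferencing is manual entry/CSV: no live map-service or gazetteer
  queries.
* The CMS emulation covers the record-flow semantics (ordering, matching,
  IRN round-trip, deletion of superseded records), not any vendor API.
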