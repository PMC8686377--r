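---
title: "Managing cBioPortal study directories with cbpstudio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing cBioPortal study directories with cbpstudio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The study folder as an interface

A cBioPortal study is a folder of paired files: every tab-separated data
file has a `key: value` meta file telling cBioPortal how to interpret it.
`cbpstudio` treats a *study root* directory — the folder a local
cBioPortal instance imports from — as its only interface: it lists the
studies below it, loads one study into an in-memory `cbp_study` object,
lets code modify the components, and writes the changed files back. The
package never talks to a cBioPortal server; uploading the folder (e.g.
with cBioPortal's own import script) is a separate, independent step.

Because cBioPortal itself discovers data files through meta files but this
package must work the other way around, data files carry canonical names:
`data_clinical_patient.txt`, `data_clinical_sample.txt`,
`data_mutations_extended.txt`, `data_timeline_<track>.txt`, and the four
`data_resource_*.txt` files, each paired with `meta_<same suffix>.txt`.
These follow cBioPortal community convention. One extra sidecar,
`dates_first_diagnosis.txt`, holds the first-diagnosis-date registry (see
below); it is not part of the upload.

All files are UTF-8 with Unix line endings, tab separators and no
quoting. Cells may not contain tabs or newlines — this is rejected at
input — which keeps the writers canonical and the load→save round trip
byte-exact. Saves are atomic (write to a temp file in the target
directory, then rename): a study folder shared by several users never
exposes a half-written file, and a save that fails its pre-checks writes
nothing at all. Loading is equally atomic; a malformed file raises a parse
error naming the file and row, and no partial study is returned. Absent
optional files simply load as empty components, because the intended
workflow builds a study incrementally: study metadata first, then
patients, then samples, then optional mutation, timeline and resource
data. That ordering is enforced by precondition errors (a sample for an
unknown patient tells you to add the patient first), not merely by
documentation.

## Clinical tables

The editable model of a patient or sample table is deliberately the one a
documentalist sees on screen: three metadata rows — short name, long name,
datatype — above one row per patient or sample
(`clinical_editable_view()`). The on-disk dialect is cBioPortal's clinical
format, which adds a fourth header row (priority). Priority is not part of
the editable model; it is written as 1 for every attribute so the files
import cleanly, and read back tolerantly.

Datatypes are `STRING`, `NUMBER` (any decimal), or `BOOLEAN`
(`true`/`false`, case-insensitive); values are checked on entry and by the
validator. Missing values are written as empty cells; both empty and
`"NA"` read back as missing (tolerant reader, canonical writer).
`PATIENT_ID` is the only mandatory patient attribute; samples additionally
require `SAMPLE_ID`, and both must be unique within their table. Columns
come either from `attribute_def()` (user-defined) or from a
predefined-attribute catalog shipped as a plain TSV
(`inst/extdata/predefined_attributes.tsv`) so sites can extend it. The
catalog types `OS_STATUS` as `STRING`, matching cBioPortal's categorical
convention (`0:LIVING`, `1:DECEASED`).

Deleting a patient cascades: their samples, the mutation rows of those
samples, timeline events, diagnosis date and resource entries are removed
rather than orphaned, since the validator (and cBioPortal) would reject
orphans anyway. `import_patient()` is the inverse operation across
studies: it copies the patient with that same closure of dependents, and
unions attribute columns and timeline tracks into the destination,
creating them with the source metadata where missing. A repeated import is
refused and leaves the destination untouched.

## Mutations

MAF input must contain `Hugo_Symbol`, `Tumor_Sample_Barcode`,
`Variant_Classification` and `HGVSp_Short`; all further columns are
preserved verbatim in order of first appearance. Imports concatenate onto
the existing table — no deduplication, no re-sorting — so repeated uploads
behave predictably; the validator flags exact duplicate rows as a warning
rather than silently dropping them. An unknown barcode is a warning, not
an import failure, because samples are sometimes registered after their
sequencing results arrive; the validator reports the dangling reference
until it is resolved.

Saving mutations always writes three files: the data file (header-only
when the table is empty, so a study without mutation data still imports
without errors), its meta file, and
`case_lists/cases_sequenced.txt` listing each distinct barcode once with
stable ID `<study>_sequenced` — cBioPortal requires this case list
whenever a mutation profile exists.

## Timelines and day arithmetic

cBioPortal positions timeline events by the integer number of days since
the patient's first diagnosis, not by date. Rather than asking for the
diagnosis date with every event, the package keeps a per-patient registry
(`set_first_diagnosis_date()`); events may then be entered as calendar
dates and are converted by `date_to_days()`:
`offset = event − diagnosis` in proleptic Gregorian calendar days, no time
zones, no times of day. Negative offsets (pre-diagnosis events, e.g. an
earlier surgery) are allowed with a warning, since cBioPortal accepts
them.

When a diagnosis date is edited after events exist, every stored offset of
that patient is recomputed by shifting: moving the diagnosis *k* days
earlier increases each offset by *k*. This is exact — the underlying event
dates are unchanged and the offset is their difference — so no per-event
calendar dates need to be stored, and the registry sidecar stays the only
non-cBioPortal file.

The built-in tracks mirror cBioPortal convention: `treatment` is a span
track with extras `TREATMENT_TYPE`, `SUBTYPE`, `AGENT`; `surgery` and
`status` are point tracks with `SUBTYPE` and `STATUS` respectively. They
exist in every study and their modes cannot be overridden. Custom tracks
declare span (start and stop) or point (start only) mode. The cBioPortal
file dialect records no mode, so on load a custom track's mode is
inferred: span if any `STOP_DATE` cell is non-empty. A custom track with
no events loads as span — the permissive choice, since a span track still
accepts stop-less events — which is a known limitation: a freshly created,
still-empty point track re-loads as span until its first event is saved.

## Resources and the cancer-type vocabulary

Resources are hyperlinks (reports, images, wiki pages) attached to the
study, a patient, or a sample. A definition fixes the ID, display
metadata and scope; entries then attach URLs to concrete, existing
targets. `OPEN_BY_DEFAULT` defaults to false — opening external documents
unasked is rarely wanted in a clinical viewer. URLs are checked only for
non-emptiness: clinical intranet links are not reachable from a build or
test environment, so dereferencing them would be meaningless.

Study types are OncoTree codes (MSK's open cancer-type ontology of short
lowercase codes) or the literal `mixed`, the conventional label for
multi-entity MTB cohorts. A snapshot of ~40 common codes ships as a plain
TSV so no network access is ever needed; `oncotree_load()` accepts a full
OncoTree export in the same four-column format, and checks uniqueness,
parent existence and acyclicity on load. Search ranks exact code matches
first, then name matches, alphabetically within rank. Which OncoTree
release a site uses is a deployment choice; unknown codes in existing
on-disk studies are a validation warning, not a load failure.

## Validation

`validate_study()` natively re-implements the upload-readiness checks for
the data types this package writes; it reads the on-disk files, not the
in-memory object, because the files are what cBioPortal will see. The 16
rules each carry a stable `rule_id` (e.g. `ref.sample_patient`,
`maf.required_cols`, `tl.stop_ge_start`); findings are ordered by file
then line, and the status is derived deterministically: any ERROR means
`FAIL`, warnings only mean `PASS_WITH_WARNINGS`, otherwise `PASS`. Two
design points keep reports useful: referential rules are suppressed
against a table that itself failed to parse, so a single header defect
does not cascade into spurious findings; and warnings (duplicate MAF rows,
negative day offsets, unknown cancer-type codes) never block an upload.
The CLI maps the report to exit codes 0/2, with `--strict` turning
warnings into exit 1, and 3 for an unreadable directory.

Two properties tie the toolkit together and are tested as such:
*soundness* — any study produced purely by this package's save paths
validates with zero errors — and *completeness* — for every rule,
`seed_defect()` produces a minimal file edit that triggers exactly that
rule and no other error rule.

## The example-study generator

`generate_example_study()` plays the role of a bundled test study: a
deterministic, structurally complete study built exclusively through the
package's own API (which is why soundness holds by construction). Defaults
are 2 patients, 2 samples per patient, 3 mutations per sample and 2
timeline events per patient — the scale of a hand-curated example study,
small enough that a full generate–validate cycle runs in well under a
second. Gene symbols and variant classifications come from fixed pools
(TP53, KRAS, BRAF, ...; Missense_Mutation, Nonsense_Mutation, ...), ages,
sexes, dates and agents are drawn from seeded uniform choices, and the
caller's RNG state is restored afterwards. The same seed yields
byte-identical directories.

What the generator emulates is the *structure* of real MTB data — linked
patients, samples, variants, therapy timelines, report links — not its
content: allele frequencies, clinically coherent therapy narratives and
realistic attrition are out of scope. Tests passing on generated studies
therefore demonstrate format and referential correctness, not clinical
plausibility.

## Numerical and procedural choices

- Day arithmetic uses R's `Date` (proleptic Gregorian); the test suite and
  the acceptance script cross-check it against an independently
  implemented civil-calendar day count over random dates in 1900–2100
  (10,000 pairs in the acceptance run, including leap years and the
  identity case).
- Round-trip fidelity is measured over 20 generated studies per
  acceptance run: byte-identity of every file after load→save, and
  field-by-field equality after a second load.
- Lexicographic orderings (`list_studies()`, validator file order, search
  tie-breaks) use radix sort, i.e. C-locale byte order, for
  locale-independent determinism.
- Identifiers (study, track, resource) are restricted to
  `[A-Za-z0-9_-]+` so they are safe as file-name components on all
  platforms.

## Known limitations

- Only the six data types above are covered; copy-number, fusion,
  expression and methylation formats are not written or validated.
- VCF input is out of scope; variants must already be in MAF form
  (annotation pipelines such as vcf2maf produce it).
- Studies cannot be renamed or deleted through the API, and there is no
  cross-process write locking; atomic renames only protect readers.
- Gene symbols are not checked against a gene database, and parity of the
  validator's wording with cBioPortal's own validator is not attempted —
  only the pass/fail decision on studies this package writes.
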