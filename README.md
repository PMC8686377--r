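# cbpstudio

Scriptable creation, editing, merging and validation of cBioPortal study
directories.

## The problem

cBioPortal for Cancer Genomics is widely used in hospitals to store,
annotate and visualize the clinical and molecular data discussed in
Molecular Tumor Boards (MTBs). A local cBioPortal instance is fed from
*study directories*: folders of tab-separated data files, each paired with
a `key: value` meta file, covering six data types — cancer study metadata,
patient and sample clinical tables, MAF mutation data, patient timelines,
and resource links. Assembling these files by hand is error-prone: clinical
tables need four `#`-prefixed metadata header rows, timelines encode event
times as integer *day offsets from first diagnosis* rather than dates, MAF
files need specific mandatory columns, and every referential slip
(a sample pointing at a missing patient, a barcode pointing at a missing
sample) breaks the upload.

`cbpstudio` makes this workflow scriptable and testable. It is aimed at
clinical documentalists and bioinformaticians who maintain MTB studies and
want reproducible, diffable ETL instead of manual file editing.

At its core are:

- a **study store** that reads and writes whole study folders with
  canonical file names, deterministic byte-exact output and atomic saves;
- **clinical tables** modeled as attribute metadata (short name, long
  name, datatype) plus records, with a predefined-attribute catalog
  (`OS_STATUS`, `AGE`, `SEX`, ...) and custom columns;
- a **first-diagnosis-date registry** converting calendar dates to
  cBioPortal's day-offset timeline coordinate
  (`offset = event date − diagnosis date` in proleptic Gregorian days);
- a **native validator** re-implementing the upload-readiness checks as 16
  testable rules (structural pairing, header shape, datatypes, referential
  integrity, timeline arithmetic, resource scoping, OncoTree codes) with a
  text/HTML report;
- a deterministic **example-study generator** and per-rule defect seeding
  for testing;
- a **command line** (`inst/cli/cbp`) exposing the full workflow in the
  mandated order: study → patients → samples → optional mutations,
  timelines and resources → validation.

## Worked example

```r
library(cbpstudio)

root  <- tempfile("studies")
meta  <- study_meta("mtb_mainz", "mixed", "MTB Mainz",
                    "Molecular tumor board cohort")
study <- create_study(root, meta)

study <- add_patient(study, list(PATIENT_ID = "P1"))
study$patients <- add_column(study$patients, "AGE")   # predefined catalog
study <- add_patient(study, list(PATIENT_ID = "P2", AGE = "54"))
study <- add_sample(study, list(PATIENT_ID = "P1", SAMPLE_ID = "P1-S1"))

study <- set_first_diagnosis_date(study, "P1", "2020-01-01")
study <- add_event(study, "treatment", "P1",
                   start = "2020-02-01", stop = "2020-03-01",
                   event_type = "Medical Therapy",
                   extras = list(AGENT = "Cisplatin"))

study <- save_study(study, components = "all")
study
#> <cbp_study> mtb_mainz (mixed)
#>   patients: 2  samples: 1  mutations: 0
#>   timeline events: 1 (3 tracks)  diagnosis dates: 1
#>   resources: 0 definition(s)  dirty: <none>

validate_study(file.path(root, "mtb_mainz"))
#> Validation report for study 'mtb_mainz'
#> 0 error(s), 0 warning(s)
#> PASS
```

The treatment event was entered with calendar dates but is stored in
cBioPortal's day-offset coordinate — 2020 is a leap year, so
2020-02-01 and 2020-03-01 become days 31 and 60 after the 2020-01-01
diagnosis:

```
PATIENT_ID  START_DATE  STOP_DATE  EVENT_TYPE       TREATMENT_TYPE  SUBTYPE  AGENT
P1          31          60         Medical Therapy                           Cisplatin
```

The same steps are available from a shell via the CLI wrapper:

```sh
inst/cli/cbp init-study --studies-root /data/studies --study mtb_mainz \
    --type mixed --name "MTB Mainz" --description "Molecular tumor board cohort"
inst/cli/cbp add-patient --studies-root /data/studies --study mtb_mainz PATIENT_ID=P1
inst/cli/cbp validate --studies-root /data/studies --study mtb_mainz
```

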