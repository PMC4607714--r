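---
title: "Curating literature bioactivity data: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating literature bioactivity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarclean)
```

## The problem

Bioactivity measurements extracted from the medicinal-chemistry literature
are recorded as the authors published them: `IC50 = 0.25 uM`,
`pKi = 7.5`, `t(1/2) = 90 min`. Three families of defects make this raw
material hazardous for modelling:

* **Heterogeneity** — the same endpoint appears under many type spellings
  and unit dialects; log-scale and linear reports of the same quantity
  cannot be compared directly.
* **Author-introduced redundancy** — papers routinely tabulate reference
  values cited from earlier publications (often rounded), so the apparent
  number of independent measurements for a compound–target pair is
  inflated; and cited values are sometimes transcribed with the wrong
  units, producing potencies off by exactly 10³ or 10⁶.
* **Implausible values** — a sub-picomolar IC50 or a millimolar Ki is more
  likely an extraction or unit error than a discovery.

The curation model here mirrors production practice in large bioactivity
databases: *flag, never delete*. Published fields are preserved verbatim;
every derived quantity lives in `standard_*` columns, a single
`data_validity_comment`, a separate `potential_duplicate` flag and a
`pchembl_value`. Users then choose their own trade-off between coverage
and strictness by filtering on the flags.

## Standardisation

`standardize_activities()` recomputes all standard fields from the
published fields, which makes it idempotent by construction and keeps the
published record as the immutable source of truth.

* **Type normalisation** is a synonym-table lookup after case folding and
  punctuation stripping, so `'Half life'`, `'half-life'` and `'t(1/2)'`
  all resolve to `T1/2`. Unknown types pass through trimmed — the synonym
  table is data (`inst/extdata/curation_config.yaml`), and extending it is
  a configuration change, not a code change.
* **Unlogging**: negative-log types (pKi, pIC50, …) become
  `10^(-x)` on their declared reference scale, expressed in nM; censored
  relations flip (`pKi > 6` is `Ki < 1000 nM`). Plain-log types
  (logIC50) antilog without a flip. The reference scale is declared
  per type in the config and defaults to molar, because log types in the
  wild are ambiguous about their base scale; a deployment that knows its
  logs are over nM can say so per type.
* **Unit conversion** happens strictly *within* a dimension class:
  molar concentration dialects to nM, mass-per-volume to µg·mL⁻¹,
  exposure (AUC) to ng·h·mL⁻¹, durations to hours. No molar↔mass
  crossing via molecular weight is attempted: the published unit's own
  dimension decides the standard unit, and silent MW-based conversion
  would manufacture values with a different provenance than the
  publication's. Matching is case-insensitive with separator
  normalisation (`ug mL-1` ≡ `ug.mL-1` ≡ `ug×ml-1`); the shipped table
  carries a representative, extensible subset (33 concentration dialects,
  15 mass, 12 AUC, 12 time).
* **Rounding** is two-tier and arithmetic (half-up): values with magnitude
  below 10 keep 3 significant figures, everything else keeps two decimals.
  Half-up is used because "arithmetic rounding" is the stated convention;
  banker's rounding would leave boundary halves direction-dependent.
  The boundary is strict (`< 10`), and rounding is applied once, after
  conversion — a single rounding step avoids compounding representation
  error. Binary floating point cannot represent decimal halves exactly
  (1.005 is stored just below), so the implementation treats doubles
  within a relative 10⁻¹² of a half as halves; this recovers the decimal
  intent of published values without disturbing genuine near-half reals.

A failed conversion (unknown unit, or a non-positive value in a
concentration class) is not an error: the value and units pass through
unchanged and the record is picked up by the unit flagger downstream.

## Validity flagging

The workflow applies at most one comment per record, in a fixed order of
precedence — missing data, then non-standard units, then out-of-range,
then transcription errors. Earlier steps describe more fundamental
defects, and a single comment column (mirroring the production schema)
cannot hold two; later steps therefore never overwrite.

* **Missing**: no published value *and* no activity comment. A record
  saying only "Not active" is an informative outcome, not missing data.
* **Non-standard units**: each standard type accepts a small set of
  canonical units; anything else — including absent units — draws the
  flag. Types without an entry are not policed: the allowed-units table is
  opt-in, so the flagger cannot punish endpoints it knows nothing about.
* **Out of range**: an inclusive window per (type, unit), shipped as
  0.01 nM–100 µM for the dose–response endpoints. The window is
  deliberately stringent; values outside it *may* be correct, which is
  exactly why the policy is a flag and not a deletion. Compounds with
  MW < 350 Da are fragments, expected to bind weakly, so the upper bound
  is multiplied by 100 for them. The relaxation factor is configuration
  (the qualitative rule is "more relaxed", not a printed constant); 100
  spans the gap between a typical 100 µM assay ceiling and the 10 mM
  concentrations used in fragment screening. Bounds are inclusive because
  a stated range reads as an allowed interval; the lower bound is not
  relaxed for fragments — weak affinity means *high* values.

## Redundancy detection

Records are compared like-for-like only after standardisation, grouped by
(compound, target via the assay, standard type, standard units) — a
µM-vs-nM citation pair becomes a clean 10³ ratio instead of a fuzzy one.

**Citation duplicates.** Two records from *different* documents match when
their standard values are equal or one equals the other rounded to 1, 2 or
3 significant figures, in either direction — published citations are
typically truncations of the original. Matches close transitively into
clusters; within a cluster, every record except those of the earliest
document is flagged `potential_duplicate`. Document order is publication
year ascending, ties broken lexicographically by document id; records with
unknown year sort last, so an undated citation is flagged in preference to
a dated original. Same-document repeats are never flagged: one paper
legitimately reports a racemate alongside its isolated stereoisomers.
The duplicate flag is a separate boolean, not a validity comment — a cited
value is usually *correct*, it is just not independent evidence, and it
must not suppress the record's pChEMBL.

**Transcription errors.** A pair from different documents whose values sit
exactly 3 or 6 decades apart is a unit slip (µM recorded as nM, or mM as
nM); the later publication's record draws
`'Potential transcription error'`. Two decades is not a recognised slip —
the minimum is 1000-fold. "Exactly" is implemented with care: the larger
value is divided by the decade and compared with the same rounding-aware
match used for duplicates, *after re-applying the standard rounding rule
to the scaled value*. The re-rounding matters: stored values are rounded
(two decimals above 10), so a genuine down-slip of 195659.34 nM arrives as
195.66, which is not within any small tolerance of 195.65934 — but
re-rounds to it exactly. Without this step the detector would
systematically miss down-slips of 5-plus-digit values. A relative
tolerance of 10⁻⁶ absorbs binary representation error on exact decade
ratios. Duplicate and transcription matches are naturally disjoint at the
pair level (a ratio cannot be both ≈1 and ≈10³).

Both detectors are pairwise within groups and are verified in the test
suite against an independently written O(n²) brute-force oracle (its own
decimal-string rounding, explicit BFS clustering) on 1,000 randomized
groups.

### The precedence interplay

A decade slip usually also leaves the typical range, and the out-of-range
step runs first — so under a configuration that polices ranges, many true
transcription errors carry `'Outside typical range'` instead of the
transcription comment. Both comments are honest descriptions of the same
defective record, but analyses that measure the transcription detector in
isolation (and the package's own recovery experiments) disable the
typical-range table, which is opt-in by design. The same reasoning applies
to pChEMBL identity experiments: a strong pKi of 11 maps to 0.01 nM, at
the edge of the stringent window, and any comment suppresses pChEMBL.

## pChEMBL

`pChEMBL = −log10(value in M) = 9 − log10(value in nM)`, rounded to two
decimals, computed only when: the standard type is in the dose–response
set {IC50, XC50, EC50, AC50, Ki, Kd, Potency}, units are nM, the relation
is exactly `'='`, the value is positive, and the record carries no data
validity comment. Censored relations are excluded because a bound has no
point estimate to take a log of; `'~'` is likewise excluded. The
`potential_duplicate` flag does not suppress the value. Aggregating
multiple pChEMBL values per compound–target pair (median, mean) is left to
the user's modelling step, where the duplicate flag should inform the
weighting.

## Assay and target annotation

The assay classifiers are explicit keyword surrogates for expert manual
curation: the field's criteria are precedence rules, not an algorithm, so
the lists live in configuration and the code only fixes the precedence.

* **Assay type** (B/F/A/T/P): ADME keywords dominate — a cytochrome P450
  binding assay is filed under A, because users filtering for
  pharmacokinetics data find it there. Physicochemical keywords yield P
  only when no biological-target context is present. Cytotoxicity splits
  on an explicit `therapeutic_context` flag: the same HepG2 viability
  assay is functional efficacy in an anti-cancer program and toxicity in a
  safety panel. That context is an input, not inferred from text —
  inferring disease context from a one-line description is unreliable and
  out of scope. Binding keywords give B; the default is F, the most common
  category for phenotypic readouts.
* **BAO format**: organism > tissue > cell > biochemical, because a more
  complex system subsumes the cues of simpler ones — an isolated guinea
  pig ileum preparation mentions tissue and implies cells, and must read
  tissue-based; an in-vivo xenograft model mentions cells and must read
  organism-based. An extracted cell-line token forces at least
  cell-based. With no cue at all the format stays unassigned rather than
  guessed.
* **Cell-line ambiguity**: tokens are looked up in a dictionary carrying
  candidate identities with organism and an opaque ontology identifier;
  more than one candidate (the classic `H4`: rat hepatoma vs human
  neuroglioma) means organism context is required before mapping. Unknown
  tokens are reported as unknown, not ambiguous.

Target records enforce the component taxonomy: SINGLE PROTEIN has exactly
one component; PROTEIN FAMILY (subtype unresolved), PROTEIN COMPLEX
(multi-subunit) and PROTEIN COMPLEX GROUP (a complex of unresolved
composition, e.g. a pentameric receptor assembled from α/β/γ subunit
pools) have at least two; an annotated binding subunit must itself be a
component. Validation returns violations rather than raising, so a whole
target table can be audited in one pass.

## The synthetic corpus

`generate_corpus()` realizes the error taxonomy as a seeded sampling
process, so every flagging rule can be scored against known truth without
any external database.

* Each compound–target pair draws a true pActivity from
  Normal(6.5, 1.5) on the −log10 M scale and each measurement adds
  Normal(0, 0.5) of assay noise. These are the package's defaults for a
  plausible medicinal-chemistry landscape: potencies centred near 300 nM
  spanning roughly picomolar to millimolar, with inter-assay scatter of
  about a factor of three — the literature reports inter-laboratory
  variability qualitatively, and these values are a deliberate,
  documented choice rather than an estimate.
* Records render in a random unit dialect (nM, µM, mM, M, pM,
  nmol/l…) and, with probability 0.2, as a log type. For log-rendered
  records the published value is the rounded 2-decimal log and the
  intended standard value is derived *from the published value*, so
  re-standardising the published fields reproduces the intended standard
  values exactly — a generator invariant the tests assert.
* A record is *eligible* for defect injection when an earlier document
  already reported its pair. Eligible records become citations (copy the
  earliest document's value, re-rounded to 2–3 significant figures half
  the time) with probability 0.05, or decade slips (×10³ or ×10⁶, random
  direction) with probability 0.02. Injected records are always rendered
  in linear dialects: the real-world mechanism is a table of concentration
  values with wrong units, and a log-re-rounded citation would drift off
  its source by more than the rounding-aware match tolerates. Citations
  always cite the pair's earliest document, which makes the
  "later publication is flagged" rule directly checkable.
* With probability 0.01 a clean record loses its value (and has no
  activity comment), becoming ground-truth missing data.
* A fraction 0.1 of compounds are fragments (MW drawn below 350 Da,
  others above), exercising the relaxed-range rule.
* One RNG stream, fixed draw order: a fixed seed reproduces the corpus
  byte-for-byte. Across *different implementations* of the same sampling
  description only distributional agreement is expected, so
  cross-implementation comparisons should use the injected-count
  intervals, not record identity.

What the generator does *not* emulate: structure-level errors (salt forms,
stereochemistry), spelling noise in assay descriptions, systematic
inter-lab bias, or correlated errors within a paper. Passing recovery
tests on this corpus therefore demonstrates that the detectors implement
their rules exactly — not that real literature error rates are recovered.
There is no explicit out-of-range injection: with the distribution above,
genuine tails beyond the 0.01 nM–100 µM window arise naturally
(a pActivity beyond 11 or below 4), and those tail records are the
out-of-range positives.

## Numerical and testing choices

* Problem sizes: the recovery experiment uses ~6,000 records
  (300 compounds × 10 targets × 40 documents), large enough that the
  eligible-record count exceeds 2,000 and the binomial 99% intervals for
  injected counts are informative; the pChEMBL identity uses 10,000
  records; the oracle-equivalence property uses 1,000 random groups of up
  to 20 members.
* Published pKi values in the identity experiment are drawn on a
  2-decimal grid in [1, 11] — the precision at which log endpoints are
  actually reported. On that grid the pipeline's pChEMBL reproduces the
  published value exactly; for arbitrary-precision reals the standard
  rounding perturbs the recovered log by up to ~2×10⁻⁴, which can
  legitimately move a value across a 2-decimal rounding boundary.
* Degenerate inputs: an empty corpus yields an all-zero report (percentages
  defined as 0); records missing any redundancy-group key component are
  skipped and counted; validation functions never raise.
* Determinism: the pipeline proper contains no randomness; identical
  inputs and configuration give identical outputs, and re-running the
  pipeline on its own output is a no-op because standard fields are always
  recomputed from published fields.

## Known limitations

* Keyword classification is a surrogate: descriptions written without the
  configured cue words fall back to F / unassigned. The lists are
  extensible config, and the worked examples in the test fixtures define
  the supported behaviour.
* Mass↔molar unit crossing is intentionally unsupported, so an IC50
  published only in µg·mL⁻¹ standardises to µg·mL⁻¹ and never merges
  with nM groups for redundancy detection.
* The duplicate detector cannot distinguish a citation from a genuinely
  identical independent measurement in a later paper; the flag means
  "not safely independent", not "wrong".
* Cross-database reconciliation and compound-structure curation are out of
  scope.
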