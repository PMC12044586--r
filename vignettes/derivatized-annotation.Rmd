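---
title: "Annotating charge-tagged metabolites: models, parameters, and design choices"
author: "derivmz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating charge-tagged metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derivmz)
```

## The problem

On-tissue chemical derivatization makes poorly ionizing metabolites —
catecholamines, trace amines, amino acids — detectable in MALDI mass
spectrometry imaging by covalently attaching a charged tag to specific
functional groups. The price is a combinatorial annotation problem: a
metabolite with several reactive sites can appear as a family of ions,
one per tag count and charge-reduction loss, and none of them sits at a
"textbook" adduct mass. `derivmz` solves the resulting bookkeeping and
search problem with exact monoisotopic arithmetic and structure-derived
constraints on which ions a molecule can form.

## Mass arithmetic

Every mass in the package flows through a single elemental-composition
type: a map element → count plus a signed charge. The monoisotopic mass is
the sum of per-element monoisotopic isotope masses minus charge × electron
mass, divided by |charge| for ions. The isotope table uses CODATA/AME
values at 8+ decimals; at 7 decimals and below, 6-decimal reference values
such as the FMP-10 tag shift no longer reproduce at their final digit.
Reported values are rounded half away from zero, matching how instrument
software prints m/z.

## The derivatization model

A derivatizing matrix is described by four pieces of chemistry, all
user-configurable in `inst/extdata/config.yaml`:

* the intact **reagent cation** (FMP-10: C₂₀H₁₅FN⁺),
* the neutral **leaving group** lost per reaction (HF; water for
  amide-coupling reagents like AMPP),
* the **target patterns** it reacts with, and
* its **charge-reduction losses**: +1 cations shed by multiply tagged ions
  to return to charge +1 — for FMP-10 a methyl cation (label A,
  15.022927 Da, "demethylated") or a proton (label B, 1.007276 Da,
  "dehydrogenated").

An ion with *n* tags and losses X₁…X_{n−1} has

m/z = m(M) + *n*·(m(R⁺) − m(L)) − Σ m(Xᵢ⁺),

always at charge +1. The per-tag shift for FMP-10, 268.112076 Da, equals
the m/z of the reagent fragment peak seen in spectra, which is why
153.07898 + 268.112076 = 421.1911 for singly tagged dopamine.

Labelling follows the field's convention: the single-tag species is `1A`
even though no loss occurs; multi-tag labels append the sorted loss
letters (`2A`, `2B`, `3AA`, ...). By default all loss multisets are
enumerated, including mixed forms such as `3AB`; whether mixed-loss triple
forms occur in practice is not settled, so `strict_losses = TRUE`
restricts enumeration to uniform (all-A / all-B) multisets. Multiply
charged un-reduced ions (2+, 3+) are not emitted: the annotation target is
the +1 ion series observed in imaging data. Derivative m/z values that
coincide within 1e-9 Da are merged with their labels concatenated, so a
numeric index never holds duplicate keys.

`max_tags` for FMP-10 defaults to 3, the highest derivatization state of
its classic targets; matrices may instead enumerate up to each
metabolite's full target count (`max_tags: all`).

## Counting derivatization targets

Target counts come from SMARTS substructure matching (OpenBabel) on each
metabolite's SMILES, deduplicated over symmetric atom mappings so a
symmetric diol counts exactly its two reactive oxygens. The shipped
FMP-10 pattern set encodes the chemistry's specificity:

* *phenolic hydroxyl*: `[OX2H][c]` — a hydroxyl oxygen on an aromatic
  carbon. Carboxylic OH (on sp² carbon, not aromatic) and aliphatic or
  benzylic OH never match, which is what makes p-octopamine a two-target,
  not three-target, molecule.
* *primary amine*: `[NX3;H2][#6]` minus amide and sulfonamide exclusion
  patterns, floored at zero.
* *secondary amine*: included by default but individually toggleable
  (`include_secondary`), with the same exclusions. Aromatic ring NH (the
  indole nitrogen of serotonin) is **not** counted by default — aliphatic
  SMARTS `N` cannot match aromatic `n` — because whether ring NH reacts
  under imaging conditions is unestablished; `include_ring_nh = TRUE`
  adds it as a separate pattern for users who observe such derivatives.

Exclusions are subtracted match counts rather than being folded into one
giant SMARTS, so a pattern file remains readable and user-editable, and
net counts are floored at zero by construction.

## The candidate store and the two-step query

`build_database()` validates records (unique ids; a stored mass, when
present, must agree with the formula within 1e-6 Da; unparseable SMILES
demote a record to adduct-only search), precomputes per-matrix target
counts, and materializes a candidate index sorted by m/z containing every
target-feasible derivative form plus any requested adducts. Step 1 of a
query (`filter_candidates()`) restricts by source, m/z range,
derivatizability, tag sufficiency, endogeneity, and tissue; Step 2
(`annotate_features()`) walks the feature list and takes each candidate
within a multiplicative ±ppm window (default 2 ppm, boundary inclusive)
via binary search on the sorted index. All in-window matches are reported,
sorted by |Δppm| then id — no arbitrary best pick, because co-annotating
isomers is informative, not noise.

Filter semantics that the underlying data do not pin down were fixed
once: a tissue filter passes a record whose tissue set intersects the
selection (or `"any"`); an endogeneity filter with several levels is
their union; records with no annotation are `"unspecified"`.

The store persists as a single JSON document. The candidate index is
*rebuilt* from records on load rather than deserialized, which makes
round-trip identity a structural guarantee: masses are always recomputed
from formulas and never stored as primary data. An earlier design using
an embedded SQL database was set aside in favor of this scheme to keep
builds hermetic and diff-able; the table decomposition (metabolites,
target counts, candidates, spectra) is unchanged.

## Recalibration

Instrument mass error is typically zero at the lock mass and grows along
the m/z axis, so the correction model is quadratic in the experimental
m/z:

mₐ = mₑ − (a·mₑ² + b·mₑ + c),

with the sign convention that positive c shifts masses down. The model is
linear in (a, b, c), so ordinary least squares on (observed − reference)
is exact and deterministic and is the default optimizer; a two-stage
derivative-free Nelder–Mead minimization (restarted from its own stage-1
optimum, in the spirit of the NEWUOA/BOBYQA pairing used by some
instrument software) is available as `method = "nelder-mead"` and agrees
with OLS to ~1e-6. Three distinct points interpolate exactly; fewer than
three, or duplicate observed masses, are errors. A fit that *increases*
mean |ppm| on its own calibration points is rejected outright.

Calibration pairs can be given directly or built with
`pair_calibration_points()`, which matches each reference mass to the
nearest feature inside a coarse 20 ppm window — wide enough to catch
miscalibrated peaks, narrow enough to avoid mispairing at typical MSI
feature densities. Improvement is reported by `delta_ppm_report()` on
held-out pairs, excluding the calibration points themselves.

## MS2 matching

Spectra are binned onto a fixed grid with origin 0 and
`floor(mz / bin_size)` indexing (left-closed bins): a fixed origin makes
scores reproducible across runs and machines, where precursor-anchored
origins would not be. Intensities are summed within bins and **not**
transformed — plain cosine similarity on raw intensities, which is
scale-invariant by construction; peaks above the optional maximum m/z
(typically set slightly above the precursor) are dropped before binning,
and with no limit the entire spectrum is used. Coarser bins can only merge
mass-shifted signal into agreement, which is why scores at bin 1.0 bound
scores at bin 0.01 from above on shifted copies — larger bins trade
specificity for tolerance. Library hits are ranked by descending score
with a deterministic tie-break on reference id. An all-zero intensity
vector has no direction, so its cosine is an error rather than a silent 0.

Reference spectra live in the same database object (add/remove
operations included) and store raw intensities; since cosine is
scale-invariant, normalization on storage would change nothing and is
omitted. Diagnostic product ions are computed, not configured as numbers:
the tag fragment (reagent − leaving group) plus a retained neutral per
functional class (H₂O for phenolic hydroxyls, NH₃ for primary amines),
giving 286.122641 and 285.138625 for FMP-10.

mzML is read through `mzR`; profile-mode MS2 scans are rejected with
advice to centroid. The package also carries a deliberately minimal mzML
*writer* (one run, centroid MS2 scans, uncompressed 64-bit arrays) so
that synthetic query files can be generated and the read path exercised
hermetically; `mzR` then serves as an independent reader of those files.

## Synthetic data: what it does and does not show

The generators produce every test input in code:

* `fig_isomer_panel()` — four C₈H₁₁NO₂ isomers with 3/2/2/0 targets.
* `standards_panel()` — a fixed 36-compound roster (catecholamines, the
  proteinogenic amino-acid core, and a handful of exogenous compounds)
  with exactly 28 flagged endogenous. The named members and the 36/28
  split are the anchored facts; the rest of the roster is a
  representative in-repo choice.
* `make_feature_list()` — one feature per candidate ion, perturbed as
  true + a·m² + b·m + c + N(0, sd·m·1e-6), plus uniform decoys, with a
  truth table mapping features to generating candidates. Defaults are a
  zero-error model; tests use curves of a few ppm across m/z 400–1000 and
  0.05–0.2 ppm noise, the scale of a drifting but functioning FTICR
  calibration.
* `make_ms2_library()` — spectra of 10–40 uniform-random peaks (m/z
  50–440) with exponential intensities, paired queries with 5% relative
  intensity noise by default, optional diagnostic ions.

These emulate the *logical* structure of real data — mass-error curves
that grow with m/z, decoys, shared-intensity spectra — not instrument
physics: no isotope envelopes, no peak-shape or centroiding artifacts, no
spatial (per-pixel) structure, no correlated chemical noise. Passing
tests therefore demonstrate that the algorithms are correct on their
stated contracts, not that any particular real dataset will reach a given
annotation rate. Published improvement figures from real FTICR/timsTOF
experiments depend on those unpublished datasets and are deliberately not
asserted anywhere; the tests replace them with property-based checks
(exact parameter recovery, held-out error reduction, rank-1 self-match).

Problem sizes in the shipped tests — a 36-record panel (~200 candidate
ions), 1000-case bisection randomizations, 10-entry spectral libraries —
were chosen as the smallest sizes at which each property is
non-trivially exercised; the full suite runs in well under a minute.

## Numerical choices, edge cases, limitations

* ppm windows are multiplicative and boundary-inclusive; tolerance 0
  degenerates to exact equality.
* Bisection returns a half-open index range and is property-tested
  against a linear scan, including empty lists and empty windows.
* Derivative-m/z merge tolerance is 1e-9 Da (below any instrument's
  resolution, above double-precision noise).
* csv/txt I/O is locale-independent ("." decimal separator); feature
  tables sniff comma/semicolon/tab and find the m/z column by header
  regex, falling back to the first numeric column.
* Formula parsing accepts Hill-style strings only (no isotope labels, no
  charges in the string, no parenthesized groups); unknown element
  symbols are errors naming the symbol.
* Isotope-pattern simulation, average masses, fragmentation prediction,
  peak picking, and image rendering are out of scope.
* The HMDB-dialect importer targets the snippet structure exercised in
  tests (accession, formula, SMILES, disposition terms, biospecimen
  locations); it is not a validator for the full schema.
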