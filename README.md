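# derivmz

Structure-aware annotation of chemically derivatized metabolite ions in
MALDI mass spectrometry imaging (MALDI-MSI).

Reactive (derivatizing) MALDI matrices such as FMP-10 covalently tag
specific functional groups — phenolic hydroxyls and primary or secondary
amines — adding a fixed mass and a permanent positive charge per tag. This
makes poorly ionizing neurotransmitters and other small metabolites visible
in imaging experiments, but it also changes every observed *m/z*: a
metabolite can carry one tag, or several, and multiply tagged ions return
to charge +1 by losing a methyl cation (the demethylated "A" form) or a
proton (the dehydrogenated "B" form). Plain mass-based annotation tools
know none of this. `derivmz` is for MSI labs that need annotation which
understands the chemistry: it counts the derivatizable sites on each
candidate structure and only proposes ions the molecule can actually form.

## The model

All arithmetic is exact monoisotopic mass bookkeeping on elemental
compositions. For a metabolite M with neutral monoisotopic mass *m*(M) and
a matrix with reagent cation R⁺ and neutral leaving group L (HF for
FMP-10), each tagging reaction adds the shift

    Δ = m(R⁺) − m(L)            (FMP-10: Δ = 268.112076 Da)

and one positive charge. An ion with *n* tags carries *n* − 1
charge-reduction losses, each a +1 cation X⁺ ∈ {CH₃⁺, H⁺}, so every
observable singly charged derivative has

    m/z(n, losses) = m(M) + n·Δ − Σ m(X⁺)

labelled `1A`, `2A`, `2B`, `3AA`, ... (tag count, then sorted loss
letters). The number of tags is bounded by the number of reactive sites on
the structure, counted by SMARTS substructure matching on the metabolite's
SMILES. Candidate ions for a whole metabolite panel are indexed sorted by
*m/z* and queried per experimental feature by bisection inside a
multiplicative ±ppm window; optional endogeneity and tissue filters
restrict the candidate set first.

Two further components round out the workflow:

* **Recalibration** — a three-parameter correction fitted to known
  (observed, reference) *m/z* pairs: *m*ₐ = *m*ₑ − (a·*m*ₑ² + b·*m*ₑ + c),
  fitted by exact least squares (the model is linear in a, b, c).
* **MS2 library search** — spectra are binned onto a fixed grid
  (origin 0, `floor(mz / bin_size)`, optional maximum *m/z*) and compared
  by cosine similarity; class-diagnostic product ions (tag + H₂O at
  286.122641 for phenolic hydroxyls, tag + NH₃ at 285.138625 for primary
  amines under FMP-10) flag which functional group a queried spectrum
  derivatized through.

## Worked example

Four isomers share the formula C₈H₁₁NO₂ and the neutral mass 153.07898,
but carry 3 (dopamine), 2 (p-octopamine), 2 (norfenefrine) and 0
(enbucrilate) FMP-10 targets:

```r
library(derivmz)

db <- build_database(fig_isomer_panel())
db
#> <annotation_db: 4 metabolites, 12 candidates (12 derivative / 0 adduct), 1 matrices, 0 MS2 spectra>

res <- annotate_features(c(927.3694, 421.1911, 268.5000), db,
                         matrix = "FMP-10", tol = 2)
res
#> <annotation_set: 2/3 features annotated (66.7%) at 2 ppm, 4 candidate matches>
res$matches[, c("query_mz", "name", "form", "theoretical_mz", "delta_ppm")]
#>   query_mz         name form theoretical_mz  delta_ppm
#> 1 927.3694     dopamine  3AA       927.3694 0.05048066
#> 2 421.1911     dopamine   1A       421.1911 0.10809669
#> 3 421.1911 p-octopamine   1A       421.1911 0.10809669
#> 4 421.1911 norfenefrine   1A       421.1911 0.10809669
```

The triple-tag peak at *m/z* 927.3694 annotates to dopamine alone — only
dopamine has three reactive sites — while the single-tag peak at 421.1911
is shared by all three derivatizable isomers and enbucrilate is never
proposed. The third feature matches nothing and is reported unannotated.

Recalibration is an ordinary fitted model with the usual methods:

```r
fit <- fit_correction(c(200.0006, 500.0021, 800.0051), c(200, 500, 800))
fit
#> Quadratic mass-correction model: m_adj = m - (a*m^2 + b*m + c)
#>   a = 8.333146e-09   b = -8.332496e-07   c = 4.333226e-04
#>   3 calibration points; RMS residual 0 ppm; mean |ppm| 4.525 -> 0
round(apply_correction(fit, 927.3723), 4)
#> [1] 927.3655
```

A thin command-line wrapper over the same functions ships in `inst/cli/`
(`build-db`, `annotate`, `recalibrate`, `ms2-search`, `add-spectrum`,
`fixtures`); matrices, adducts and SMARTS pattern sets are defined in
`inst/extdata/config.yaml` and are user-extensible without code changes.

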