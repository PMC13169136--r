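---
title: "Diagnostic-ion dereplication of plant phenolics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic-ion dereplication of plant phenolics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derepms)
```

## The problem

Crude plant extracts routinely contain over a hundred phenolic metabolites —
acylquinic acids (chlorogenic-acid family), acylhexaric (glucaric) acids of
the leontopodic-acid type, hydroxybenzoic/hydroxycinnamic acid glycosides
and sugar esters, and flavonoid glycosides. Full isolation and NMR of each
is out of the question; instead, practitioners *dereplicate*: they annotate
known chemistry from negative-ion ESI-MS/MS fragmentation alone, using
hierarchical keys built on diagnostic fragment ions and their relative
abundances. `derepms` turns such a key into a reusable, tested rule engine
with an explicit evidence trail, together with the exact-mass arithmetic it
rests on, a percent-peak-area semi-quantitation step, and a ground-truthed
synthetic-spectrum generator so the whole pipeline is testable without any
instrument data.

## Mass arithmetic

All matching decisions reduce to monoisotopic arithmetic over elemental
formulas (C 12 exactly, H 1.00782503, O 15.9949146, N 14.0030740 Da). Ion
m/z follow the proton-subtraction convention

$$ m/z\,[\mathrm{M-H}]^- = M - 1.00727646, \qquad
   m/z\,[\mathrm{2M-H}]^- = 2M - 1.00727646, $$

with no separate electron-mass bookkeeping. This convention reproduces the
calculated values printed in the metabolite-profiling literature for these
compound families to four decimal places (e.g. 781.1622 for the
deprotonated C~37~H~34~O~19~ of the hydroxybutanyl-tricaffeoylhexaric
type), which is why it was chosen. Display rounding is half-away-from-zero
at the requested precision.

Extracted-ion windows are multiplicatively symmetric ppm intervals,
$c\,(1 \pm t \times 10^{-6})$, so that the signed ppm error of a window
edge maps back to exactly $\pm t$.

## The annotation key

Annotation proceeds hierarchically; each step records the matched peaks as
evidence, and a spectrum that fires no rule is returned `unannotated`
rather than guessed at.

**Backbone.** The quinate anion series (191.056 → 173.045 → 111.045 →
93.035, plus 85.030) and the hexarate series (209.030 → 191.020 → 173.009,
147.030, 129.019, 111.009, 85.030) are matched against theory-anchored
m/z. A backbone is called at ≥ 3 series hits; the two series are separated
by 191.056 vs 191.020, which is unambiguous at the default 10 mDa
tolerance (any tolerance under 18 mDa works).

**Acyl composition.** Candidate residues come from marker ions — the free
acid anion (caffeic 179.035, ferulic 193.051, coumaric 163.040,
hydroxydihydrocaffeic 197.046, ...) or secondary ions (decarboxylated
135.045/119.050, the demethylated-decarboxylated 134.037 of ferulate).
Multiplicity is then settled by whole-composition arithmetic: the multiset
of residue neutral losses must explain precursor − backbone-anion within
tolerance. This is more robust than counting ladder rungs alone, because
printed and measured spectra often omit an intermediate loss ion; the
sequential-loss ladder is still walked and recorded as evidence.

**Quinic regiochemistry.** The base-peak key is read over the *diagnostic*
ion set (backbone 191/173 ions plus the composition residues' acid and
secondary markers), not the whole spectrum — the surviving precursor ion is
frequently the global base peak and carries no positional information.
For monoacyls: base 173.045 ("dehydrated" quinate) → C-4; base at the acid
anion → C-3; base 191.056 → C-3 when the residue's acid ions are prominent
(≥ 20 % of base) and C-5 when negligible; a decarboxylated marker as base
cannot separate C-1 from C-3 and yields `"3(or 1)"`. For mixed diacyls the
residue whose [M−H−acyl]⁻ ion is more abundant departed first and takes
C-5, provided the two loss ions differ by at least a 3× ratio — below that
both orders are reported. Vicinal substitution is flagged by the 173.045
base; three identical acyls with a 173.045 base yield 3,4,5. Where the key
cannot separate candidates (1 vs 3; the non-4 partner of a symmetric
vicinal diacyl) the result carries the ambiguity explicitly instead of a
guess.

**Hexaric branch.** The caffeoyl count k and any residual ester are found
by matching precursor − 209.030 against $k \times 162.0317 + \text{ester}$
over the ester registry (hydroxybutanyl C₄H₆O₂ 86.037; hydroxyvaleryl,
butanyl, methylbutanyl analogues; hydroxybenzoyl C₇H₄O₂ with its 137.023 /
93.033 markers). Ester losses are stored as free acid and derived anhydro
mass, because ladders may terminate on either the hexarate anion (209.030)
or its dehydrated ion (191.020). An unmatched residual is reported as
`unknown(Δm)`.

**Glycosides.** Sugar neutral losses (hexose 162.053, di-hexose 324.106,
rutinosyl 308.111, acetylhexose 204.063, caffeoylhexose 324.085) are
matched from the precursor; the residual fragment is looked up in the
aglycone registry (flavonoids myricetin 317.030 … apigenin 269.046;
phenolic acids 137.023 … 197.045). A linkage is called "sugar ester" when
at least two hexose cross-ring cleavages (−60/−90/−120 Da) are present,
else "O-glycoside". Isobaric aglycone pairs (luteolin/kaempferol,
nepetin/isorhamnetin) are reported as either/or unless an optional
retention-time prior resolves them.

**Context-dependent markers.** m/z 197.045 is hydroxydihydrocaffeoyl on a
quinic backbone but syringic acid in the glycoside branch; the registry
carries a context field and the resolution is never global.

**Confidence.** Six levels: A2 (standard match including stereochemical
confirmation — stereochemistry is never inferred from MS2, only asserted
via the standards registry or an external flag), B/C (standard match
without stereo; which of the two is policy, default C), D1 (no standard,
fully resolved structure), D2 (composition resolved, positions or isobaric
identity ambiguous), E (class level only).

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| MS2 match tolerance | 10 | mDa | the modelled instrument's MS2 axis reads ~3–6 ppm low against theory; an absolute window is robust at low m/z where 5 ppm would be < 1 mDa |
| MS1 / EIC tolerance | 5 | ppm | standard Orbitrap-class extracted-ion practice |
| composition tolerance | 15 | mDa | precursor and per-residue theory errors accumulate over up to four losses |
| marker prominence | 20 | % of base | separates the printed "prominent" (≈ 60 %) from "negligible" (≈ 1 %) acid ions with a wide margin |
| negligible threshold | 5 | % of base | documentation of the key's lower band |
| diacyl order ratio | 3 | fold | the published ordered calls differ by ≥ 9×; the published ambiguous pair differs by 2.5× |

All registries (acyl residues, sugars, aglycones, backbone series, hexaric
esters, authentic standards) are editable YAML files under
`inst/extdata/registries/`; loaders accept an alternate directory, and the
CLI exposes `--registries`.

## The synthetic generator

`synthesize_spectrum()` inverts the key: it emits the deprotonated
precursor, the full sequential-loss ladder, the backbone series, residue
markers, and places the base peak according to the regio archetype of the
generating structure (5-acyl → 191-dominant with suppressed acid ions,
4-acyl → 173-dominant, 3-acyl → acid-anion-dominant, 1-acyl →
decarboxylated-marker-dominant). Abundance archetypes are fixed lookup
profiles shaped once to resemble printed spectra of each regio class; no
physical fragmentation model is attempted. The noise model applies a
signed ppm calibration bias (default −5 ppm, emulating the
measured-vs-theory offset of the modelled acquisition), log-normal
relative-abundance jitter (default sd 0.15, mild), and uniform decoy peaks
(default 2 per spectrum at 1–20 % intensity). A single master seed drives
independent per-record streams, so datasets are byte-reproducible and
individual records can be regenerated.

What the generator deliberately does *not* emulate: chromatographic
behaviour, isotopologue envelopes, in-source fragmentation, co-isolation
chimeras, and abundance patterns outside the archetypes. Passing recovery
tests therefore demonstrates that the engine inverts rule-consistent
spectra under calibration bias, abundance noise and decoys — not that it
would reach the same rates on arbitrary instrument data, where
rule-inconsistent fragmentation and chimeric spectra occur.

The shipped enumeration (`spec_enumeration()`, 63 structures) covers the
space the key resolves: it excludes syringoyl-on-quinic (indistinguishable
from hydroxydihydrocaffeoyl by mass and markers) and mixed vicinal
diacyls such as 3,4-disubstitution with two different residues, whose
printed assignments rest on literature retention orders rather than the
MS2 key. Recovery of an ambiguous label counts as correct only when the
truth lies inside the reported candidate set and the candidate set is what
the key warrants (e.g. truth C-1 recovered as `"3(or 1)"`).

## Numerical and design choices

* Chlorogenic-acid numbering follows the convention in which chlorogenic
  acid is 5-caffeoylquinic acid; the alternative (3-) convention exists in
  the older literature, so canonical names, not numbers, drive the
  standards lookup.
* Abundances are normalised to base peak 100; zero-abundance peaks are
  dropped with a warning; duplicated fragments within 1 mDa (a
  transcription artifact in printed tables) keep the first occurrence with
  a warning. Normalisation is idempotent.
* Base-peak ties break to the lower m/z and carry a tie flag.
* Fixture loading flags printed "exact mass" cells that disagree with
  their printed formula by > 2 mDa (several such cells exist in the
  transcribed table, e.g. 353.0867 printed for C₁₆H₁₈O₉ where the formula
  gives 353.0878, and C₁₇H₂₀O₈ printed where the ion demands C₁₇H₂₀O₉);
  the engine always works from the measured peaks.
* One printed ester loss appears as "102.069 Da (C₅H₁₀O₃)" although
  C₅H₁₀O₃ weighs 118.063; the ester registry anchors that residue on
  C₅H₁₀O₂ (free acid), whose anhydro loss of 84.058 against the hexarate
  terminus reproduces the printed ladder.
* The hexarate anion is anchored at theory (209.0303) even though printed
  spectra show both 209.026 and 209.030.
* The dimer ion [2M−H]⁻, when present, is confirmatory only and never
  required.
* Loss-identification ties break to the smallest absolute mass error.

## Problem sizes

The test suite and the acceptance script run the Table-1 worked example
(39 spectra), the zero-noise round-trip over the 63-structure enumeration,
a 200-spectrum noisy recovery experiment, and a 50-spectrum decoy
specificity experiment; these sizes keep every experiment's Monte-Carlo
error well below the margins being tested while completing in seconds.

## Known limitations

* C-1 vs C-3 monoacyl substitution and the non-4 partner of symmetric
  vicinal diacyls are not separable from MS2 alone; results carry the
  ambiguity, resolvable in principle with retention-time priors.
* Confidence grades reflect what the spectrum and the standards registry
  support; isomer pairs sharing a canonical name (e.g. two 4,5-diacyl
  isomers at different retention times) receive the same grade.
* Only singly deprotonated negative-mode ions are modelled: no isotope
  patterns, charge states beyond 1−, or positive-ion adducts.
* The semi-quantitation step validates by construction (sums to 100,
  scale-invariant); published extract-level class shares cannot be checked
  because the underlying raw areas are not public. Class shares are
  computed area-weighted.
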