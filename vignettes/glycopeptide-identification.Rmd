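---
title: "Methods: glycan-database-independent N-glycopeptide identification"
author: "glycotandem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycan-database-independent N-glycopeptide identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotandem)
```

# Overview

`glycotandem` identifies intact N-glycopeptides from
stepped-collision-energy HCD spectra in two decoupled passes — peptide
backbone first, glycan second — so that peptide identification never
depends on a glycan database, and glycans outside any database
(phosphorylated, ammonium-adducted, otherwise modified) remain
discoverable. This vignette records the model, its assumptions, the
tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

# Backbone derivation from the core Y-ion ladder

Every N-glycan is built on the pentasaccharide core Hex(3)HexNAc(2)
(892.3172 Da), so a glycopeptide spectrum contains a predictable Y-ion
ladder at fixed mass gaps above the peptide: Y0 (bare peptide), Y1
(peptide+HexNAc), Y2 (+2 HexNAc), then +1, +2, +3 Hex. `matchCoreLadder`
treats every peak at every charge 1..z as a hypothetical ladder member,
converts it to an implied peptide mass, and clusters the implied masses
by single linkage at the fragment tolerance. A cluster becomes a
backbone candidate when it is supported by at least `minCoreIons = 3`
distinct ladder ions; by default a Y2 ion is also required, which
deliberately excludes very small glycans (single GlcNAc) whose
glycosylation type cannot be distinguished in HCD — setting
`requireY2 = FALSE` with a lower `minCoreIons` re-enables them.

Candidates are ranked by the relative intensity of their Y1 ion; up to
`maxCandidates = 5` are retained, and a candidate whose Y1 exceeds 0.9
of the base peak suppresses all others. Ties are broken by matched-ion
count and then by lower peptide mass — the ranking rule needs a
deterministic completion and these two criteria prefer the
better-supported, more parsimonious candidate. Implied peptide masses
are gated to 600–4500 Da, mirroring the search-space bounds of the
downstream peptide search.

In-silico deglycosylation (`stripAndRewrite`) removes the oxonium ions,
the matched ladder peaks and their +1/+2 isotopologues, and then walks
upward: any higher-m/z peak whose distance to an already-matched Y ion
equals a monosaccharide residue mass (at any charge up to the precursor
charge) is itself a Y ion and is removed, iterating to a fixed point.
Removal is upward-only — the stepping rule is defined on the high-m/z
side of the matched ladder, and peaks below Y0 are peptide territory.
The precursor is rewritten to (P + HexNAc + z·proton)/z so that a
proteomic engine can match b/y ions that retained a HexNAc stub.

# The initial search

The package integrates external engines import-only
(`loadInitialPsms`, q < 0.01 retained, non-sequon peptides dropped);
`builtinSearch` is a minimal self-contained scorer so the pipeline and
its tests run without external binaries. It scores candidates from the
sequon-restricted tryptic index (cleave after K/R except before P, ≤3
missed cleavages, length 6–40, mass 600–4500 Da, fixed
carbamidomethyl-C, variable oxidation-M) by shared-peak count and
relative intensity over theoretical b/y ions (with -NH3/-H2O losses,
+1/+2 isotopologues and +HexNAc stub variants at the sequon), with
reversed-sequence decoys providing target-decoy q values. A PSM must
match at least four fragment ions: with ~800 theoretical m/z windows at
20 ppm against a ~100-peak spectrum, about two matches arise by chance,
so a floor of two reported essentially every spectrum whose precursor
fit; four is comfortably above the chance expectation while far below
the ~30 matches of a genuine identification. This scorer is a
convenience stand-in, not a reimplementation of a production engine; on
real data an external search of the deglycosylated MGF is preferable.

# Spectrum expansion

A backbone's fragmentation pattern — the ion-type → normalised
intensity map, charges pre-summed — is extracted from each of its
identified spectra and averaged (arithmetic mean over contributing
PSMs, absent types as zero, renormalised to max 1). Unassigned spectra
within `rtWindow = 1800` s of the backbone's mean retention time are
scored by the two-term score: the pattern-cosine-weighted,
frequency-normalised, α-powered sum over matched peptide ions, plus the
linear frequency-normalised sum over matched core Y ions. α = 0.3
throughout (for the glycan score too, which does not restate its own
exponent). The frequency of an ion is the number of theoretical b/y
ions of *other* digest peptides within the fragment tolerance, floored
at 1 — computed digest-wide from base b/y ions at 1+/2+, which is
deterministic and precomputable.

Each candidate is also scored against its decoy spectrum (every
fragment shifted by an independent draw from Uniform(1, 30) Th with
random sign — the sign is symmetric to avoid systematic m/z inflation,
and draws are pinned to the (seed, scan id) pair for reproducibility).
The pooled target+decoy scores feed a linear tail fit of log10 survival
vs score over the tail above the 60th percentile of the decoy scores
(minimum five distinct points; an invalid fit — non-negative slope —
rejects the whole peptide's expansion rather than passing unreliable
e-values). Matches are ranked by e-value and accepted while
FDR = 2·N_decoy/(N_decoy+N_target) < 0.01, with at least three matched
core Y ions including Y1 and a non-negative implied glycan mass.

One deliberate choice: the Y1 requirement is enforced at acceptance,
not as a candidate prefilter. Prefiltering would be cheaper, but with
per-peptide dynamic thresholds it starves the score null distribution —
a backbone with four suppressed spectra in its window would contribute
fewer than the ten scores the tail fit needs and lose all of them.
Scoring every RT-window candidate (and its decoy) keeps the null
well-populated; the Y1 gate then removes wrong-backbone matches at
acceptance, where the method defines it.

Stage-one PSMs are re-scored with the same pattern-aware score so
thresholds are comparable across the two identification stages.

# Precursor correction and glycan assignment

Instrument software often triggers on a non-monoisotopic isotopologue.
`correctPrecursor` tests offsets −2..+2: for each candidate monoisotope
it extracts the isotopologue XICs (±30 s), discards channels whose
elution profile correlates with the anchor below 0.7 (coeluting noise),
and compares the surviving envelope by cosine to the theoretical
pattern. The theoretical pattern uses the peptide's exact elements plus
a *pseudo-glycan*: the core's elements plus the residual mass expressed
as a fractional number of hexose units (C6H10O5), valid also for
sub-core masses via negative units. Fractional units are evaluated by
linear interpolation between the integer-hexose convolutions — the
approximation error is far below the 0.7-correlation and
envelope-cosine decision margins.

The corrected glycan mass is matched against the database at a
tolerance propagated from the precursor ppm tolerance (floor 0.01 Da);
candidate entries are fragmented into B/Y ions by single cuts of their
topology tree (explicit nested-parenthesis topologies, or a canonical
N-glycan fallback: chitobiose core, trimannosyl arms, antennae filled
HexNAc→Hex→sialic acid, core fucose on the reducing HexNAc — the
fallback reproduces the Y-mass sets of common compositions but is
approximate for branch placement). Best Eq.-2-style score wins; ties go
to fewer residues, then lexicographic label.

Unmatched masses go to monosaccharide stepping. Moieties are
positive-only by default (1–300 Da): the subtraction can formally
produce negative moieties, but a negative gap cannot be stepped along a
Y-ion series. A route must witness every cumulative Y mass — from
peptide+core through each residue or moiety gap to the intact
glycopeptide at any charge — in the spectrum; this subsumes the rule
that a moiety gap must be flanked by two consecutive observed Y ions.
The candidate with the maximum number of distinct gap orderings wins;
ties prefer the smaller moiety. Glycan masses are harmonised across
PSMs to the precise profile peak centers (1-Da rough histogram, then
0.002/0.001 Da sliding windows; moiety profiles at 0.001 Da smoothed by
a width-5 centred moving average) so one glycan gets one composition.

Glycan-level FDR mirrors the expansion machinery: decoy spectra,
rescored glycan fragments, linear tail-fit e-values, the same FDR
formula, flags at 1%. Fewer than ten GPSMs is reported as
indeterminate rather than fitted unreliably.

# Quantification

Each identified glycopeptide's isotopologue m/z list (peptide elements
plus pseudo-glycan, so modified glycans are covered) is traced through
the MS1 map at 20 ppm per observed charge state; the summed trace is
integrated by the trapezoidal rule from the shared apex outward until
intensity falls below 1% of the apex or a local valley — the method
defines area-under-profile without bounds, and valley/1% is the
standard choice that excludes neighbouring features. Site-specific
relative abundances normalise areas per glycosite; site occupancy is
deliberately not computed (enrichment destroys the non-glycosylated
reference).

# The synthetic-run generator

`simulateRun` emulates what the method exploits and measures: oxonium
ions and small B ions; the full core Y ladder at charges 1–2 with a
prominent Y1; the stepped Y series out to the intact glycopeptide
(with any planted moiety as the final gap); b/y ions with losses whose
base intensities are drawn once per backbone (log-normal, σ = 0.8) and
reused across glycoforms — the conserved-pattern property — scaled
down by `suppressionFactor` for sialylated glycoforms; uniform noise
peaks; and MS1 isotope envelopes on Gaussian elution profiles (σ = 10 s,
2 s sampling, 1200 s gradient) at charges 2–3. `corruptRun` degrades
targeted evidence: `drop_by` removes the peptide fragments of selected
spectra entirely (the hard version of sialic-acid suppression),
`shift_precursor_isotope` moves the reported precursor to M+1; planted
moieties are generated natively via `moietyFraction` because shifting a
finished spectrum would desynchronise the stepped Y ladder from the
recorded truth.

What the generator does not emulate — and what passing tests therefore
do not establish about real data: chimeric precursors (co-isolated
glycopeptides), retention-time drift and peak-shape asymmetry,
correlated (non-uniform) chemical noise, in-source decay, charge states
beyond 3, isotope-envelope interference between co-eluting species, and
realistic engine score distributions (the built-in scorer is far
simpler than MS-GF+). The test suite demonstrates that the algorithms
implement the method faithfully and recover planted truth under clean,
known conditions; performance claims on real runs require real runs.

Default generator conditions used by the acceptance suite: 500 spectra
(10 backbones × 5 glycoforms × 10 scans) with 40% of spectra
b/y-suppressed plus a 48-spectrum entrapment block of foreign
backbones for the expansion recall/FDR test; 36 spectra with planted
17.0265 and 79.9663 Da moieties for stepping; 32 spectra half-shifted
to M+1 for precursor correction; 5:3:2 abundance triplets for
quantification. These sizes keep every property measurable (binomial
noise on a 95% criterion at n ≈ 30–200 is a few percent) while the
whole suite stays fast enough to run routinely.

# Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fragmentTolPpm` | 20 | fragment and oxonium matching half-window |
| `precursorTolPpm` | 5 | precursor matching; propagated to glycan-mass tolerance |
| `minOxonium` | 3 | distinct oxonium ions required ("more than two") |
| `minCoreIons` | 3 | core Y ions per backbone candidate |
| `maxCoreCandidates` | 5 | backbone candidates per spectrum |
| `qThreshold` | 0.01 | stage-one PSM q cutoff (0 allowed: empties the pipeline) |
| `fdrThreshold` | 0.01 | expansion and glycan FDR gates |
| `rtWindow` | 1800 s | expansion retention-time half-window (long gradients: raise) |
| `alpha` | 0.3 | intensity exponent in both scores |
| `moietyRange` | 1–300 Da | stepping moiety search interval |

The oxonium list (`defaultOxoniumList`) is a configurable standard set
(HexNAc ladder, Hex, HexHexNAc, NeuAc/NeuGc ± water, phospho-Hex
243.0269); the phospho-Hex entry differs by ~0.5 mDa between the
proton and hydrogen-atom charging conventions, well inside the 20 ppm
screening window at m/z 243.

# Degenerate inputs and numerical notes

Empty spectra screen negative; spectra with no ladder produce no
candidates (not an error). Duplicate m/z peaks are merged by intensity
summation at construction. An all-zero site is dropped from the
distribution with a warning. The e-value model refuses to extrapolate
from degenerate tails. Atomic masses are CODATA/NIST monoisotopic
values to ≥6 decimals; the proton mass 1.007276 is used for every
m/z↔mass conversion. Fe-54 is omitted from the iron isotope vector
(offsets must start at the principal isotope); iron-bearing species are
outside the package's chemistry.

# Known limitations

Chimeric spectra are not deconvoluted — a co-isolated glycopeptide's
ladder appears as a competing candidate at best. WURCS-encoded fine
structure is not parsed; topologies come from the nested-parenthesis
column or the canonical fallback, so structural isomers beyond
Y/B-mass-set differences are not distinguished, and the moiety's
position within the glycan is not localised. O-glycosylation and
ETD/EThcD fragmentation are out of scope. The built-in search engine
is intentionally minimal; its q values are honest target-decoy
estimates but rest on a much smaller feature set than a production
engine.
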