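---
title: "Methods: mass calculus, annotation and validation in glycomaldi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass calculus, annotation and validation in glycomaldi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomaldi)
```

## The problem

MALDI-TOF profiling of permethylated N-glycans is the workhorse of tissue
glycomics: glycans are released with PNGase F, permethylated, and profiled
in reflector mode, with each centroided peak assigned a monosaccharide
composition.  Sulfoglycomics extends this to sulfated glycans: a mild
permethylation preserves sulfate esters, anion exchange separates the
sulfated pool from the neutral/sialylated pool, and the sulfated pool is
profiled in negative-ion mode, where the sulfate carries the charge.
`glycomaldi` implements the complete desk-side calculus for this workflow —
ion masses, composition enumeration, peak annotation, MS/MS diagnostic
logic for sulfate position, glycan-class statistics — together with
synthetic-data generators so that every stage can be validated end to end
with known ground truth.

## Mass model

A composition is a count vector (Hex, HexNAc, dHex, NeuAc) plus a sulfate
count.  The neutral monoisotopic mass of the fully permethylated,
free-reducing-end glycan (free-acid form) is

    M = nHex*204.0998 + nHexNAc*245.1263 + ndHex*174.0892
        + nNeuAc*361.1737 + 46.0419 + nS*(SO3 - CH2)

where 46.0419 Da (C2H6O) closes the two chain termini and each sulfate
contributes SO3 − CH2 = +65.9412 Da because the sulfated hydroxyl escapes
methylation.  Singly charged ion conventions:

* positive, no sulfate: [M + Na]+;
* negative, n sulfates: [M − nH + (n−1)Na]−, i.e. all sulfates
  deprotonated with n−1 sodium counterions;
* positive, n sulfates: [M − nH + (n+1)Na]+, the fully sodium-exchanged
  salt.

The negative-mode formula deserves a note.  The conventional label
"[M−H+(n−1)Na]−" is ambiguous about what M is; reading M as the free acid
and subtracting only one proton overshoots the observed di-sulfated ions by
1 Da.  The convention adopted here (all sulfates deprotonated) reproduces
the mono-sulfated labels, the di-sulfated labels, and their +88 Da spacing
(SO3 − CH2 + Na − H = 87.92) simultaneously, so it is the one frozen into
the package.  Two consequences are useful invariants: consecutive
sulfation states of the same composition are spaced by 87.92 Da in negative
mode, and the positive-salt/negative pair of a mono-sulfated glycan is
split by exactly 2(Na − H) = 45.96 Da.

The electron mass is ignored and no isotopic envelope is modeled
(reflector-mode monoisotopic peaks); both effects are far below the
matching tolerance.  Printed profile labels mix floor and round
conventions (a computed 1579.8 is labelled "1579", a computed 2040.9
"2041"), so agreement with integer labels is always assessed at ±1 Da.

## Annotation

`annotate_spectrum()` filters peaks at S/N ≥ 2 (the acquisition
convention) inside the 1000–6000 m/z range, then enumerates, for each
retained peak, every composition whose ion m/z falls within the tolerance.
Defaults:

* tolerance ±0.5 Da — externally calibrated MALDI-TOF reflector accuracy;
* bounds Hex ≤ 12, HexNAc ≤ 10, dHex ≤ 4, NeuAc ≤ 6, Sulf ≤ 3, with the
  N-glycan core minima (Hex ≥ 3, HexNAc ≥ 2) and plausibility caps
  NeuAc ≤ HexNAc − 2, Sulf ≤ Hex − 2.

Candidates are ranked by absolute mass error; exact ties are broken by
parsimony (fewer residues, then fewer sulfates, then the canonical string).
This ranking is a policy, not a reconstruction of manual curation: curated
workflows resolve ties against a structure database and prior knowledge.
All candidates are preserved in the report; unassigned peaks are kept and
flagged, mirroring the asterisked signals of curated profiles.

Satellite flagging links peak pairs spaced by −14.016 Da
(under-permethylation, one missing methyl) and, in the sulfated fraction,
by +87.92 Da (a di-sulfation companion).  Links never alter rank-1
assignments — a −14 satellite is evidence about its parent, not a new
composition.

## Composition-level classification

Composition alone cannot prove topology, so classification is explicitly
heuristic:

* oligomannose: HexNAc = 2, Hex ≥ 5; paucimannose: HexNAc = 2, Hex ≤ 4;
  hybrid: HexNAc = 3, Hex ≥ 5 (the minimal composition consistent with a
  mono-antennary hybrid); complex otherwise.
* antennarity = min(HexNAc − 2, 4).  Where a LacNAc-extended biantennary
  and a genuine tri-antennary share a composition, both readings exist; the
  package reports the antennarity reading and leaves the extension
  hypothesis to MS/MS.
* bisect_candidate when HexNAc − 2 > Hex − 3: an extra HexNAc without its
  galactose is *consistent with* a bisecting GlcNAc.  The flag is never
  promoted to a claim of bisection.
* dHex ≥ 1 maps to core_fucosylated, because in this tissue context
  fucosylation is overwhelmingly on the core; fragment-level evidence
  (e.g. a B ion retaining GlcNAc+Fuc) can override.

`desialylate()` models exoglycosidase treatment: sialidase A removes all
NeuAc (idempotent); sialidase S removes only the α2,3-linked share, default
0 because α2,6 linkage dominates these N-glycomes.  A composition cannot
track which *remaining* NeuAc are α2,3 after a partial digest, so
idempotence is only guaranteed at fractions 0 and 1.

## MS/MS fragment conventions

Glycosidic B/C/Y/Z ions are enumerated per bond (4 per bond before
polarity filtering), with internal fragments from up to two cleavages
(capped to bound enumeration).  The end-group bookkeeping for
permethylated fragments was frozen only after reproducing the printed
validation ions of the sulfated biantennary precursor (m/z 2286 negative /
2332 positive salt):

* positive B = Σ(residues) + 15.0229 + (Na − H) (sodiated oxocarbenium);
* negative B = Σ(residues) + 15.0229 − 2H, sulfate-retaining fragments
  only (the sulfate is the charge carrier);
* Y = precursor − Σ(lost residues) − 14.0157 per cleavage; in positive
  mode a departing sulfate also takes its sodium (− 21.98 per sulfate
  lost); in negative mode the retained part must keep a sulfate;
* C = B + H2O, Z = Y − H2O.

These conventions reproduce the B-type core-fucosylation ion (1834), the
sequential antenna Y ions (2067, 1822) and the positive-mode complementary
ions (1781, 2026, 486) within ±1 Da.

Cross-ring (A/X) and elimination (E) ions are *not* enumerated.  The three
masses diagnostic for 3-O-sulfation of galactose (153, 181, 253) are
carried as curated constants in `diagnostic_ions()`, alongside the
computed sulfate anion (96.96) and B-type sulfo-Gal (283.05) and
sulfo-LacNAc (528.17) ions.  E-ion chemistry is used as a fixed signature
here; deriving it is out of scope.  The decision chain in
`assign_sulfo_linkage()` is conservative: m/z 97 establishes sulfate; 97 +
528 a sulfo-LacNAc; 283 places the sulfate on the terminal galactose; and
the 3-O linkage is called only when 97 *and* at least one of 153/181/253
match.  Anything less is reported as indeterminate — including the
genuinely ambiguous di-sulfated-LacNAc isomer question, which the package
never resolves.  One nomenclature note: the terminal sulfo-Gal B ion is
conventionally labelled "B2" in annotated spectra even though it spans one
residue; the package stores it as a B-type terminal sulfo-Gal entry.

## Statistics

Per-sample glycan-class profiles are TIC-normalized fractions of rank-1
assigned intensity; the four structural categories partition assigned
signal (they sum to 1), while feature classes (branched = antennarity ≥ 3,
bisect_candidate, sialylated, core_fucosylated, sulfated, di_sulfated)
overlap freely.  Glycan classes are compared with unpaired two-sample
t-tests (pooled variance by default, Welch as an option); expression is
compared with a paired t-test on per-patient tumor − normal differences.
RPKM is tested untransformed by default (a log2(x+1) option exists), no
multiple-testing correction is applied by default (a Benjamini–Hochberg
option exists), and p < 0.05 is the significance rule — all three choices
match the comparison design the package operationalizes.  Degenerate
inputs are handled explicitly rather than delegated: zero variance with
equal means is an error, zero variance with unequal means reports p = 0
with a warning.

## What the generators emulate — and what they do not

`simulate_spectrum()` emulates a centroided reflector peak list: one peak
per library composition at its theoretical ion m/z plus Gaussian error
(σ = 0.05 Da), log-normal intensities (σ_log = 0.5) around the library's
base abundances, under-permethylation satellites (probability 0.3,
intensity ratio 0.2 — a fixed ratio so satellite links are testable),
di-sulfation companions in the sulfated fraction (probability 0.2), and
Poisson(20) noise peaks uniform over the range with S/N drawn below the
filtering threshold (0.5–1.9) while signals draw S/N in 3–50.  The default
library is the set of compositions dominating the thyroid profiles: the
oligomannose series, the core-fucosylated biantennary series with 0–2
sialic acids, minor tri-/tetra-antennary and bisect-candidate species, and
the mono-/bi-/tri-antennary mono-sulfated set with one di-sulfated
biantennary.

`simulate_cohort()` (default 5 patients, the paired-sample design of the
profiling comparisons) draws a per-patient, per-composition abundance
effect (log σ = 0.5) shared by both members of a pair, applies class-level
multipliers to the tumor member — branched ×1.8, bisect-candidate ×1.8,
sialylated ×0.6, di-sulfated ×0.4, oligomannose unchanged, encoding the
observed tumor directions — and adds residual log-noise (σ = 0.3) per
sample.  `simulate_expression()` (default 20 pairs, matching the compared
RNAseq cohort) generates RPKM = 2^(gene baseline + patient effect ±
log2-fold-change + noise) for a ten-glycogene panel whose default signs
follow the reported directions (MGAT3 up, MGAT4B up, ST6GAL1 down, MAN1A1
down, MAN1B1 up, GAL3ST3 null, GAL3ST4 up, B4GALT3/5/6 up), with unit
|log2FC| as a conventional two-fold effect.

What passing tests on these data do **not** show: real spectra have
isotope envelopes, baseline structure, detector saturation, mass-dependent
calibration drift, and chemical noise that is not uniform in m/z; real
cohorts have patient covariates and compositional correlations between
classes.  The generators validate the *logic* of the pipeline (masses,
matching, ranking, satellite algebra, test calibration), not its
robustness to raw-data pathology, which is upstream of this package's
scope (no baseline correction, centroiding or smoothing is provided).

## Numerical choices and problem sizes

All masses are monoisotopic, in Da, carried at the precision of the
residue table (4 decimals); matching tolerances are user-set in Da
(default 0.5 for MS and MS/MS matching, 0.3 for satellite spacings).
Enumeration is exhaustive over the bounded grid (about 10^4 compositions
under defaults), vectorized, and deterministic including tie order.  The
validation suite uses 100 random targets against a brute-force oracle,
20 replicate spectra for recovery (≥95% observed at σ = 0.05 Da; exactly
100% at σ = 0), 10,000 Monte-Carlo replicates for t-test calibration
(empirical type-I error within [0.04, 0.06] at α = 0.05 on both the
unpaired and paired paths), and 20 seeds for the planted-MGAT3 power check
(≥95% detection) — sizes chosen so the whole suite runs in well under a
minute of CPU per stage while keeping Monte-Carlo error small against the
acceptance bands.

## Known limitations

* Composition-level class calls (bisection, core fucose, hybrid,
  tri-antennary vs LacNAc extension) are heuristics and are documented as
  such; only MS/MS can upgrade them.
* O-glycans, glycosaminoglycans, phosphorylated oligomannose species,
  multiply charged ions and average masses are out of scope.
* The sulfo-linkage verdict depends on curated diagnostic masses; a
  different derivatization chemistry would need a different table.
* `read_peaklist()` expects centroided peak lists; raw profile data must
  be centroided upstream.
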