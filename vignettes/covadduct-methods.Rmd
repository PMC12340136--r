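---
title: "Methods: covalent-adduct mapping, crosslink mass search and inhibition kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: covalent-adduct mapping, crosslink mass search and inhibition kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covadduct)
```

## Scope

`covadduct` implements the computational core of chemoproteomics target
discovery for sulforaphane (SFN), the electrophilic isothiocyanate
stabilized clinically as SFX-01. SFN covalently adducts reactive protein
cysteines; mapping which proteins are hit in vivo, and what chemistry the
adduct settles into on a given target, takes three distinct numerical
procedures that this package provides as tested, reusable functions:

1. **Spectral-count differential enrichment** — which proteins are
   reproducibly immuno-enriched from treated versus control tissue, scored
   from peptide-spectrum-match (PSM) counts.
2. **Crosslink mass search** — whether a bridged (dithiolethione) adduct
   between two cysteines of one protein (Shp2) explains otherwise-unassigned
   precursor masses, via in-silico digestion and non-cleavable-linker
   matching.
3. **Inhibition kinetics** — how phosphatase activity decays with inhibitor
   concentration, via a DiFMU standard curve and a one-phase exponential
   decay fit.

A fourth module generates seeded synthetic data with planted ground truth
for all of the above, so every stage is testable without any raw
mass-spectrometry download.

## Spectral-count enrichment model

Each identified PSM is one counting unit. Identifications are accepted when
the peptide probability exceeds 90% and the protein probability exceeds
99.9% (both strictly, matching the "greater than" acceptance wording of
Scaffold-style validation), and a protein needs at least two retained PSMs
(inclusive). After tallying a protein-by-sample count matrix for the
4-versus-4 design, per-group totals are formed by summation and a zero
total is replaced by a pseudocount of 0.1 — applied to *totals only*, never
to the per-sample counts that feed the t-test. The volcano coordinates are

- effect: `x = log2(treated_total / control_total)` on the adjusted totals;
- confidence: `y = -log10(p)` from a two-sided two-sample t-test on the
  per-sample counts, capped at 16.

Significance is the inclusive rectangular gate `x >= 2` (at least fourfold)
and `y >= 1.3` (confidence over 95%), in the treated-enriched direction
only.

Two points were genuinely open and are resolved here as package defaults:

- **Log base of y.** The confidence axis of this kind of volcano is often
  labelled a natural log, yet the conventional 95% gate of 1.3 equals
  `-log10(0.05)` — the two statements cannot both hold. The default here is
  `-log10`, so that the threshold value means the stated confidence, and
  `log_base_y = "ln"` is selectable for the other reading.
- **t-test variant.** Nothing in the procedure fixes the variant; the default is the
  pooled-variance Student test (the classic choice for a balanced 4-vs-4
  design) with Welch available by flag. Degenerate variances are handled
  explicitly rather than erroring: all counts identical gives `p = 1`; two
  zero-variance groups with different means give `p = 0` with `y` at the
  cap. Proteins with zero PSMs in both groups have an undefined ratio and
  are excluded (and logged), not reported at `x = 0`.

## Digestion and mass arithmetic

Digestion uses strict trypsin specificity: cleavage C-terminal to K or R,
suppressed before proline — the default convention of the common search
engines. All peptides with up to `max_missed` internal sites (default 3)
are enumerated and length-filtered (4–60 residues by default). The default
of three missed cleavages is deliberate: bridged-cysteine evidence requires
longer, partially cleaved peptides to be reachable. Coordinates are 1-based
so cysteine positions read exactly like residue numbering (Cys333 etc.).

All masses are monoisotopic, derived from an elemental table
(H, C, N, O, S) and residue formulas, matching Orbitrap precursor usage;
`m/z = (M + z·p)/z` with the proton mass `p = 1.007276 Da`.

## Crosslink candidate model

The adduct chemistry: SFN's isothiocyanate first adds across a cysteine
thiol to give a dithiocarbamate (mono-adduct, +C6H11NOS2 = 177.0282 Da);
a second, spatially proximal cysteine can then attack the dithiocarbamate
carbon, expelling the sulforaphane amine and leaving a cyclic
dithiolethione-type bridge between the two sulfurs. The net mass change for
the bridge used as the shipped default is therefore

```
bridge delta = +CS - 2H = 41.9564 Da
```

(the full molecule in, the amine out, one proton lost from each thiol).
Both deltas are *configuration values* (`linker_spec()`), not hard-coded
chemistry: the bridge's exact elemental composition is not established, and
other small-neutral losses in the cyclization would shift the delta. All
candidate masses obey strict additivity — for a peptide pair,
`M = m(a) + m(b) + delta` — and this is tested as an exact invariant.

Candidate enumeration covers, for a bridge: every unordered pair of
cysteine-containing peptides (including a peptide with a second copy of
itself), every cysteine-by-cysteine placement, and loop-links inside
peptides with two or more cysteines. Fixed cysteine caps (e.g. maleimide)
apply to non-bridged cysteines only — a bridged cysteine cannot also be
alkylated — and maleimide is OFF by default for the recombinant-protein
search. Search is intra-protein by default — the natural setting for a
single-protein (recombinant Shp2) database — with inter-protein pairing a
deliberate non-default.

MS1 matching converts each precursor to a neutral mass and accepts
candidates within 10 ppm (Orbitrap-class default). MS2 annotation builds
b/y ladders per constituent peptide at charges 1–2, treating the partner
peptide plus linker as a fixed mass on the bridged cysteine (the
non-cleavable-linker model); loop-link fragments must span neither or both
bridged residues. The score is simply the matched fraction of the
theoretical ladder — commercial crosslink engines such as XLinkX use
proprietary scoring, so this transparent score is declared plumbing:
adequate to rank planted candidates in simulation, not a calibrated
discriminant.

## The synthetic Shp2 worked example

The bridge reported on Shp2 joins Cys333 and Cys367, near the catalytic
Cys459. Because this package must run without network access, it ships a
**synthetic** 593-residue Shp2-like sequence (`shp2_like_sequence()`):
random canonical residues with cysteines fixed at coordinates 333, 367 and
459 and tryptic sites placed so the two bridge peptides are distinct. It is
clearly labelled `SHP2_SYNTHETIC` and is *not* the canonical Q06124
sequence; users with the real FASTA get the identical code path via
`read_fasta()`. The worked example plants a precursor at the Cys333–Cys367
bridge mass and verifies the search reports that bridge with a complete
fragment ladder.

## Kinetics

The DiFMU standard curve is an ordinary least-squares line over the
0–100 µM standards; product formation is read off by inverting the line,
with values outside the standard range flagged as extrapolated (a 1e-9
relative guard keeps exact boundary values unflagged). Inhibition follows
a one-phase exponential decay `Y(c) = plateau + (y0 - plateau)·exp(-k·c)`,
fitted by Levenberg–Marquardt least squares with multi-start: `k` from a
12-point log-spaced grid scaled to the dose span, `y0`/`plateau` from the
data extremes, constraints `k >= 0`, `plateau >= 0`. `r2 = 1 - SSres/SStot`
about the mean — the convention of common graphing software for nonlinear
fits — and exactly-constant data return `r2 = 0` by that convention with
`k = 0`. The fit is validated by parameter recovery on simulated data
rather than against any figure-derived statistic, since underlying assay
points are not distributed with this package.

## What the generators emulate — and what they do not

All generators hang off one `sim_config()` seed; each draws from its own
named stream, so changing spectra parameters never perturbs the count
simulation, and a fixed seed gives byte-identical output files.

- `gen_psm_table()` emulates the 4-vs-4 replicate design: Poisson counts
  (negative binomial with configurable size available, since real PSM
  counts are overdispersed), baseline mean 2 PSMs, 10 of 100 proteins
  enriched eightfold (treated mean 16 vs 2) — the planted-signal condition
  the enrichment validation uses. Probabilities are drawn so ~5% of rows
  fail the peptide filter and ~2% of proteins fail the protein filter,
  a realistic identification-quality mix at these thresholds.
- `gen_crosslink_spectra()` plants 10 bridge candidates per run as spectra:
  precursor at theoretical m/z with 5 ppm Gaussian jitter, charge 2–4,
  fragment ladders with 20% dropout, 100 uniform noise peaks per spectrum,
  plus 20 pure-noise decoy spectra. With 5 ppm jitter and a 10 ppm window
  the expected recovery is the 2-sigma normal mass, ~95.4%; observed
  recovery across seeds sits around 94–98%.
- `gen_dose_response()` emulates the inhibition dose series: zero plus
  log-spaced doses over 0.007–1.75 µM (a realistic SFX-01 assay range),
  y0 = 100, plateau = 10, k = 2 /µM, Gaussian noise sd 1 (1% of y0).

Not emulated: isotope envelopes, retention time, intensity models,
chimeric spectra, FDR structure of real search-engine output. Passing
tests therefore demonstrate correctness of the arithmetic, filters and
statistics under the stated generative model — not end-to-end performance
on raw instrument data.

## Problem sizes and numerical choices

The validation suite runs at desk scale by design: 100 random proteins of
up to 60 residues for digestion-oracle equivalence, 2,000 proteins for the
null t-test calibration, 20 seeds for each stochastic recovery property.
Ties, degenerate variances, zero-count proteins, empty peak lists and
boundary-exact precursors (a match exactly at ±tolerance is accepted; a
1e-9 ppm slack absorbs construction roundoff) all have defined, tested
behavior. Reports and tables are TSV with '.' decimals and LF endings so
fixed-seed runs are byte-reproducible.

## Reproducing the numbers

The `analysis/` scripts run the three stages over a simulated dataset and
print what they find; `scripts/acceptance.R --seed N --out f.json`
recomputes the headline quantities (boundary arithmetic, enrichment
sensitivity and false-flag rate, null type-I error, crosslink recovery,
the Shp2 bridge coordinates, decay parameter recovery) from scratch.
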