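---
title: "Recognizing molecular ion species in methane-CI GC-MS and assigning formulas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing molecular ion species in methane-CI GC-MS and assigning formulas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimion)
```

## The problem

Electron ionization (EI) GC-MS fragments trimethylsilylated (TMS)
metabolites so thoroughly that the molecular ion is usually weak or absent,
which blocks any formula-calculation workflow that needs a precursor mass.
Methane chemical ionization (CI) is soft enough to preserve a predictable
family of ions around the intact derivatized molecule M:

* `[M-CH3]+` — methyl loss from a TMS group, frequently the base peak;
* the molecular cluster `[M-H]+`, `[M]+`, `[M+H]+`, at variable but usually
  greater than 5 % of base-peak intensity;
* the reagent-gas adducts `[M+C2H5]+` and `[M+C3H5]+`, mostly below 5 %;
* occasionally `[M-H2O+H]+` (water loss) and, for some analytes, a
  rearrangement adduct `[M+TMS]+` *above* `[M+C3H5]+`.

Because every inter-species mass difference is an exact constant
(`[M]+ − [M-CH3]+` = 15.023475, `[M+H]+ − [M-H]+` = 2.015650,
`[M+TMS]+ − [M]+` = 73.047352 Da, ...), the pattern can be recognized
automatically in centroided accurate-mass spectra, yielding the neutral
monoisotopic mass — the input every formula engine needs.

## Mass arithmetic and conventions

Monoisotopic masses are hard-coded IUPAC/NIST values at nine decimals over
the supported element set C, H, N, O, P, S, Si. Derivatization is pure
formula arithmetic: each TMS group replaces one active hydrogen
(net +C3H8Si, +72.0395 Da), each methoximation converts a carbonyl to a
methyloxime (net +CH3N, +29.0266 Da). Active-hydrogen *perception* is out
of scope: group counts are inputs.

**Electron mass.** Cation m/z is computed as plain neutral-formula
arithmetic, without subtracting the electron mass. This is deliberate: the
reference worked examples for this instrument class tabulate theoretical
m/z that way (the `[M]+` value of the 3-TMS derivative of
3,4-dihydroxyphenylacetic acid is printed as 384.1608, the neutral
C17H32O4Si3 mass, not the electron-corrected 384.1603). An
`electron_correction` flag is available on `ion_mz()` for the physically
strict convention, default off.

**Isotope patterns.** `isotope_pattern()` convolves per-element isotope
distributions one atom at a time and aggregates on nominal-mass shift, so
13C and 29Si contributions merge within A+1 — which is what a
unit-resolution grouping of centroided peaks observes. Abundances are
renormalized to sum to 1 after truncation at `max_shift`. The
implementation is checked against an exhaustive multinomial enumeration
oracle to 1e-6.

## The detector

`detect_molecular_ion()` proceeds in five steps:

1. normalize intensities to the base peak;
2. group isotopologues greedily in ascending m/z: a peak joins an open
   group when its distance to the group's last member lies in
   [0.996, 1.007] Da and its intensity does not exceed the group's
   monoisotopic member. The window covers 13C (+1.00336) and 29Si
   (+0.99957) while excluding the +1.00783 proton spacing, so adjacent
   cluster species open separate groups;
3. treat every monoisotopic member above `noise_floor` as an anchor — as a
   hypothetical `[M-CH3]+` (primary, because that fragment is the most
   reliably present) and as a hypothetical cluster member (fallback for
   spectra without methyl loss) — and test all species positions at exact
   offsets within `mz_tolerance`;
4. score each hypothesis by the count of distinct species found, breaking
   ties by summed relative intensity, then by larger M; acceptance needs
   `[M-CH3]+` plus one more species or two cluster members, and at least
   one cluster member at or above `molecular_intensity_floor`;
5. in strict mode, reject the spectrum when any candidate peak above the
   `[M+C3H5]+` position is unexplained ("unexplained high-mass ions") —
   the empirically dominant failure mode, resolved either by the
   `[M+TMS]+` whitelist or by lenient mode.

The reported neutral mass is the mean of the per-species back-calculated
masses, so it is consistent with every supporting ion within tolerance.
Water-loss ions are annotated but never anchor or score.

### Numerical choices worth knowing

* `mz_tolerance` defaults to 0.005 Da. The source workflow never states its
  tolerance; observed accuracy on these instruments is about 0.001 ±
  0.0008 Da, and 5 mDa is a comfortable 3-sigma envelope that still
  separates the 4.5-mDa gap between `[M]+` and the 13C peak of `[M-H]+`.
* The intensity floors encode the qualitative ">5 % bp for molecular
  species, <5 % for adducts" observation as 0.05 and 0.001 defaults; both
  are configurable because real spectra include patterns too weak to pass.
* **Isotopologue tails in the strict screen.** For Si-rich ions the A+2 bin
  is dominated by 30Si (+1.9937 Da), so the A+2 − A+1 spacing (~0.992 Da)
  falls below the grouping window and A+2 peaks of the highest adduct can
  escape their group, landing above the high-mass ceiling. The strict
  screen therefore explains any peak sitting k nominal units
  (k × [0.992, 1.005] Da, k = 1..3) above a found or whitelisted ion before
  declaring it unexplained. Without this, roughly 8 % of well-behaved
  Si-heavy synthetic spectra are falsely rejected; with it, strict-mode
  rejections coincide exactly with generated contaminants.
* Tie-breaks (summed intensity, then larger M) are conventions chosen for
  determinism; the underlying method is silent on ties.

## Formula assignment

`decompose_mass()` enumerates *all* neutral formulas within ppm tolerance
of an observed ion under per-element bounds — loops over Si, P, S, N, O
with mass pruning, a vectorized C loop, and the H count solved from the
remainder, so completeness relative to the bounds is structural (and tested
against a grid-enumeration oracle). Filters: RDBE ≥ −0.5 with Si counted
tetravalent and N, P trivalent (`1 + C + Si − H/2 + (N+P)/2`), H/C in
[0.1, 4] when carbon is present, and optionally Si ≥ 1 — the natural
constraint for TMS derivatives. Default bounds (C ≤ 60, H ≤ 120, N ≤ 10,
O ≤ 25, P ≤ 4, S ≤ 4, Si ≤ 12, 10 ppm) cover derivatized metabolites to
about 1 kDa; they are invented here, flagged as such, and configurable.

`rank_candidates()` scores `w1 * scaled(−|ppm error|) +
w2 * scaled(explained fragments)`, where a peak is explained if some
subformula of the candidate matches it as a cation within tolerance (this
subsumes CH3, TMSOH and H2O losses). Weights default to 1 after per-list
min-max scaling. This is a transparent local stand-in for an external
engine such as SIRIUS — `write_sirius_ms()` and `write_mgf()` exist
precisely so the real engine can be run on the same assignments — and no
claim is made that its absolute top-1 rates match fragmentation-tree
scoring. On the phosphoric-acid worked example the true formula carries
sub-ppm error but ranks third among the 10-ppm candidate set: mass error
alone cannot separate isomeric CHNOPSSi formulas at 300-600 Da, which is
exactly why fragment and isotope evidence exist as separate terms.

`assign_with_strategy()` exposes the three anchoring strategies:
`m_minus_ch3` (decompose the methyl-loss peak), `molecular_ion` (decompose
the base cluster species) and `with_isotopes` (add an isotope-ratio
agreement term). The interesting physics is in the failure of the third:
when the cluster species overlap within unit resolution, the 13C peak of
`[M-H]+` merges with the monoisotope of `[M]+` (and likewise one step up),
inflating observed A+1/A ratios and biasing the merged centroid, so isotope
evidence actively misleads. `[M-CH3]+` is immune — it can only derive from
the monoisotopic molecular ion — which is why it is the preferred anchor.
The package reproduces this direction of effect on synthetic merged-cluster
libraries (top-1 recovery: with_isotopes ≤ m_minus_ch3), and that
directional property, not any absolute percentage, is what the test suite
asserts.

## The synthetic world

`simulate_library()` generates centroided CI spectra from a ~20-compound
table of literature formulas. Its defaults *are* the stated world of the
method it emulates: base-species priors 74 % `[M+H]+` / 7 % `[M-H]+` / 4 %
`[M]+`, 15 % hard spectra split 37:14 between unexplained-high-mass
contaminants (an added `[M+TMS]+`) and patterns too weak to rise above
noise; `[M-CH3]+` present 84 % of the time with `[M+C2H5]+`/`[M+C3H5]+`
co-occurring at 90 %/84 %; water loss at 6 %; Gaussian m/z error of
2.8 ppm. Where the stated world gives only bands, the generator chooses
once: molecular-species intensities log-uniform in [15 %, 90 %] of base
peak with cluster companions at 20-80 % of the base species, adducts
log-uniform in [0.5 %, 4.5 %], and about five Poisson noise peaks per
spectrum at 0.1-2 %.

Two modeling choices matter for interpreting green tests. First, noise
peaks are placed *below* the molecular region, so every strict-mode
rejection is attributable to a deliberately generated hard case — real
spectra can of course carry high-mass junk, so the measured [0.80, 0.90]
recognition band is a property of the stated world, not an instrument
claim. Second, `merge_isotope_clusters` sums the cluster isotopologues into
shared unit-resolution bins (abundance-weighted centroids), reproducing the
QTOF's inability to resolve the 4.5-mDa splits; it does not model peak
shape, chromatography, co-elution, or detector saturation. A 100 %
clean-mode recognition rate therefore establishes correctness of the
arithmetic and the scan logic, not field performance.

## Known limitations

* Single charge, positive mode only; element set fixed at C/H/N/O/P/S/Si.
* No deconvolution: one compound per spectrum is assumed.
* The ranker's absolute accuracy is not benchmarked against
  fragmentation-tree engines; use the exporters for real identifications.
* Runtime: full-bounds decomposition near 600 Da costs about a second; the
  bundled evaluation harness uses compound-table-derived bounds and caps
  ranking at 15 candidates / 6 fragments per spectrum (identically across
  strategies) to keep the synthetic benchmark inside a few minutes.

## A worked session

```{r example}
s <- spectrum(c(299.0719, 315.1031, 343.1345, 355.1342), c(100, 40, 3, 2),
              metadata = list(name = "phosphoric acid 3TMS"))
a <- detect_molecular_ion(s)
a

head(assign_with_strategy(s, a, "m_minus_ch3")[, c("formula",
     "mass_error_ppm", "explained_fragments", "rank_score")], 3)
```
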